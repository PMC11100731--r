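#' Normalize antibody-capture (ADT) counts within batches
#'
#' Log-transforms (`log1p`) the raw antibody-capture counts and Z-scores
#' them within each sequencing batch, removing batch-scale effects. The
#' sample standard deviation (n - 1 denominator) is used.
#'
#' @param counts Non-negative numeric vector of ADT counts.
#' @param batch Batch label per cell.
#' @return Numeric vector of per-cell Z-scores.
#' @export
normalize_adt <- function(counts, batch) {
  stopifnot(length(counts) == length(batch))
  if (any(counts < 0, na.rm = TRUE))
    stop("normalize_adt: counts must be non-negative")
  z <- rep(NA_real_, length(counts))
  for (b in unique(batch)) {
    i <- which(batch == b)
    if (length(i) < 2)
      stop("normalize_adt: batch '", b, "' has fewer than 2 cells")
    x <- log1p(counts[i])
    s <- stats::sd(x)
    if (is.na(s) || s == 0)
      stop("normalize_adt: batch '", b, "' has zero variance")
    z[i] <- (x - mean(x)) / s
  }
  z
}

#' Assign rank-based low/mid/high bins
#'
#' Ranks the values ascending and labels the bottom `floor(f_low * n)` as
#' `"low"`, the top `floor(f_high * n)` as `"high"` and the remainder as
#' `"mid"` (the default 30/40/30 split). Ties are broken
#' deterministically by `ids` (lexicographic; input index if `ids` is
#' `NULL`); a warning is issued when tied values straddle a bin boundary.
#'
#' @param values Numeric vector (length at least 3).
#' @param fractions Length-3 fractions `(low, mid, high)` summing to 1.
#' @param ids Optional tie-breaking identifiers (e.g. barcodes).
#' @return Character vector of bin labels in input order, with attribute
#'   `boundary_ranks` (the last low rank and first high rank).
#' @export
assign_bins <- function(values, fractions = c(0.3, 0.4, 0.3),
                        ids = NULL) {
  n <- length(values)
  if (n < 3) stop("assign_bins: need at least 3 values")
  if (length(fractions) != 3 || any(fractions < 0) ||
      abs(sum(fractions) - 1) > 1e-9)
    stop("assign_bins: fractions must be 3 non-negative values summing ",
         "to 1")
  if (is.null(ids)) ids <- seq_len(n)
  if (anyDuplicated(ids)) stop("assign_bins: ids must be unique")
  ord <- order(values, ids)
  n_low <- floor(fractions[1] * n)
  n_high <- floor(fractions[3] * n)
  bins <- rep("mid", n)
  if (n_low > 0) bins[ord[seq_len(n_low)]] <- "low"
  if (n_high > 0) bins[ord[seq(n - n_high + 1, n)]] <- "high"

  sorted <- values[ord]
  tie_at_boundary <- (n_low > 0 && n_low < n &&
                        sorted[n_low] == sorted[n_low + 1]) ||
    (n_high > 0 && n - n_high >= 1 &&
       sorted[n - n_high] == sorted[n - n_high + 1])
  if (tie_at_boundary)
    warning("assign_bins: tied values straddle a bin boundary; ties ",
            "broken by id order")
  attr(bins, "boundary_ranks") <- c(low_max_rank = n_low,
                                    high_min_rank = n - n_high + 1)
  bins
}

# ---- exact enumeration machinery (small samples, no ties) -------------

# all ways to partition ranks 1..N into groups of the given sizes,
# applying `stat_fun(list_of_rank_vectors)`; returns the statistic values
enumerate_group_stats <- function(sizes, stat_fun) {
  n <- sum(sizes)
  res <- numeric(0)
  recurse <- function(remaining, groups) {
    if (length(groups) == length(sizes) - 1) {
      res[[length(res) + 1]] <<- stat_fun(c(groups, list(remaining)))
      return(invisible())
    }
    k <- sizes[length(groups) + 1]
    picks <- utils::combn(length(remaining), k, simplify = FALSE)
    for (p in picks) {
      recurse(remaining[-p], c(groups, list(remaining[p])))
    }
  }
  recurse(seq_len(n), list())
  unlist(res)
}

mw_u_stat <- function(rank_groups) {
  n1 <- length(rank_groups[[1]])
  sum(rank_groups[[1]]) - n1 * (n1 + 1) / 2
}

kw_h_stat <- function(rank_groups) {
  n <- sum(lengths(rank_groups))
  s <- sum(vapply(rank_groups,
                  function(r) sum(r)^2 / length(r), 0))
  12 / (n * (n + 1)) * s - 3 * (n + 1)
}

friedman_q_stat <- function(rank_matrix) {
  # rank_matrix: blocks x treatments of within-block ranks
  k <- ncol(rank_matrix)
  n <- nrow(rank_matrix)
  rj <- colSums(rank_matrix)
  12 / (n * k * (k + 1)) * sum(rj^2) - 3 * n * (k + 1)
}

has_ties <- function(x) anyDuplicated(x) > 0

#' Rank-based group comparison with all-vs-all post hoc
#'
#' Runs the nonparametric test matching the design: Mann-Whitney for two
#' independent groups, Kruskal-Wallis for three or more independent
#' groups, Friedman for three or more related groups (equal block
#' counts, blocks aligned by element index). With at most 10
#' observations and no ties, the two-sided p-value is computed by exact
#' enumeration of the permutation distribution; otherwise the standard
#' normal / chi-square approximations with tie correction are used (via
#' [stats::wilcox.test()], [stats::kruskal.test()],
#' [stats::friedman.test()]).
#'
#' For three or more groups an all-pairs post-hoc table is attached:
#' Dunn-type pairwise rank comparisons (tie-corrected) after
#' Kruskal-Wallis, mean-rank comparisons after Friedman, both with Holm
#' adjustment.
#'
#' @param groups Named list of numeric vectors (for `friedman`, vectors
#'   of equal length whose i-th entries form block i).
#' @param kind `"mann_whitney"`, `"kruskal_wallis"` or `"friedman"`.
#' @return A list of class `rank_test`: `kind`, `method`
#'   (`"exact enumeration"` or `"asymptotic"`), `groups` (label/size
#'   tibble), `statistic` (U, H or Q), `p_value`, `post_hoc` (tibble or
#'   `NULL`).
#' @examples
#' rank_test(list(a = c(1, 2, 3), b = c(4, 5, 6)), "mann_whitney")
#' @export
rank_test <- function(groups,
                      kind = c("mann_whitney", "kruskal_wallis",
                               "friedman")) {
  kind <- match.arg(kind)
  if (is.null(names(groups)) || any(!nzchar(names(groups))))
    names(groups) <- paste0("group", seq_along(groups))
  k <- length(groups)
  if (kind == "mann_whitney" && k != 2)
    stop("rank_test: mann_whitney requires exactly 2 groups")
  if (kind == "kruskal_wallis" && k < 3)
    stop("rank_test: kruskal_wallis requires at least 3 groups")
  if (kind == "friedman") {
    if (k < 3) stop("rank_test: friedman requires at least 3 groups")
    if (length(unique(lengths(groups))) != 1)
      stop("rank_test: friedman requires equal block counts per group")
  }
  sizes <- lengths(groups)
  pooled <- unlist(groups, use.names = FALSE)
  n_total <- length(pooled)

  if (kind == "friedman") {
    mat <- do.call(cbind, groups)                 # blocks x treatments
    rmat <- t(apply(mat, 1, rank))
    stat <- friedman_q_stat(rmat)
    tied <- any(apply(mat, 1, has_ties))
    if (!tied && n_total <= 10) {
      perms <- permutations_of(k)
      nb <- nrow(mat)
      idx_grid <- as.matrix(expand.grid(rep(list(seq_len(nrow(perms))),
                                            nb)))
      stats_all <- apply(idx_grid, 1, function(sel) {
        pm <- do.call(rbind, lapply(seq_len(nb),
                                    function(b) perms[sel[b], ]))
        friedman_q_stat(pm)
      })
      p <- mean(stats_all >= stat - 1e-12)
      method <- "exact enumeration"
    } else {
      p <- stats::friedman.test(mat)$p.value
      method <- "asymptotic"
    }
    post <- friedman_posthoc(rmat, names(groups))
  } else if (kind == "mann_whitney") {
    r <- rank(pooled)
    rg <- split(r, rep(seq_along(groups), sizes))
    stat <- mw_u_stat(rg)
    if (!has_ties(pooled) && n_total <= 10) {
      dist <- enumerate_group_stats(sizes, mw_u_stat)
      p <- min(1, 2 * min(mean(dist <= stat + 1e-12),
                          mean(dist >= stat - 1e-12)))
      method <- "exact enumeration"
    } else {
      p <- stats::wilcox.test(groups[[1]], groups[[2]],
                              exact = FALSE)$p.value
      method <- "asymptotic"
    }
    post <- NULL
  } else {
    r <- rank(pooled)
    rg <- split(r, rep(seq_along(groups), sizes))
    if (!has_ties(pooled) && n_total <= 10) {
      stat <- kw_h_stat(rg)
      dist <- enumerate_group_stats(sizes, kw_h_stat)
      p <- mean(dist >= stat - 1e-12)
      method <- "exact enumeration"
    } else {
      kt <- stats::kruskal.test(pooled,
                                factor(rep(names(groups), sizes),
                                       levels = names(groups)))
      stat <- unname(kt$statistic)
      p <- kt$p.value
      method <- "asymptotic"
    }
    post <- dunn_posthoc(pooled, rep(names(groups), sizes))
  }

  structure(list(
    kind = kind, method = method,
    groups = tibble::tibble(label = names(groups), n = unname(sizes)),
    statistic = unname(stat), p_value = unname(p), post_hoc = post
  ), class = "rank_test")
}

permutations_of <- function(k) {
  if (k == 1) return(matrix(1, 1, 1))
  sub <- permutations_of(k - 1)
  out <- NULL
  for (i in seq_len(k)) {
    ins <- cbind(sub[, seq_len(i - 1), drop = FALSE], k,
                 sub[, seq(i, k - 1)[seq_len(k - i)], drop = FALSE])
    out <- rbind(out, ins)
  }
  out
}

# Dunn-type pairwise rank comparisons with tie correction, Holm-adjusted
dunn_posthoc <- function(values, labels) {
  n <- length(values)
  r <- rank(values)
  tie_term <- {
    t <- table(values)
    sum(t^3 - t) / (12 * (n - 1))
  }
  groups <- unique(labels)
  pairs <- utils::combn(groups, 2, simplify = FALSE)
  rows <- lapply(pairs, function(pr) {
    i <- labels == pr[1]; j <- labels == pr[2]
    z <- (mean(r[i]) - mean(r[j])) /
      sqrt((n * (n + 1) / 12 - tie_term) * (1 / sum(i) + 1 / sum(j)))
    tibble::tibble(group1 = pr[1], group2 = pr[2], statistic = z,
                   p = 2 * stats::pnorm(-abs(z)))
  })
  out <- dplyr::bind_rows(rows)
  out$p_adjusted <- stats::p.adjust(out$p, method = "holm")
  out$adjustment <- "holm"
  out
}

friedman_posthoc <- function(rank_matrix, labels) {
  k <- ncol(rank_matrix)
  nb <- nrow(rank_matrix)
  rbar <- colMeans(rank_matrix)
  se <- sqrt(k * (k + 1) / (6 * nb))
  pairs <- utils::combn(seq_len(k), 2, simplify = FALSE)
  rows <- lapply(pairs, function(pr) {
    z <- (rbar[pr[1]] - rbar[pr[2]]) / se
    tibble::tibble(group1 = labels[pr[1]], group2 = labels[pr[2]],
                   statistic = unname(z),
                   p = 2 * stats::pnorm(-abs(z)))
  })
  out <- dplyr::bind_rows(rows)
  out$p_adjusted <- stats::p.adjust(out$p, method = "holm")
  out$adjustment <- "holm"
  out
}

#' Spearman rank correlation
#'
#' @param x,y Numeric vectors of equal length (at least 3); ties are
#'   handled by average ranks. Constant vectors are rejected.
#' @return A list with `rho` and `p` (two-sided).
#' @export
spearman_correlation <- function(x, y) {
  if (length(x) != length(y))
    stop("spearman_correlation: x and y differ in length")
  if (length(x) < 3)
    stop("spearman_correlation: need at least 3 paired values")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("spearman_correlation: constant input vector")
  ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman"))
  list(rho = unname(ct$estimate), p = ct$p.value)
}

#' Association of one gene's expression with a grouping
#'
#' Compares a gene's (normalized) expression across bins or structure
#' labels: Mann-Whitney for two groups, Kruskal-Wallis with Dunn post hoc
#' for three or more. Groups with zero cells are dropped with a warning.
#'
#' @param expression Numeric vector of per-cell expression values.
#' @param grouping Group label per cell (bin or structure).
#' @return A list with `test` (a [rank_test()] result) and `summary`
#'   (per-group `n`, `median`, `iqr`).
#' @export
gene_bin_association <- function(expression, grouping) {
  stopifnot(length(expression) == length(grouping))
  keep <- !is.na(expression) & !is.na(grouping)
  expression <- expression[keep]
  grouping <- as.character(grouping[keep])
  groups <- split(expression, grouping)
  empty <- lengths(groups) == 0
  if (any(empty)) {
    warning("gene_bin_association: dropping empty group(s) ",
            paste(names(groups)[empty], collapse = ", "))
    groups <- groups[!empty]
  }
  if (length(groups) < 2)
    stop("gene_bin_association: fewer than 2 non-empty groups")
  kind <- if (length(groups) == 2) "mann_whitney" else "kruskal_wallis"
  test <- rank_test(groups, kind)
  summary <- tibble::tibble(
    group = names(groups),
    n = lengths(groups),
    median = vapply(groups, stats::median, 0),
    iqr = vapply(groups, stats::IQR, 0)
  )
  list(test = test, summary = summary)
}
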