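# Independent oracles used to validate the package's implementations.
# They deliberately take different computational routes: brute-force
# transitive closure for clustering, and base-R test statistics evaluated
# over explicitly enumerated group assignments for the rank tests.

# brute-force clonal clustering: all-pairs distances within each
# (v, j, CDR3-length) partition, then transitive closure by repeated
# boolean matrix multiplication
oracle_cluster <- function(records, max_dist) {
  v <- sub("\\*.*$", "", records$v_call)
  j <- sub("\\*.*$", "", records$j_call)
  key <- paste(v, j, nchar(records$junction_aa), sep = "|")
  membership <- rep(NA_integer_, nrow(records))
  next_id <- 0L
  for (k in unique(key)) {
    rows <- which(key == k)
    m <- length(rows)
    adj <- diag(m) > 0
    if (m > 1) {
      for (a in 1:(m - 1)) {
        for (b in (a + 1):m) {
          s1 <- strsplit(records$junction_aa[rows[a]], "")[[1]]
          s2 <- strsplit(records$junction_aa[rows[b]], "")[[1]]
          d <- mean(s1 != s2)
          adj[a, b] <- adj[b, a] <- d <= max_dist
        }
      }
      repeat {
        closure <- (adj %*% adj) > 0 | adj
        if (identical(closure, adj)) break
        adj <- closure
      }
    }
    seen <- rep(FALSE, m)
    for (a in seq_len(m)) {
      if (seen[a]) next
      comp <- which(adj[a, ])
      next_id <- next_id + 1L
      membership[rows[comp]] <- next_id
      seen[comp] <- TRUE
    }
  }
  membership
}

# partitions agree up to label renaming
same_partition <- function(a, b) {
  identical(as.integer(factor(a, levels = unique(a))),
            as.integer(factor(b, levels = unique(b))))
}

# enumerate all assignments of the pooled observations to groups of the
# given sizes and apply `fun(list_of_value_vectors)`
oracle_assignments <- function(values, sizes, fun) {
  out <- c()
  recurse <- function(remaining, acc) {
    if (length(acc) == length(sizes) - 1) {
      out[[length(out) + 1]] <<- fun(c(acc, list(remaining)))
      return(invisible())
    }
    for (p in utils::combn(length(remaining), sizes[length(acc) + 1],
                           simplify = FALSE)) {
      recurse(remaining[-p], c(acc, list(remaining[p])))
    }
  }
  recurse(values, list())
  unlist(out)
}

# exact Kruskal-Wallis p-value: tail probability of the base-R statistic
# over all enumerated assignments
oracle_kw_exact <- function(groups) {
  values <- unlist(groups)
  sizes <- lengths(groups)
  obs <- stats::kruskal.test(values,
                             factor(rep(seq_along(groups), sizes)))$statistic
  dist <- oracle_assignments(values, sizes, function(gs) {
    stats::kruskal.test(unlist(gs),
                        factor(rep(seq_along(gs), lengths(gs))))$statistic
  })
  mean(dist >= obs - 1e-12)
}

perms_list <- function(k) {
  if (k == 1) return(list(1L))
  out <- list()
  for (p in perms_list(k - 1)) {
    for (i in 0:(k - 1)) {
      out[[length(out) + 1]] <- append(p, k, after = i)
    }
  }
  out
}

# exact Friedman p-value: enumerate all within-block orderings
oracle_friedman_exact <- function(mat) {
  obs <- stats::friedman.test(mat)$statistic
  k <- ncol(mat)
  nb <- nrow(mat)
  perms <- perms_list(k)
  grid <- expand.grid(rep(list(seq_along(perms)), nb))
  dist <- apply(grid, 1, function(sel) {
    pm <- do.call(rbind, lapply(seq_len(nb),
                                function(b) unlist(perms[[sel[b]]])))
    stats::friedman.test(pm)$statistic
  })
  mean(dist >= obs - 1e-12)
}

# random clustering instance: a few V/J genes, CDR3s concentrated on few
# lengths so partitions contain several records
random_instance <- function(n, seed) {
  set.seed(seed)
  lens <- sample(10:12, n, replace = TRUE)
  aa <- c("A", "C", "D", "E", "F", "G")
  tibble::tibble(
    cell_id = sprintf("BC%03d", seq_len(n)),
    v_call = sample(c("IGHV1-S", "IGHV2-S"), n, replace = TRUE),
    j_call = sample(c("IGHJ1-S", "IGHJ2-S"), n, replace = TRUE),
    junction_aa = vapply(lens, function(l)
      paste(sample(aa, l, replace = TRUE), collapse = ""), "")
  )
}
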