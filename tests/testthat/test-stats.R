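test_that("ADT normalization Z-scores log counts within batches", {
  counts <- c(10, 20, 40, 80)
  z <- normalize_adt(counts, rep("b1", 4))
  expect_equal(mean(z), 0)
  expect_equal(stats::sd(z), 1)

  # batches are independent: an affine shift on the log scale in one
  # batch does not change its Z-scores
  c2 <- expm1(log1p(counts) + 2)
  z2 <- normalize_adt(c(counts, c2), rep(c("b1", "b2"), each = 4))
  expect_equal(z2[1:4], z2[5:8], tolerance = 1e-10)
  expect_equal(z2[1:4], z, tolerance = 1e-10)

  # two-cell batch under the sample-sd (n - 1) convention
  z3 <- normalize_adt(c(0, exp(1) - 1), c("a", "a"))
  expect_equal(z3, c(-1, 1) / sqrt(2))

  expect_error(normalize_adt(c(5, 5), c("a", "a")), "zero variance")
  expect_error(normalize_adt(c(5), c("solo")), "fewer than 2")
})

test_that("bins split 30/40/30 by rank with deterministic tie-breaking", {
  b <- assign_bins(sample(10))
  expect_equal(unname(table(b)[c("low", "mid", "high")]), c(3, 4, 3),
               ignore_attr = TRUE)

  b <- assign_bins(stats::rnorm(1000))
  expect_equal(sum(b == "low"), 300)
  expect_equal(sum(b == "mid"), 400)
  expect_equal(sum(b == "high"), 300)

  expect_warning(b <- assign_bins(rep(1, 10), ids = letters[1:10]),
                 "tie")
  expect_equal(unname(table(b)[c("low", "mid", "high")]), c(3, 4, 3),
               ignore_attr = TRUE)
  expect_error(assign_bins(c(1, 2)), "at least 3")
})

test_that("bins are invariant to order and monotone transforms", {
  set.seed(4)
  x <- stats::rnorm(50)
  ids <- sprintf("c%02d", 1:50)
  b1 <- assign_bins(x, ids = ids)
  perm <- sample(50)
  b2 <- assign_bins(x[perm], ids = ids[perm])
  expect_equal(as.character(b2[order(perm)]), as.character(b1))
  b3 <- assign_bins(exp(3 * x), ids = ids)
  expect_equal(as.character(b3), as.character(b1))
})

test_that("rank tests reproduce hand-derived small-sample results", {
  mw <- rank_test(list(a = c(1, 2, 3), b = c(4, 5, 6)), "mann_whitney")
  expect_equal(mw$statistic, 0)
  expect_equal(mw$p_value, 0.1)
  expect_equal(mw$method, "exact enumeration")
  expect_null(mw$post_hoc)

  kw <- rank_test(list(a = c(1, 2), b = c(3, 4), c = c(5, 6)),
                  "kruskal_wallis")
  expect_equal(kw$statistic, 4.571, tolerance = 1e-3)
  expect_s3_class(kw$post_hoc, "tbl_df")
  expect_equal(nrow(kw$post_hoc), 3)

  fr <- rank_test(list(t1 = c(1, 2), t2 = c(5, 6), t3 = c(9, 10)),
                  "friedman")
  expect_equal(fr$statistic, 4)
})

test_that("rank tests enforce the group-count contract", {
  expect_error(rank_test(list(a = 1:3), "mann_whitney"), "exactly 2")
  expect_error(rank_test(list(a = 1:3, b = 1:3), "kruskal_wallis"),
               "at least 3")
  expect_error(rank_test(list(a = 1:3, b = 1:3, c = 1:2), "friedman"),
               "equal block")
})

test_that("exact Mann-Whitney p-values match the enumeration oracle", {
  set.seed(11)
  for (n1 in 1:4) {
    for (n2 in n1:(10 - n1)) {
      if (n1 + n2 > 10) next
      x <- sample(seq(0.1, 100, by = 0.7), n1 + n2)
      g <- list(a = x[seq_len(n1)], b = x[-seq_len(n1)])
      got <- rank_test(g, "mann_whitney")
      expect_equal(got$method, "exact enumeration")
      oracle <- stats::wilcox.test(g$a, g$b, exact = TRUE)$p.value
      expect_equal(got$p_value, oracle,
                   label = sprintf("MW n1=%d n2=%d", n1, n2))
    }
  }
})

test_that("exact Kruskal-Wallis p-values match the enumeration oracle", {
  set.seed(12)
  combos <- list(c(2, 2, 2), c(1, 2, 3), c(2, 3, 3), c(3, 3, 3),
                 c(2, 2, 2, 2))
  for (sz in combos) {
    x <- sample(seq(1, 500, by = 3.7), sum(sz))
    g <- split(x, rep(seq_along(sz), sz))
    names(g) <- paste0("g", seq_along(sz))
    got <- rank_test(g, "kruskal_wallis")
    expect_equal(got$method, "exact enumeration")
    expect_equal(got$p_value, oracle_kw_exact(g),
                 label = paste("KW sizes", paste(sz, collapse = "/")))
  }
})

test_that("exact Friedman p-values match the enumeration oracle", {
  set.seed(13)
  for (nb in 2:3) {
    mat <- matrix(sample(seq(1, 90, by = 1.3), nb * 3), nrow = nb)
    g <- list(t1 = mat[, 1], t2 = mat[, 2], t3 = mat[, 3])
    got <- rank_test(g, "friedman")
    expect_equal(got$method, "exact enumeration")
    expect_equal(got$p_value, oracle_friedman_exact(mat),
                 label = paste("Friedman blocks", nb))
  }
})

test_that("large or tied samples fall back to tie-corrected asymptotics", {
  set.seed(14)
  a <- stats::rnorm(30); b <- stats::rnorm(30, 1)
  got <- rank_test(list(a = a, b = b), "mann_whitney")
  expect_equal(got$method, "asymptotic")
  expect_equal(got$p_value,
               stats::wilcox.test(a, b, exact = FALSE)$p.value)

  g3 <- list(a = c(1, 1, 2), b = c(2, 3, 3), c = c(4, 4, 5))
  got <- rank_test(g3, "kruskal_wallis")
  expect_equal(got$method, "asymptotic")
  ref <- stats::kruskal.test(unlist(g3),
                             factor(rep(1:3, each = 3)))
  expect_equal(got$statistic, unname(ref$statistic))
  expect_equal(got$p_value, ref$p.value)
})

test_that("post-hoc tables cover all pairs with Holm adjustment", {
  set.seed(15)
  g <- list(a = stats::rnorm(12), b = stats::rnorm(12, 2),
            c = stats::rnorm(12, 4))
  kw <- rank_test(g, "kruskal_wallis")
  expect_equal(nrow(kw$post_hoc), 3)
  expect_true(all(kw$post_hoc$adjustment == "holm"))
  expect_true(all(kw$post_hoc$p_adjusted >= kw$post_hoc$p))
  # the extreme pair separates most clearly
  ac <- kw$post_hoc$p_adjusted[kw$post_hoc$group1 == "a" &
                                 kw$post_hoc$group2 == "c"]
  expect_lt(ac, 0.05)
})

test_that("spearman correlation handles monotone and mixed rankings", {
  x <- 1:20
  expect_equal(spearman_correlation(x, x^3)$rho, 1)
  expect_equal(spearman_correlation(x, rev(x))$rho, -1)
  expect_equal(spearman_correlation(c(1, 2, 3), c(2, 1, 3))$rho, 0.5)
  expect_error(spearman_correlation(rep(1, 5), 1:5), "constant")
  expect_error(spearman_correlation(1:4, 1:5), "length")
})

test_that("gene association flags planted group differences only", {
  # constant gene: equal medians, no significant difference declared
  assoc <- gene_bin_association(rep(2, 30),
                                rep(c("low", "mid", "high"), 10))
  expect_true(all(assoc$summary$median == 2))
  expect_false(isTRUE(assoc$test$p_value < 0.05))

  # two groups with disjoint ranges: exact extreme-configuration p
  expr <- c(1:5, 101:105)
  grp <- rep(c("low", "high"), each = 5)
  assoc <- gene_bin_association(expr, grp)
  oracle <- stats::wilcox.test(expr[grp == "high"], expr[grp == "low"],
                               exact = TRUE)$p.value
  expect_equal(assoc$test$p_value, oracle)

  expect_error(gene_bin_association(1:4, rep("only", 4)), "2 non-empty")
})

test_that("planted JCHAIN shift appears in the CD19-low bin", {
  sim <- simulate_repertoire(sim_config(n_cells = 1200, seed = 21))
  z <- normalize_adt(sim$counts$CD19_ADT, sim$meta$batch)
  bins <- suppressWarnings(assign_bins(z, ids = sim$counts$barcode))
  assoc <- gene_bin_association(log1p(sim$counts$JCHAIN), bins)
  med <- stats::setNames(assoc$summary$median, assoc$summary$group)
  expect_gt(med["low"], med["high"])
  expect_lt(assoc$test$p_value, 0.05)
})
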