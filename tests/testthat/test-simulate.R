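test_that("mutate_sequence hits exactly the requested number of positions", {
  expect_identical(mutate_sequence("ATGCATGC", 0), "ATGCATGC")

  set.seed(1)
  full <- mutate_sequence("ATGCATGC", 8)
  expect_equal(sum(strsplit(full, "")[[1]] !=
                     strsplit("ATGCATGC", "")[[1]]), 8)

  germ <- strrep("A", 100)
  for (rep in 1:5) {
    mut <- mutate_sequence(germ, 3)
    expect_equal(sum(strsplit(mut, "")[[1]] != strsplit(germ, "")[[1]]), 3)
  }

  expect_error(mutate_sequence("ATGC", 5), "exceeds")
  expect_error(mutate_sequence("ATGN", 1), "alphabet")
})

test_that("mutate_sequence never touches protected positions", {
  set.seed(7)
  germ <- strrep("ACGT", 25)
  protect <- 11:40
  for (rep in 1:10) {
    mut <- mutate_sequence(germ, 20, protect = protect)
    expect_identical(substr(mut, 11, 40), substr(germ, 11, 40))
    expect_equal(sum(strsplit(mut, "")[[1]] != strsplit(germ, "")[[1]]), 20)
  }
  expect_error(mutate_sequence("ATGC", 3, protect = 1:2), "mutable")
})

test_that("sim_config validates fractions and probability tables", {
  expect_s3_class(sim_config(), "sim_config")
  expect_error(sim_config(origin_mix = 1.2), "fraction")
  expect_error(sim_config(vdj_dropout = -0.1), "fraction")
  bad <- default_isotype_probs()
  bad[1, 1] <- bad[1, 1] + 0.01
  expect_error(sim_config(isotype_probs = bad), "sum to 1")
  expect_error(sim_config(qc_fail_rates = c(mito = 0.5, rna = 0.4,
                                            lineage = 0.3)), "at most 1")
})

test_that("family plans respect origin mix and intraclonal scheme", {
  cfg <- tiny_config(n_cells = 200, origin_mix = 0,
                     clone_size_distribution = list(name = "zeta",
                                                    exponent = 2.5,
                                                    max_size = 1))
  set.seed(cfg$seed)
  plan <- sample_family_plan(cfg)
  expect_true(all(plan$size == 1))
  expect_true(all(plan$origin == "MBC"))
  expect_equal(sum(plan$size), 200)

  cfg <- tiny_config(n_cells = 400, origin_mix = 1)
  set.seed(cfg$seed)
  plan <- sample_family_plan(cfg)
  expect_true(all(plan$origin == "GC"))
  multi <- plan[plan$size >= 2, ]
  expect_gt(nrow(multi), 0)
  for (i in seq_len(nrow(multi)))
    expect_gte(length(unique(multi$private_mut[[i]])), 2)
  # MBC plans share one sequence: all private loads zero
  cfg <- tiny_config(n_cells = 400, origin_mix = 0)
  set.seed(cfg$seed)
  plan <- sample_family_plan(cfg)
  expect_true(all(vapply(plan$private_mut,
                         function(p) all(p == 0), TRUE)))
})

test_that("family plans are deterministic under a fixed seed", {
  cfg <- tiny_config(n_cells = 300)
  set.seed(99); p1 <- sample_family_plan(cfg)
  set.seed(99); p2 <- sample_family_plan(cfg)
  expect_identical(p1, p2)
})

test_that("simulated repertoires honor dropout and contamination settings", {
  sim <- simulate_repertoire(tiny_config(n_cells = 100, vdj_dropout = 0))
  expect_equal(nrow(sim$vdj), 100)

  sim <- simulate_repertoire(tiny_config(n_cells = 150, ambient_rate = 0))
  genes <- intersect(colnames(sim$counts),
                     c("IGHM", "IGHD", "IGHG1", "IGHG2", "IGHG3", "IGHG4",
                       "IGHA1", "IGHA2", "IGHE"))
  mat <- as.matrix(sim$counts[, genes])
  truth_gene <- names(bmpcrep:::subclass_labels())[
    match(sim$truth_cells$isotype_subclass,
          bmpcrep:::subclass_labels())]
  for (i in seq_len(nrow(mat))) {
    off <- mat[i, setdiff(genes, truth_gene[i])]
    expect_true(all(off == 0))
  }
})

test_that("per-cell realized SHM equals planted mutations exactly", {
  sim <- simulate_repertoire(tiny_config(n_cells = 200, vdj_dropout = 0))
  realized <- compute_shm(sim$vdj$sequence, sim$vdj$germline_alignment)
  planted <- sim$truth_cells$shm_true[match(sim$vdj$cell_id,
                                            sim$truth_cells$barcode)]
  expect_equal(realized, planted, tolerance = 1e-12)
})

test_that("planted CD19 shift is recovered from truth labels", {
  cfg <- sim_config(n_cells = 2000, cd19_effect = 1.5, seed = 11)
  sim <- simulate_repertoire(cfg)
  z <- normalize_adt(sim$counts$CD19_ADT, sim$meta$batch)
  gc <- sim$truth_cells$origin == "GC"
  diff <- mean(z[gc]) - mean(z[!gc])
  expect_lt(abs(diff - 1.5), 0.15)
})

test_that("planted SHM and JCHAIN effects are recovered within 3 SE", {
  cfg <- sim_config(n_cells = 1500, seed = 5)
  sim <- simulate_repertoire(cfg)
  tc <- sim$truth_cells
  mbc <- tc$origin == "MBC"
  # SHM: per-clone targets are drawn around the origin means
  cl <- sim$truth_clones
  for (org in c("MBC", "GC")) {
    x <- cl$target_shm[cl$origin == org]
    mu <- if (org == "GC") cfg$shm_gc_mean else cfg$shm_mbc_mean
    se <- stats::sd(x) / sqrt(length(x))
    # truncation at zero pulls the realized mean slightly up
    expect_lt(abs(mean(x) - mu), 3 * se + 0.2)
  }
  # JCHAIN: log-scale shift between origins
  jl <- log1p(sim$counts$JCHAIN)
  d <- mean(jl[mbc]) - mean(jl[!mbc])
  se <- sqrt(stats::var(jl[mbc]) / sum(mbc) +
               stats::var(jl[!mbc]) / sum(!mbc))
  expect_lt(abs(d - cfg$jchain_effect), 3 * se + 0.1)
})

test_that("identical config and seed give byte-identical outputs", {
  cfg <- tiny_config(n_cells = 120)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_simulation(simulate_repertoire(cfg), d1)
  write_simulation(simulate_repertoire(cfg), d2)
  for (f in list.files(d1)) {
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))),
                     label = f)
  }
})

test_that("planted QC failures appear at the configured rates", {
  cfg <- tiny_config(n_cells = 1000,
                     qc_fail_rates = c(mito = 0.05, rna = 0.05,
                                       lineage = 0.05))
  sim <- simulate_repertoire(cfg)
  cells <- dplyr::inner_join(sim$meta, sim$counts, by = "barcode")
  qc <- qc_filter(cells)
  expect_equal(unname(qc$removal_counts["mito"]), 50)
  expect_equal(unname(qc$removal_counts["rna"]), 50)
  expect_equal(unname(qc$removal_counts["lineage"]), 50)
  expect_equal(nrow(qc$retained), 850)
})

test_that("every barcode appears exactly once in the truth table", {
  sim <- simulate_repertoire(tiny_config(n_cells = 250))
  expect_equal(sort(sim$truth_cells$barcode), sort(sim$counts$barcode))
  expect_false(anyDuplicated(sim$truth_cells$barcode) > 0)
  # clone members agree with the per-clone truth
  sizes <- table(sim$truth_cells$clone_id)
  expect_equal(as.integer(sizes[sim$truth_clones$clone_id]),
               sim$truth_clones$size)
})
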