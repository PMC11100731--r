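test_that("structure labels follow the size/uniqueness definition", {
  expect_equal(classify_clone_structure("ATGC"), "singlet")
  expect_equal(classify_clone_structure(rep("ATGC", 3)), "isogenic")
  expect_equal(classify_clone_structure(c("ATGC", "ATGA")), "heterogenic")
  expect_warning(lab <- classify_clone_structure(c("ATGC", NA)),
                 "without a sequence")
  expect_equal(lab, "singlet")
  expect_error(suppressWarnings(classify_clone_structure(NA_character_)),
               "no sequenced members")
})

test_that("family CD19 composition applies the strict 30% rule", {
  comp <- family_cd19_composition(c(rep("low", 4), rep("mid", 4),
                                    rep("high", 2)))
  expect_equal(unname(comp$fractions), c(0.4, 0.4, 0.2))
  expect_equal(comp$predominant, "low")

  # 0.30 is not strictly greater than 0.30
  comp <- family_cd19_composition(c(rep("low", 3), rep("mid", 4),
                                    rep("high", 3)))
  expect_equal(comp$predominant, "neither")

  comp <- family_cd19_composition(rep("high", 6))
  expect_equal(comp$predominant, "high")

  expect_error(family_cd19_composition(character(0)), "binned member")
})

fam_tbl <- function(medians, structure = "heterogenic", size = 6) {
  tibble::tibble(clone_id = sprintf("C%02d", seq_along(medians)),
                 structure = structure, size = size,
                 median_shm = medians,
                 frac_cd19_high = 0.5)
}

test_that("extreme-family selection ranks by median SHM with stable ties", {
  fams <- fam_tbl(c(1, 5, 9))
  ext <- select_extreme_families(fams, k = 1, min_size = 5)
  expect_equal(ext$most_mutated$median_shm, 9)
  expect_equal(ext$least_mutated$median_shm, 1)

  expect_warning(ext <- select_extreme_families(fams, k = 5, min_size = 5),
                 "overlap")
  expect_equal(nrow(ext$most_mutated), 3)
  expect_equal(nrow(ext$least_mutated), 3)

  tied <- fam_tbl(c(4, 4))
  ext <- suppressWarnings(select_extreme_families(tied, k = 1))
  expect_equal(ext$most_mutated$clone_id, "C01")  # tie broken by clone_id
  expect_equal(ext$least_mutated$clone_id, "C01")

  small <- fam_tbl(c(1, 2), size = 3)
  expect_error(select_extreme_families(small, k = 1, min_size = 5),
               "size >= 5")
})

test_that("structure-isotype tables are row-normalized with counts kept", {
  cells <- tibble::tibble(
    structure = c("singlet", "singlet", "singlet", "singlet"),
    isotype_class = c("IgG", "IgG", "IgM", "IgM"))
  tab <- structure_isotype_frequencies(cells)
  expect_equal(tab$fraction, c(0.5, 0.5))
  expect_equal(sum(tab$n), 4)

  allA <- tibble::tibble(structure = c("singlet", "isogenic"),
                         isotype_class = "IgA")
  tab <- structure_isotype_frequencies(allA)
  expect_true(all(tab$fraction == 1))

  expect_error(structure_isotype_frequencies(cells[0, ]), "empty")
  expect_error(structure_isotype_frequencies(
    tibble::tibble(structure = "singlet", isotype_class = NA)), "needs")
})

test_that("clone summaries reconcile sizes and respect barcode relabeling", {
  sim <- simulate_repertoire(tiny_config(n_cells = 400, vdj_dropout = 0))
  cl <- cluster_clones(sim$vdj)
  cells <- tibble::tibble(
    barcode = cl$barcode, clone_id = cl$clone_id,
    sequence = sim$vdj$sequence[match(cl$barcode, sim$vdj$cell_id)],
    shm_percent = compute_shm(sim$vdj$sequence,
                              sim$vdj$germline_alignment)[
                                match(cl$barcode, sim$vdj$cell_id)])
  fams <- summarize_clones(cells)
  expect_equal(sum(fams$size), nrow(cells))
  expect_true(all(fams$unique_sequences <= fams$size))
  expect_true(all(fams$size >= 1))
  expect_true(all((fams$structure == "singlet") == (fams$size == 1)))
  expect_true(all((fams$structure == "isogenic") ==
                    (fams$size >= 2 & fams$unique_sequences == 1)))
  expect_true(all((fams$structure == "heterogenic") ==
                    (fams$size >= 2 & fams$unique_sequences >= 2)))

  # relabeling barcodes changes no structure label
  relabeled <- cells
  relabeled$barcode <- paste0("X", rev(cells$barcode))
  fams2 <- summarize_clones(relabeled)
  expect_equal(fams2$structure[match(fams$clone_id, fams2$clone_id)],
               fams$structure)
})

test_that("multi-cell GC clones are heterogenic, MBC clones isogenic", {
  sim <- simulate_repertoire(tiny_config(n_cells = 800, vdj_dropout = 0))
  shm <- compute_shm(sim$vdj$sequence, sim$vdj$germline_alignment)
  cells <- tibble::tibble(
    barcode = sim$vdj$cell_id,
    clone_id = sim$truth_cells$clone_id[match(sim$vdj$cell_id,
                                              sim$truth_cells$barcode)],
    sequence = sim$vdj$sequence, shm_percent = shm)
  fams <- summarize_clones(cells)
  truth <- sim$truth_clones
  got <- fams$structure[match(truth$clone_id, fams$clone_id)]
  expect_equal(got, truth$structure)
})
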