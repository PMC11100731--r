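with_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    stop("stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
}

#' Run the BMPC repertoire analysis on in-memory tables
#'
#' Executes the full analysis in stage order: quality control, combined
#' GEX/VDJ isotype assignment (cells without a confident isotype are
#' discarded), SHM quantification and clonal clustering, CD19/SHM
#' binning, clonal-structure classification, and the rank-statistics
#' battery (SHM across CD19 bins, CD19 across SHM bins, structure SHM,
#' heterogenic-clone frequency by bin, per-donor isotype frequencies
#' across bins, CD19-SHM correlation, association-gene tests, and
#' extreme-family compositions). Any stage failure aborts with the stage
#' name.
#'
#' @param vdj AIRR tibble (as from [read_airr()] or
#'   [simulate_repertoire()]).
#' @param counts Cell-by-feature tibble keyed by `barcode`.
#' @param meta Per-cell metadata tibble (`barcode`, `donor`, `batch`,
#'   `allergy_status`, `mito_fraction`, `total_rna`).
#' @param params A [pipeline_config()] object.
#' @return A list with `per_cell` (assignment table), `clones`
#'   (per-family table), `stat_tests` (one row per statistical test),
#'   `tables` (auxiliary composition tables), `tests` (the full
#'   [rank_test()] objects, keyed by analysis name) and `params`.
#' @export
analyze_repertoire <- function(vdj, counts, meta,
                               params = pipeline_config()) {
  stopifnot(inherits(params, "pipeline_config"))

  cells <- with_stage("qc", {
    stopifnot("barcode" %in% names(counts), "barcode" %in% names(meta))
    dplyr::inner_join(meta, counts, by = "barcode")
  })
  qc <- with_stage("qc", qc_filter(cells, mito_max = params$mito_max,
                                   rna_min = params$rna_min,
                                   rna_max = params$rna_max))

  iso <- with_stage("isotype", {
    assign_isotypes(qc$retained, vdj = vdj,
                    majority_fraction = params$majority_fraction,
                    min_counts = params$min_counts)
  })
  # cells without a confident isotype are discarded from the analysis
  kept <- qc$retained[iso$provenance != "none", , drop = FALSE]
  iso_kept <- iso[iso$provenance != "none", , drop = FALSE]

  clono <- with_stage("clonotyping", {
    if (is.null(vdj)) stop("no VDJ table supplied")
    v <- vdj[vdj$cell_id %in% kept$barcode, , drop = FALSE]
    cl <- cluster_clones(v, cutoff = params$distance_cutoff,
                         semantics = params$distance_semantics)
    cl$shm_percent <- NA_real_
    have <- !is.na(v$sequence) & !is.na(v$germline_alignment)
    cl$shm_percent[have] <- compute_shm(v$sequence[have],
                                        v$germline_alignment[have])
    cl$sequence <- v$sequence
    cl
  })

  binned <- with_stage("binning", {
    out <- tibble::tibble(barcode = kept$barcode,
                          cd19_z = NA_real_,
                          cd19_bin = NA_character_,
                          shm_bin = NA_character_)
    if (params$cd19_feature %in% names(kept)) {
      out$cd19_z <- normalize_adt(kept[[params$cd19_feature]],
                                  kept$batch)
      out$cd19_bin <- assign_bins(out$cd19_z,
                                  fractions = params$bin_fractions,
                                  ids = out$barcode)
    }
    shm <- clono$shm_percent[match(out$barcode, clono$barcode)]
    with_shm <- !is.na(shm)
    if (sum(with_shm) >= 3)
      out$shm_bin[with_shm] <- assign_bins(
        shm[with_shm], fractions = params$bin_fractions,
        ids = out$barcode[with_shm])
    out
  })

  per_cell <- with_stage("structure", {
    pc <- tibble::tibble(barcode = cells$barcode) |>
      dplyr::left_join(qc$flags, by = "barcode") |>
      dplyr::left_join(meta[, intersect(c("barcode", "donor", "batch",
                                          "allergy_status"),
                                        names(meta))], by = "barcode") |>
      dplyr::left_join(iso, by = "barcode") |>
      dplyr::left_join(clono[, c("barcode", "clone_id", "shm_percent",
                                 "sequence")], by = "barcode") |>
      dplyr::left_join(binned, by = "barcode")
    pc$isotype_subclass[!pc$qc_pass] <- NA_character_
    pc
  })

  clones <- with_stage("structure", {
    cc <- per_cell[!is.na(per_cell$clone_id), , drop = FALSE]
    summarize_clones(cc)
  })
  per_cell$structure <- clones$structure[match(per_cell$clone_id,
                                               clones$clone_id)]

  stats_out <- with_stage("stats",
                          run_stats_battery(per_cell, kept, clones,
                                            params))

  list(per_cell = per_cell[, setdiff(names(per_cell), "sequence")],
       clones = clones, stat_tests = stats_out$stat_tests,
       tables = stats_out$tables, tests = stats_out$tests,
       params = params)
}

# the rank-statistics battery over the assembled per-cell table
run_stats_battery <- function(per_cell, kept, clones, params) {
  tests <- list()
  tables <- list()

  ok <- per_cell[!is.na(per_cell$shm_percent), , drop = FALSE]
  bin_levels <- c("low", "mid", "high")

  grp <- function(values, labels, levels) {
    keep <- !is.na(values) & !is.na(labels)
    split(values[keep], factor(labels[keep], levels = levels))
  }

  g <- grp(ok$shm_percent, ok$cd19_bin, bin_levels)
  if (all(lengths(g) > 0))
    tests$shm_by_cd19_bin <- rank_test(g, "kruskal_wallis")

  g <- grp(ok$cd19_z, ok$shm_bin, bin_levels)
  if (all(lengths(g) > 0))
    tests$cd19_by_shm_bin <- rank_test(g, "kruskal_wallis")

  g <- grp(ok$shm_percent, ok$structure,
           c("singlet", "isogenic", "heterogenic"))
  if (all(lengths(g) > 0))
    tests$shm_by_structure <- rank_test(g, "kruskal_wallis")

  # heterogenic-clone frequency per CD19 bin, donors as replicates
  het <- ok[!is.na(ok$cd19_bin) & !is.na(ok$structure), , drop = FALSE]
  if (nrow(het)) {
    freq <- het |>
      dplyr::group_by(.data$donor, .data$cd19_bin) |>
      dplyr::summarise(frac_heterogenic =
                         mean(.data$structure == "heterogenic"),
                       n = dplyr::n(), .groups = "drop")
    tables$heterogenic_freq_by_bin <- freq
    g <- split(freq$frac_heterogenic,
               factor(freq$cd19_bin, levels = bin_levels))
    if (all(lengths(g) >= 2))
      tests$heterogenic_freq_by_bin <- rank_test(g, "kruskal_wallis")
  }

  # SHM-bin composition of each CD19 bin
  both <- ok[!is.na(ok$cd19_bin) & !is.na(ok$shm_bin), , drop = FALSE]
  if (nrow(both))
    tables$shm_bin_by_cd19_bin <- both |>
      dplyr::count(.data$cd19_bin, .data$shm_bin, name = "n") |>
      dplyr::group_by(.data$cd19_bin) |>
      dplyr::mutate(fraction = .data$n / sum(.data$n)) |>
      dplyr::ungroup()

  # per-donor isotype frequency across CD19 bins (Friedman, donors as
  # blocks), for the classes tracked across bins
  iso_bin <- per_cell[!is.na(per_cell$cd19_bin) &
                        !is.na(per_cell$isotype_subclass), , drop = FALSE]
  if (nrow(iso_bin)) {
    for (iso in c("IgM", "IgG1", "IgA1")) {
      wide <- iso_bin |>
        dplyr::group_by(.data$donor, .data$cd19_bin) |>
        dplyr::summarise(frac = mean(.data$isotype_subclass == iso |
                                       .data$isotype_class == iso),
                         .groups = "drop") |>
        tidyr::pivot_wider(names_from = "cd19_bin",
                           values_from = "frac")
      complete <- stats::complete.cases(wide[, bin_levels])
      wide <- wide[complete, , drop = FALSE]
      if (nrow(wide) >= 2) {
        g <- as.list(wide[, bin_levels])
        tests[[paste0("isotype_", iso, "_by_cd19_bin")]] <-
          rank_test(g, "friedman")
      }
    }
    tables$isotype_by_cd19_bin <- iso_bin |>
      dplyr::count(.data$cd19_bin, .data$isotype_class, name = "n") |>
      dplyr::group_by(.data$cd19_bin) |>
      dplyr::mutate(fraction = .data$n / sum(.data$n)) |>
      dplyr::ungroup()
  }

  # CD19-SHM correlation
  cor_ok <- ok[!is.na(ok$cd19_z), , drop = FALSE]
  if (nrow(cor_ok) >= 3 && stats::sd(cor_ok$shm_percent) > 0) {
    sp <- spearman_correlation(cor_ok$cd19_z, cor_ok$shm_percent)
    tests$cd19_shm_spearman <- structure(list(
      kind = "spearman", method = "asymptotic",
      groups = tibble::tibble(label = "cells", n = nrow(cor_ok)),
      statistic = sp$rho, p_value = sp$p, post_hoc = NULL),
      class = "rank_test")
  }

  # association gene across CD19 bins and clone structures
  gene <- params$association_gene
  if (gene %in% names(kept)) {
    expr <- log1p(kept[[gene]])
    cd19_bin <- per_cell$cd19_bin[match(kept$barcode, per_cell$barcode)]
    if (sum(!is.na(cd19_bin)) >= 6) {
      assoc <- gene_bin_association(expr, cd19_bin)
      tests[[paste0(tolower(gene), "_by_cd19_bin")]] <- assoc$test
      tables[[paste0(tolower(gene), "_by_cd19_bin_summary")]] <-
        assoc$summary
    }
    structure_lab <- per_cell$structure[match(kept$barcode,
                                              per_cell$barcode)]
    if (length(unique(stats::na.omit(structure_lab))) >= 2) {
      assoc <- gene_bin_association(expr, structure_lab)
      tests[[paste0(tolower(gene), "_by_structure")]] <- assoc$test
      tables[[paste0(tolower(gene), "_by_structure_summary")]] <-
        assoc$summary
    }
  }

  # isotype composition by clone structure
  sc <- per_cell[!is.na(per_cell$structure) &
                   !is.na(per_cell$isotype_class), , drop = FALSE]
  if (nrow(sc))
    tables$structure_isotype <- structure_isotype_frequencies(sc)

  # extreme heterogenic families: predominant-CD19 calls and the
  # CD19-high fraction contrast between most and least mutated
  n_eligible <- sum(clones$structure == "heterogenic" &
                      clones$size >= params$family_min_size)
  for (k in params$extreme_family_k) {
    if (n_eligible == 0) break
    ext <- suppressWarnings(
      select_extreme_families(clones, k = k,
                              min_size = params$family_min_size))
    tab <- dplyr::bind_rows(
      dplyr::mutate(ext$most_mutated, extreme = "most_mutated"),
      dplyr::mutate(ext$least_mutated, extreme = "least_mutated"))
    tables[[paste0("extreme_families_k", k)]] <- tab
    g <- list(most = ext$most_mutated$frac_cd19_high,
              least = ext$least_mutated$frac_cd19_high)
    g <- lapply(g, function(x) x[!is.na(x)])
    if (all(lengths(g) >= 2))
      tests[[paste0("cd19_high_extreme_k", k)]] <-
        rank_test(g, "mann_whitney")
  }

  # isotype composition by donor allergy status
  if ("allergy_status" %in% names(per_cell)) {
    ia <- per_cell[!is.na(per_cell$isotype_subclass), , drop = FALSE]
    if (nrow(ia))
      tables$isotype_by_allergy <- ia |>
        dplyr::count(.data$isotype_subclass, .data$allergy_status,
                     name = "n") |>
        dplyr::group_by(.data$isotype_subclass) |>
        dplyr::mutate(fraction = .data$n / sum(.data$n)) |>
        dplyr::ungroup()
  }

  stat_tests <- dplyr::bind_rows(lapply(names(tests), function(nm) {
    t <- tests[[nm]]
    tibble::tibble(analysis = nm, kind = t$kind, method = t$method,
                   n_groups = nrow(t$groups),
                   n_total = sum(t$groups$n),
                   statistic = t$statistic, p_value = t$p_value)
  }))
  list(stat_tests = stat_tests, tables = tables, tests = tests)
}

#' Run the full pipeline from files
#'
#' Reads the VDJ, counts and metadata inputs named in the configuration,
#' runs [analyze_repertoire()], and (if `outdir` is set) writes all
#' result tables and the run manifest.
#'
#' @param params A [pipeline_config()] with input paths set, or the path
#'   to a YAML configuration file.
#' @return The [analyze_repertoire()] result list, invisibly.
#' @export
run_pipeline <- function(params) {
  if (is.character(params)) params <- read_pipeline_config(params)
  stopifnot(inherits(params, "pipeline_config"))
  for (f in c("vdj_path", "counts_path", "meta_path")) {
    if (is.null(params[[f]]) || !file.exists(params[[f]]))
      stop("stage 'input' failed: ", f, " (",
           if (is.null(params[[f]])) "unset" else params[[f]],
           ") is required; clonotyping and binning need all three inputs",
           call. = FALSE)
  }
  vdj <- with_stage("input", read_airr(params$vdj_path))
  counts <- with_stage("input", read_count_matrix(params$counts_path))
  meta <- with_stage("input", readr::read_tsv(
    params$meta_path, col_types = readr::cols(
      barcode = readr::col_character(),
      donor = readr::col_character(),
      batch = readr::col_character(),
      .default = readr::col_guess())))
  res <- analyze_repertoire(vdj, counts, meta, params)
  if (!is.null(params$outdir)) write_results(res, params$outdir)
  invisible(res)
}

#' @rdname rank_test
#' @param x A `rank_test` object.
#' @param ... Unused.
#' @method print rank_test
#' @export
print.rank_test <- function(x, ...) {
  cat(sprintf("%s (%s): statistic = %.4g, p = %.4g\n", x$kind, x$method,
              x$statistic, x$p_value))
  cat("groups:", paste(sprintf("%s (n=%d)", x$groups$label, x$groups$n),
                       collapse = ", "), "\n")
  if (!is.null(x$post_hoc)) {
    cat("post hoc (", x$post_hoc$adjustment[1], "-adjusted):\n",
        sep = "")
    print(as.data.frame(x$post_hoc[, c("group1", "group2", "statistic",
                                       "p_adjusted")]), row.names = FALSE)
  }
  invisible(x)
}
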