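#' Cell-level quality-control filter
#'
#' Retains cells with mitochondrial fraction below `mito_max`, total RNA
#' count within `[rna_min, rna_max]`, and zero counts of every
#' lineage-marker gene (T/NK/myeloid/erythroid contaminants). Removed
#' cells are attributed to the *first* failing rule in the fixed order
#' mito, rna, lineage.
#'
#' @param cells Tibble with columns `barcode`, `mito_fraction`,
#'   `total_rna`, and one column per lineage gene present in the data.
#' @param mito_max Maximum mitochondrial fraction, exclusive (default
#'   0.05: cells with less than 5% mitochondrial expression pass).
#' @param rna_min,rna_max Inclusive bounds on total RNA count (defaults
#'   200 and 4000).
#' @param lineage Character vector of lineage-marker genes; genes absent
#'   from `cells` are ignored.
#' @return A list with `retained` (the passing subset), `flags` (per-cell
#'   tibble `barcode`, `qc_pass`, `failing_rule`) and `removal_counts`
#'   (named counts for mito, rna, lineage).
#' @export
qc_filter <- function(cells, mito_max = 0.05, rna_min = 200,
                      rna_max = 4000, lineage = lineage_genes()) {
  stopifnot(all(c("barcode", "mito_fraction", "total_rna") %in%
                  names(cells)))
  if (mito_max <= 0 || rna_min <= 0 || rna_max < rna_min)
    stop("qc_filter: thresholds must be positive with rna_min <= rna_max")
  lin_present <- intersect(lineage, names(cells))
  lin_pos <- if (length(lin_present))
    rowSums(as.matrix(cells[, lin_present, drop = FALSE]) > 0) > 0
  else rep(FALSE, nrow(cells))

  fail_mito <- cells$mito_fraction >= mito_max
  fail_rna <- cells$total_rna < rna_min | cells$total_rna > rna_max
  failing_rule <- rep(NA_character_, nrow(cells))
  failing_rule[lin_pos] <- "lineage"
  failing_rule[fail_rna] <- "rna"
  failing_rule[fail_mito] <- "mito"   # first in precedence order wins
  qc_pass <- is.na(failing_rule)

  list(
    retained = cells[qc_pass, , drop = FALSE],
    flags = tibble::tibble(barcode = cells$barcode, qc_pass = qc_pass,
                           failing_rule = failing_rule),
    removal_counts = c(mito = sum(failing_rule == "mito", na.rm = TRUE),
                       rna = sum(failing_rule == "rna", na.rm = TRUE),
                       lineage = sum(failing_rule == "lineage",
                                     na.rm = TRUE))
  )
}

subclass_labels <- function() {
  stats::setNames(
    c("IgM", "IgD", "IgG3", "IgG1", "IgA1", "IgG2", "IgG4", "IgE", "IgA2"),
    ighc_genes()
  )
}

subclass_of_gene <- function(gene) {
  unname(subclass_labels()[gene])
}

class_of_subclass <- function(subclass) {
  ifelse(is.na(subclass), NA_character_, sub("[0-9]+$", "", subclass))
}

#' Assign a heavy-chain isotype to one cell
#'
#' VDJ information takes precedence: a cell with a constant-region call in
#' its VDJ record is assigned that subclass (provenance `"VDJ"`).
#' Otherwise the cell's IGHC transcript counts are used: the top subclass
#' is assigned (provenance `"GEX"`) if and only if it holds strictly more
#' than `majority_fraction` of the summed IGHC counts *and* strictly more
#' than `min_counts` counts. Ties for the top subclass, or failure of
#' either rule, leave the cell unassigned (provenance `"none"`).
#'
#' @param ighc_counts Named numeric vector of IGHC subclass gene counts
#'   (missing genes are treated as zero).
#' @param c_call Optional constant-region call (e.g. `"IGHG1"` or
#'   `"IGHG1*01"`); `NULL` or `NA` means no VDJ isotype information.
#' @param majority_fraction Required share of summed IGHC counts, strict
#'   (default 0.5: "more than half").
#' @param min_counts Required count of the top subclass, strict (default
#'   20: "more than 20 counts").
#' @return A list with `subclass`, `class` and `provenance`.
#' @export
assign_isotype <- function(ighc_counts, c_call = NULL,
                           majority_fraction = 0.5, min_counts = 20) {
  if (!is.null(c_call) && length(c_call) == 1 && !is.na(c_call) &&
      nzchar(c_call)) {
    gene <- toupper(sub("\\*.*$", "", c_call))
    if (!gene %in% ighc_genes())
      stop("assign_isotype: unknown constant-region call '", c_call,
           "'; accepted: ", paste(ighc_genes(), collapse = ", "))
    sub <- subclass_of_gene(gene)
    return(list(subclass = sub, class = class_of_subclass(sub),
                provenance = "VDJ"))
  }
  counts <- stats::setNames(rep(0, length(ighc_genes())), ighc_genes())
  common <- intersect(names(ighc_counts), ighc_genes())
  counts[common] <- ighc_counts[common]
  total <- sum(counts)
  unassigned <- list(subclass = NA_character_, class = NA_character_,
                     provenance = "none")
  if (total == 0) return(unassigned)
  top <- max(counts)
  if (sum(counts == top) > 1) return(unassigned)   # argmax tie
  if (top / total > majority_fraction && top > min_counts) {
    gene <- names(counts)[which.max(counts)]
    sub <- subclass_of_gene(gene)
    list(subclass = sub, class = class_of_subclass(sub), provenance = "GEX")
  } else unassigned
}

#' Assign isotypes to a table of cells
#'
#' Vectorized wrapper over [assign_isotype()]: joins cells to their VDJ
#' constant-region calls by barcode and applies the combined GEX/VDJ rule
#' to every cell.
#'
#' @param cells Tibble with `barcode` and IGHC subclass gene columns.
#' @param vdj Optional AIRR tibble with `cell_id` and `c_call`.
#' @param majority_fraction,min_counts Rule thresholds, see
#'   [assign_isotype()].
#' @return Tibble `barcode`, `isotype_subclass`, `isotype_class`,
#'   `provenance`.
#' @export
assign_isotypes <- function(cells, vdj = NULL, majority_fraction = 0.5,
                            min_counts = 20) {
  stopifnot("barcode" %in% names(cells))
  ccall <- rep(NA_character_, nrow(cells))
  if (!is.null(vdj) && nrow(vdj)) {
    idx <- match(cells$barcode, vdj$cell_id)
    ccall <- vdj$c_call[idx]
  }
  genes <- intersect(ighc_genes(), names(cells))
  mat <- as.matrix(cells[, genes, drop = FALSE])
  out <- lapply(seq_len(nrow(cells)), function(i) {
    assign_isotype(mat[i, ], c_call = ccall[i],
                   majority_fraction = majority_fraction,
                   min_counts = min_counts)
  })
  tibble::tibble(
    barcode = cells$barcode,
    isotype_subclass = vapply(out, `[[`, "", "subclass"),
    isotype_class = vapply(out, `[[`, "", "class"),
    provenance = vapply(out, `[[`, "", "provenance")
  )
}

#' Benchmark GEX-only isotype inference against VDJ truth
#'
#' For every cell that has a VDJ constant-region call, recomputes the
#' isotype from IGHC counts alone (ignoring the VDJ record) and compares
#' it with the VDJ subclass. Cells the GEX rule leaves unassigned are
#' tabulated separately and are not counted as errors.
#'
#' @param cells Tibble with `barcode` and IGHC subclass gene columns.
#' @param vdj AIRR tibble with `cell_id` and `c_call`; only cells present
#'   here are benchmarked.
#' @param majority_fraction,min_counts GEX rule thresholds, see
#'   [assign_isotype()].
#' @return A list with `overall` (one-row tibble: `n`, `n_gex_assigned`,
#'   `n_correct`, `accuracy` = correct/assigned, `assigned_rate`,
#'   `correct_rate` = correct/all benchmarked) and `per_subclass`
#'   (per-VDJ-subclass `n`, `n_assigned`, `n_correct`, `accuracy`, and
#'   `precision` of the GEX calls for that subclass). Rates are percent.
#' @export
benchmark_isotype_inference <- function(cells, vdj,
                                        majority_fraction = 0.5,
                                        min_counts = 20) {
  keep <- vdj[!is.na(vdj$c_call) & nzchar(vdj$c_call), ]
  cells <- cells[cells$barcode %in% keep$cell_id, , drop = FALSE]
  if (nrow(cells) == 0)
    stop("benchmark_isotype_inference: no cells with both GEX counts and ",
         "a VDJ constant-region call")
  truth_gene <- toupper(sub("\\*.*$", "",
                            keep$c_call[match(cells$barcode,
                                              keep$cell_id)]))
  truth <- subclass_of_gene(truth_gene)
  gex <- assign_isotypes(cells, vdj = NULL,
                         majority_fraction = majority_fraction,
                         min_counts = min_counts)
  assigned <- gex$provenance == "GEX"
  correct <- assigned & gex$isotype_subclass == truth

  overall <- tibble::tibble(
    n = nrow(cells),
    n_gex_assigned = sum(assigned),
    n_correct = sum(correct),
    accuracy = if (sum(assigned)) 100 * sum(correct) / sum(assigned)
               else NA_real_,
    assigned_rate = 100 * sum(assigned) / nrow(cells),
    correct_rate = 100 * sum(correct) / nrow(cells)
  )
  per <- tibble::tibble(subclass = truth, assigned = assigned,
                        call = gex$isotype_subclass, correct = correct) |>
    dplyr::group_by(.data$subclass) |>
    dplyr::summarise(
      n = dplyr::n(), n_assigned = sum(.data$assigned),
      n_correct = sum(.data$correct),
      accuracy = ifelse(sum(.data$assigned) > 0,
                        100 * sum(.data$correct) / sum(.data$assigned),
                        NA_real_),
      .groups = "drop")
  calls <- gex$isotype_subclass[assigned]
  tr <- truth[assigned]
  per$precision <- vapply(per$subclass, function(s) {
    called <- calls == s
    if (!sum(called)) return(NA_real_)
    100 * sum(tr[called] == s) / sum(called)
  }, 0)
  list(overall = overall, per_subclass = per)
}
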