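airr_required_cols <- c("cell_id", "v_call", "j_call", "junction_aa",
                        "sequence", "germline_alignment")

#' Read an AIRR-dialect rearrangement table
#'
#' Reads a tab-separated rearrangement file with AIRR Rearrangement
#' column names (`cell_id`, `v_call`, `j_call`, `junction_aa`,
#' `sequence`, `germline_alignment`, optional `c_call`). Rows missing a
#' CDR3 or a V/J call are retained but flagged incomplete; row order is
#' preserved.
#'
#' @param path Path to the TSV file.
#' @return A tibble with the input columns plus a logical `complete`
#'   column.
#' @export
read_airr <- function(path) {
  tab <- readr::read_tsv(path, col_types = readr::cols(
    .default = readr::col_character()))
  missing <- setdiff(airr_required_cols, names(tab))
  if (length(missing))
    stop("read_airr: missing required column(s): ",
         paste(missing, collapse = ", "))
  if (!"c_call" %in% names(tab)) tab$c_call <- NA_character_
  tab$complete <- !is.na(tab$junction_aa) & nzchar(tab$junction_aa) &
    !is.na(tab$v_call) & nzchar(tab$v_call) &
    !is.na(tab$j_call) & nzchar(tab$j_call)
  tab
}

#' Read a cell-by-feature count table
#'
#' Accepts either a dense delimited table (first column `barcode`,
#' remaining columns features) or a matrix-market triplet (`.mtx` file in
#' features x cells orientation with sibling `features.tsv` and
#' `barcodes.tsv` single-column files, overridable). Both forms of the
#' same data yield the identical cell table.
#'
#' @param path Path to the dense TSV or to the `.mtx` file.
#' @param features_path,barcodes_path Sidecar paths for the triplet form;
#'   default to `features.tsv` / `barcodes.tsv` next to the `.mtx`.
#' @return A tibble keyed by unique `barcode` with one numeric column per
#'   feature.
#' @export
read_count_matrix <- function(path, features_path = NULL,
                              barcodes_path = NULL) {
  if (grepl("\\.mtx$", path)) {
    if (is.null(features_path))
      features_path <- file.path(dirname(path), "features.tsv")
    if (is.null(barcodes_path))
      barcodes_path <- file.path(dirname(path), "barcodes.tsv")
    m <- Matrix::readMM(path)
    features <- readr::read_tsv(features_path, col_names = "feature",
                                col_types = "c")$feature
    barcodes <- readr::read_tsv(barcodes_path, col_names = "barcode",
                                col_types = "c")$barcode
    if (nrow(m) != length(features) || ncol(m) != length(barcodes))
      stop("read_count_matrix: matrix dimensions do not match feature/",
           "barcode lists")
    dense <- as.matrix(Matrix::t(m))
    colnames(dense) <- features
    tab <- tibble::as_tibble(dense)
    tab <- tibble::add_column(tab, barcode = barcodes, .before = 1)
  } else {
    tab <- readr::read_tsv(path, col_types = readr::cols(
      barcode = readr::col_character(), .default = readr::col_double()))
    if (!"barcode" %in% names(tab))
      stop("read_count_matrix: dense table must have a 'barcode' column")
  }
  dup <- tab$barcode[duplicated(tab$barcode)]
  if (length(dup))
    stop("read_count_matrix: duplicate barcode(s): ",
         paste(unique(dup), collapse = ", "))
  tab
}

#' Look up a feature column
#'
#' @param cells Cell table from [read_count_matrix()].
#' @param name Feature name.
#' @param missing_as_zero If `TRUE`, an absent feature is read as all
#'   zeros instead of raising an error.
#' @return Numeric vector of per-cell values.
#' @export
get_feature <- function(cells, name, missing_as_zero = FALSE) {
  if (name %in% names(cells)) return(cells[[name]])
  if (missing_as_zero) return(rep(0, nrow(cells)))
  stop("get_feature: feature '", name, "' absent from the cell table")
}

#' Pipeline configuration
#'
#' Collects input paths and all tunable constants of the analysis. The
#' defaults are the canonical thresholds of the workflow: less than 5%
#' mitochondrial expression, 200-4000 total RNAs, a strict more-than-half
#' majority and more-than-20-counts rule for GEX isotype assignment, a
#' 0.85 CDR3 similarity cut-off for clonal grouping, 30/40/30 binning,
#' families of at least 5 cells for composition analyses, and extreme-
#' family sizes k = 20 and 100.
#'
#' @param vdj_path,counts_path,meta_path Input file paths (may be `NULL`
#'   when tables are passed in memory to [analyze_repertoire()]).
#' @param mito_max,rna_min,rna_max QC thresholds.
#' @param majority_fraction,min_counts GEX isotype rule thresholds.
#' @param distance_cutoff,distance_semantics Clonal-clustering threshold,
#'   see [cluster_clones()].
#' @param bin_fractions Length-3 low/mid/high fractions summing to 1.
#' @param family_min_size Minimum family size for composition analyses.
#' @param extreme_family_k Integer vector of extreme-family counts.
#' @param association_gene Gene whose bin/structure association is
#'   tested (default `"JCHAIN"`).
#' @param cd19_feature Name of the CD19 antibody-capture feature.
#' @param outdir Output directory for [write_results()] (optional).
#' @param seed Integer seed recorded in the run manifest.
#' @return A validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(vdj_path = NULL, counts_path = NULL,
                            meta_path = NULL,
                            mito_max = 0.05, rna_min = 200,
                            rna_max = 4000,
                            majority_fraction = 0.5, min_counts = 20,
                            distance_cutoff = 0.85,
                            distance_semantics = "similarity",
                            bin_fractions = c(0.3, 0.4, 0.3),
                            family_min_size = 5,
                            extreme_family_k = c(20L, 100L),
                            association_gene = "JCHAIN",
                            cd19_feature = "CD19_ADT",
                            outdir = NULL, seed = 1L) {
  cfg <- list(vdj_path = vdj_path, counts_path = counts_path,
              meta_path = meta_path, mito_max = mito_max,
              rna_min = rna_min, rna_max = rna_max,
              majority_fraction = majority_fraction,
              min_counts = min_counts,
              distance_cutoff = distance_cutoff,
              distance_semantics = distance_semantics,
              bin_fractions = bin_fractions,
              family_min_size = as.integer(family_min_size),
              extreme_family_k = as.integer(extreme_family_k),
              association_gene = association_gene,
              cd19_feature = cd19_feature,
              outdir = outdir, seed = as.integer(seed))
  if (abs(sum(cfg$bin_fractions) - 1) > 1e-9 ||
      length(cfg$bin_fractions) != 3)
    stop("pipeline_config: bin_fractions must be 3 values summing to 1")
  if (cfg$distance_cutoff < 0 || cfg$distance_cutoff > 1)
    stop("pipeline_config: distance_cutoff must be in [0, 1]")
  if (!cfg$distance_semantics %in% c("similarity", "distance"))
    stop("pipeline_config: distance_semantics must be 'similarity' or ",
         "'distance'")
  if (cfg$family_min_size < 2)
    stop("pipeline_config: family_min_size must be at least 2")
  structure(cfg, class = "pipeline_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' Unknown keys are rejected; omitted keys take the defaults of
#' [pipeline_config()].
#'
#' @param path Path to a YAML file.
#' @return A `pipeline_config` object.
#' @export
read_pipeline_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown))
    stop("read_pipeline_config: unknown key(s): ",
         paste(unknown, collapse = ", "))
  do.call(pipeline_config, vals)
}

#' Write pipeline results to disk
#'
#' Writes the per-cell assignment table, the per-clone table, the
#' statistics table and every auxiliary analysis table as TSV, plus a
#' JSON run manifest with the configuration hash and seed. Output is
#' deterministic for identical inputs.
#'
#' @param results Result list from [analyze_repertoire()].
#' @param outdir Output directory (created if needed).
#' @return Invisibly, the vector of files written.
#' @export
write_results <- function(results, outdir) {
  if (!dir.exists(outdir)) {
    ok <- dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    if (!ok || !dir.exists(outdir))
      stop("write_results: cannot create output directory '", outdir, "'")
  }
  files <- character(0)
  emit <- function(tab, name) {
    p <- file.path(outdir, paste0(name, ".tsv"))
    readr::write_tsv(tab, p)
    files <<- c(files, p)
  }
  emit(results$per_cell, "per_cell")
  emit(results$clones, "clones")
  emit(results$stat_tests, "stat_tests")
  for (nm in names(results$tables)) emit(results$tables[[nm]], nm)
  manifest <- list(
    seed = results$params$seed,
    config_hash = rlang::hash(unclass(results$params)),
    files = as.list(basename(files))
  )
  mpath <- file.path(outdir, "manifest.json")
  jsonlite::write_json(manifest, mpath, auto_unbox = TRUE, pretty = TRUE)
  invisible(c(files, mpath))
}
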