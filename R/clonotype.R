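#' Percent somatic hypermutation against germline
#'
#' Compares an observed heavy-chain nucleotide sequence with its aligned
#' germline and returns 100 x mismatches / comparable positions.
#' Positions where the germline is `N`, `-` or `.` are excluded from both
#' numerator and denominator.
#'
#' @param sequence,germline Aligned nucleotide strings of equal length
#'   (vectors are processed element-wise).
#' @return Numeric vector of percent mutation.
#' @examples
#' compute_shm("ATGC", "ATGC")   # 0
#' compute_shm("ATGG", "ATNC")   # 1 mismatch / 3 comparable = 33.33
#' @export
compute_shm <- function(sequence, germline) {
  if (length(sequence) != length(germline))
    stop("compute_shm: sequence and germline vectors differ in length")
  mapply(function(s, g) {
    if (nchar(s) != nchar(g))
      stop("compute_shm: sequence (", nchar(s), " nt) and germline (",
           nchar(g), " nt) differ in length")
    sv <- strsplit(toupper(s), "")[[1]]
    gv <- strsplit(toupper(g), "")[[1]]
    comparable <- gv %in% c("A", "C", "G", "T")
    if (!any(comparable))
      stop("compute_shm: no comparable (non-N, non-gap) germline positions")
    100 * sum(sv[comparable] != gv[comparable]) / sum(comparable)
  }, sequence, germline, USE.NAMES = FALSE)
}

#' Normalized hamming distance between two CDR3 amino-acid strings
#'
#' @param a,b Amino-acid strings. Sequences of different length (or empty
#'   sequences) are incomparable and give `NA`.
#' @return Mismatches / length in `[0, 1]`, or `NA` if incomparable.
#' @examples
#' cdr3_distance("CARDYW", "CARDFW")  # 1/6
#' cdr3_distance("CARDYW", "CARDYYW") # NA, lengths differ
#' @export
cdr3_distance <- function(a, b) {
  if (is.na(a) || is.na(b) || !nzchar(a) || !nzchar(b)) return(NA_real_)
  if (nchar(a) != nchar(b)) return(NA_real_)
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  sum(av != bv) / length(av)
}

strip_allele <- function(call) {
  sub("\\*.*$", "", call)
}

#' Group cells into clonal families
#'
#' Cells are first partitioned by identical IGHV gene, IGHJ gene (allele
#' suffixes stripped) and CDR3 length; within each partition, clones are
#' the single-linkage connected components of the graph joining two cells
#' whenever their normalized CDR3 hamming distance is within the
#' threshold. The threshold is given either as a minimum similarity
#' (`semantics = "similarity"`, default, value 0.85: distance <= 0.15
#' joins) or directly as a maximum distance.
#'
#' Records without a CDR3 or V/J call are returned with `clone_id` `NA`.
#' If a barcode carries several heavy chains, the row with the highest
#' total evidence (longest sequence) is kept and the duplicates dropped
#' with a warning. Clone ids are deterministic: components are numbered
#' by their smallest member barcode, so input order never changes
#' memberships or ids.
#'
#' @param records AIRR tibble with `cell_id`, `v_call`, `j_call`,
#'   `junction_aa` (and optionally `sequence`, `germline_alignment`).
#' @param cutoff Threshold value in `[0, 1]` (default 0.85 similarity).
#' @param semantics `"similarity"` or `"distance"`.
#' @return Tibble `barcode`, `clone_id`, `v_call`, `j_call`, `cdr3_aa`
#'   (stripped calls), one row per clusterable input record.
#' @export
cluster_clones <- function(records, cutoff = 0.85,
                           semantics = c("similarity", "distance")) {
  semantics <- match.arg(semantics)
  if (cutoff < 0 || cutoff > 1)
    stop("cluster_clones: cutoff must be in [0, 1]")
  max_dist <- if (semantics == "similarity") 1 - cutoff else cutoff

  stopifnot(all(c("cell_id", "v_call", "j_call", "junction_aa") %in%
                  names(records)))
  if (anyDuplicated(records$cell_id)) {
    len <- if ("sequence" %in% names(records))
      nchar(records$sequence) else nchar(records$junction_aa)
    ord <- order(-len, seq_len(nrow(records)))
    keep <- !duplicated(records$cell_id[ord])
    dropped <- sum(!keep)
    records <- records[sort(ord[keep]), , drop = FALSE]
    warning("cluster_clones: dropped ", dropped,
            " duplicate heavy-chain row(s), keeping the highest-evidence ",
            "row per barcode")
  }

  out <- tibble::tibble(
    barcode = records$cell_id,
    clone_id = NA_character_,
    v_call = strip_allele(records$v_call),
    j_call = strip_allele(records$j_call),
    cdr3_aa = records$junction_aa
  )
  ok <- !is.na(out$cdr3_aa) & nzchar(out$cdr3_aa) &
    !is.na(out$v_call) & nzchar(out$v_call) &
    !is.na(out$j_call) & nzchar(out$j_call)

  idx <- which(ok)
  if (!length(idx)) return(out)
  part_key <- paste(out$v_call[idx], out$j_call[idx],
                    nchar(out$cdr3_aa[idx]), sep = "|")
  comp_min_barcode <- character(0)
  membership <- integer(length(idx))
  n_comp <- 0L
  for (key in unique(part_key)) {
    rows <- which(part_key == key)
    cdr3 <- out$cdr3_aa[idx[rows]]
    m <- length(rows)
    if (m == 1) {
      comps <- 1L
    } else {
      chars <- do.call(rbind, strsplit(cdr3, ""))
      len <- ncol(chars)
      d <- matrix(0, m, m)
      for (i in seq_len(m - 1)) {
        for (j in seq(i + 1, m)) {
          d[i, j] <- d[j, i] <- sum(chars[i, ] != chars[j, ]) / len
        }
      }
      adj <- (d <= max_dist) * 1
      g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected",
                                               diag = FALSE)
      comps <- igraph::components(g)$membership
    }
    for (c_local in unique(comps)) {
      n_comp <- n_comp + 1L
      members <- rows[comps == c_local]
      membership[members] <- n_comp
      comp_min_barcode[n_comp] <- min(out$barcode[idx[members]])
    }
  }
  # deterministic ids ordered by smallest member barcode
  rank_id <- rank(comp_min_barcode, ties.method = "first")
  out$clone_id[idx] <- sprintf("CLONE%05d", rank_id[membership])
  out
}
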