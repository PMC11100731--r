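#' Classify a clonal family's lineage structure
#'
#' A family is a `singlet` if it has one member, `isogenic` if all of its
#' two or more members carry byte-identical heavy-chain nucleotide
#' sequences (a recall-expanded memory-B-cell signature), and
#' `heterogenic` if it has at least two distinct member sequences (a
#' germinal-center-export signature). Members lacking a sequence are
#' excluded with a warning.
#'
#' @param sequences Character vector of the family members' full
#'   heavy-chain nucleotide sequences.
#' @return `"singlet"`, `"isogenic"` or `"heterogenic"`.
#' @examples
#' classify_clone_structure(c("ATG", "ATG", "ATG"))  # isogenic
#' classify_clone_structure(c("ATG", "ATC"))         # heterogenic
#' @export
classify_clone_structure <- function(sequences) {
  missing <- is.na(sequences) | !nzchar(sequences)
  if (any(missing)) {
    warning("classify_clone_structure: excluding ", sum(missing),
            " member(s) without a sequence")
    sequences <- sequences[!missing]
  }
  if (!length(sequences))
    stop("classify_clone_structure: family has no sequenced members")
  n <- length(sequences)
  u <- length(unique(sequences))
  if (n == 1) "singlet" else if (u == 1) "isogenic" else "heterogenic"
}

#' Summarize clonal families
#'
#' Builds the per-clone table: size, number of unique heavy-chain
#' sequences, structure label, SHM summaries, CD19-bin composition with
#' the predominant-bin call, and isotype-class counts.
#'
#' @param cells Per-cell tibble with columns `barcode`, `clone_id`,
#'   `sequence`, `shm_percent`, and optionally `cd19_bin` and
#'   `isotype_class`.
#' @param low_cut,high_cut Thresholds for the predominant-CD19 call, see
#'   [family_cd19_composition()].
#' @return Tibble with one row per clone: `clone_id`, `size`,
#'   `unique_sequences`, `structure`, `median_shm`, `mean_shm`,
#'   `frac_cd19_low/mid/high`, `predominant_cd19`, and `n_Ig*` isotype
#'   class counts.
#' @export
summarize_clones <- function(cells, low_cut = 0.30, high_cut = 0.30) {
  stopifnot(all(c("barcode", "clone_id", "sequence", "shm_percent") %in%
                  names(cells)))
  cells <- cells[!is.na(cells$clone_id), , drop = FALSE]
  have_bins <- "cd19_bin" %in% names(cells)
  have_iso <- "isotype_class" %in% names(cells)

  fam <- split(seq_len(nrow(cells)), cells$clone_id)
  rows <- lapply(names(fam), function(id) {
    i <- fam[[id]]
    seqs <- cells$sequence[i]
    res <- tibble::tibble(
      clone_id = id,
      size = length(i),
      unique_sequences = length(unique(seqs[!is.na(seqs) & nzchar(seqs)])),
      structure = classify_clone_structure(seqs),
      median_shm = stats::median(cells$shm_percent[i], na.rm = TRUE),
      mean_shm = mean(cells$shm_percent[i], na.rm = TRUE)
    )
    if (have_bins) {
      bins <- cells$cd19_bin[i]
      if (any(!is.na(bins))) {
        comp <- family_cd19_composition(bins[!is.na(bins)],
                                        low_cut = low_cut,
                                        high_cut = high_cut)
        res$frac_cd19_low <- comp$fractions[["low"]]
        res$frac_cd19_mid <- comp$fractions[["mid"]]
        res$frac_cd19_high <- comp$fractions[["high"]]
        res$predominant_cd19 <- comp$predominant
      } else {
        res$frac_cd19_low <- res$frac_cd19_mid <- res$frac_cd19_high <-
          NA_real_
        res$predominant_cd19 <- NA_character_
      }
    }
    if (have_iso) {
      for (cl in c("IgM", "IgD", "IgG", "IgA", "IgE"))
        res[[paste0("n_", cl)]] <- sum(cells$isotype_class[i] == cl,
                                       na.rm = TRUE)
    }
    res
  })
  dplyr::bind_rows(rows) |> dplyr::arrange(.data$clone_id)
}

#' CD19-bin composition of one clonal family
#'
#' Computes the family's low/mid/high CD19-bin fractions and calls the
#' family predominantly CD19-low if strictly more than `low_cut` of its
#' members are CD19-low *and* strictly less than `high_cut` are
#' CD19-high (and symmetrically for predominantly CD19-high); otherwise
#' `"neither"`.
#'
#' @param bins Character vector of member bins (`"low"`, `"mid"`,
#'   `"high"`); `NA` members must be removed by the caller.
#' @param low_cut,high_cut Fraction thresholds (defaults 0.30).
#' @return A list with `fractions` (named numeric, sums to 1) and
#'   `predominant` (`"low"`, `"high"` or `"neither"`).
#' @export
family_cd19_composition <- function(bins, low_cut = 0.30,
                                    high_cut = 0.30) {
  if (!length(bins) || any(is.na(bins)))
    stop("family_cd19_composition: requires at least one binned member ",
         "and no NA bins")
  if (!all(bins %in% c("low", "mid", "high")))
    stop("family_cd19_composition: bins must be low/mid/high")
  n <- length(bins)
  fr <- c(low = sum(bins == "low") / n, mid = sum(bins == "mid") / n,
          high = sum(bins == "high") / n)
  predominant <- if (fr[["low"]] > low_cut && fr[["high"]] < high_cut) {
    "low"
  } else if (fr[["high"]] > high_cut && fr[["low"]] < low_cut) {
    "high"
  } else "neither"
  list(fractions = fr, predominant = predominant)
}

#' Select the most and least mutated heterogenic families
#'
#' Ranks heterogenic families of at least `min_size` members by their SHM
#' summary (default the median of member percent SHM; ties broken by
#' `clone_id`) and returns the top-k most mutated and bottom-k least
#' mutated. If fewer than `2k` families are eligible the two lists
#' overlap, with a warning.
#'
#' @param families Per-clone tibble from [summarize_clones()] (must
#'   contain `clone_id`, `structure`, `size` and the ranking column).
#' @param k Number of families per extreme (the analyses use 20 and 100).
#' @param min_size Minimum family size (default 5).
#' @param rank_by Ranking column (default `"median_shm"`).
#' @return A list with tibbles `most_mutated` and `least_mutated`.
#' @export
select_extreme_families <- function(families, k = 20, min_size = 5,
                                    rank_by = "median_shm") {
  eligible <- families[families$structure == "heterogenic" &
                         families$size >= min_size, , drop = FALSE]
  if (!nrow(eligible))
    stop("select_extreme_families: no heterogenic families of size >= ",
         min_size)
  if (nrow(eligible) < 2 * k)
    warning("select_extreme_families: only ", nrow(eligible),
            " eligible families for 2k = ", 2 * k,
            "; extremes will overlap")
  ord <- order(eligible[[rank_by]], eligible$clone_id)
  least <- eligible[ord[seq_len(min(k, nrow(eligible)))], , drop = FALSE]
  ord_desc <- order(-eligible[[rank_by]], eligible$clone_id)
  most <- eligible[ord_desc[seq_len(min(k, nrow(eligible)))], ,
                   drop = FALSE]
  list(most_mutated = most, least_mutated = least)
}

#' Isotype-class composition by clone structure
#'
#' Cross-tabulates cells by clone structure and isotype class and returns
#' within-structure fractions alongside the raw counts.
#'
#' @param cells Tibble with columns `structure` and `isotype_class`, one
#'   row per cell; rows with `NA` in either column are rejected.
#' @return Tibble `structure`, `isotype_class`, `n`, `fraction` (rows of
#'   each structure sum to 1).
#' @export
structure_isotype_frequencies <- function(cells) {
  stopifnot(all(c("structure", "isotype_class") %in% names(cells)))
  if (!nrow(cells))
    stop("structure_isotype_frequencies: empty input")
  if (any(is.na(cells$structure)) || any(is.na(cells$isotype_class)))
    stop("structure_isotype_frequencies: every cell needs both a ",
         "structure and an isotype class")
  cells |>
    dplyr::count(.data$structure, .data$isotype_class, name = "n") |>
    dplyr::group_by(.data$structure) |>
    dplyr::mutate(fraction = .data$n / sum(.data$n)) |>
    dplyr::ungroup()
}
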