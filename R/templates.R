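#' Synthetic IGHV/IGHJ germline template panel
#'
#' Returns the fixed panel of synthetic heavy-chain V and J template
#' sequences bundled with the package (12 V templates of 240 nt, 6 J
#' templates of 45 nt, random composition, frozen at package build). They
#' stand in for real IMGT germline genes so that simulated rearrangements
#' have a well-defined germline to mutate away from; they carry no
#' biological motif content.
#'
#' @return A tibble with columns `name` (gene name with `*01` allele
#'   suffix), `segment` (`"V"` or `"J"`) and `sequence` (nucleotide string).
#' @examples
#' germline_templates()
#' @export
germline_templates <- function() {
  if (!is.null(.template_cache$panel)) return(.template_cache$panel)
  path <- system.file("extdata", "synthetic_ighvj_templates.fasta",
                      package = "bmpcrep", mustWork = TRUE)
  seqs <- Biostrings::readDNAStringSet(path)
  panel <- tibble::tibble(
    name = names(seqs),
    segment = ifelse(grepl("^IGHV", names(seqs)), "V", "J"),
    sequence = as.character(seqs)
  )
  .template_cache$panel <- panel
  panel
}

.template_cache <- new.env(parent = emptyenv())

# one codon per amino acid, used to reverse-translate simulated CDR3s
.codon_of <- c(
  A = "GCT", R = "CGT", N = "AAT", D = "GAT", C = "TGT",
  Q = "CAA", E = "GAA", G = "GGT", H = "CAT", I = "ATT",
  L = "CTT", K = "AAA", M = "ATG", F = "TTT", P = "CCT",
  S = "TCT", T = "ACT", W = "TGG", Y = "TAT", V = "GTT"
)

aa_to_nt <- function(aa) {
  paste(.codon_of[strsplit(aa, "")[[1]]], collapse = "")
}
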