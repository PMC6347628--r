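# Genetic-code machinery shared by the simulator and the 4DTv scorer.
# Everything is keyed on the standard code only.

BASES <- c("A", "C", "G", "T")
PURINES <- c("A", "G")

# The 8 two-base prefixes whose third position is fourfold degenerate in the
# standard code (Ser TCN, Leu CTN, Pro CCN, Arg CGN, Thr ACN, Val GTN,
# Ala GCN, Gly GGN).
FOURFOLD_PREFIXES <- c("TC", "CT", "CC", "CG", "AC", "GT", "GC", "GG")

# 61 sense codons of the standard code; the ancestral sequence simulator
# draws uniformly from these.
sense_codons <- function() {
  code <- Biostrings::GENETIC_CODE
  names(code)[code != "*"]
}

#' Test whether an aligned codon column is a fourfold-degenerate site
#'
#' A column is scored as fourfold degenerate when neither codon contains a
#' gap (`-`) or ambiguity (`N`), the two codons agree at positions 1 and 2,
#' and that shared prefix is one of the 8 fourfold families of the standard
#' genetic code. This is the strict-intersection convention: the site must be
#' fourfold degenerate in both sequences simultaneously.
#'
#' @param codon_a,codon_b Character vectors of aligned 3-mers over
#'   `{A,C,G,T,N,-}` (recycled to a common length).
#' @return Logical vector.
#' @examples
#' is_fourfold_site("GGT", "GGA") # Gly family, TRUE
#' is_fourfold_site("AGA", "AGG") # AG* splits Arg/Ser, FALSE
#' @export
is_fourfold_site <- function(codon_a, codon_b) {
  codon_a <- toupper(codon_a)
  codon_b <- toupper(codon_b)
  if (any(nchar(codon_a) != 3L) || any(nchar(codon_b) != 3L)) {
    abort("codons must be exactly 3 characters long")
  }
  ok_chars <- function(x) !grepl("[^ACGT]", x)
  pa <- substr(codon_a, 1L, 2L)
  pb <- substr(codon_b, 1L, 2L)
  ok_chars(codon_a) & ok_chars(codon_b) & pa == pb & pa %in% FOURFOLD_PREFIXES
}

# Purine/pyrimidine transversion indicator for two aligned third-position
# bases (assumed unambiguous ACGT).
is_transversion <- function(base_a, base_b) {
  (base_a %in% PURINES) != (base_b %in% PURINES)
}
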