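# Readers/writers for the pipeline's plain-text exchange formats. All TSVs
# carry a header row; columns beyond the required ones pass through.

read_tsv_checked <- function(path, required) {
  x <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  missing <- setdiff(required, names(x))
  if (length(missing)) {
    abort(paste0(path, " lacks required column(s): ",
                 paste(missing, collapse = ", ")))
  }
  x
}

#' Read coding sequences from FASTA as a named character vector
#' @param path FASTA file path.
#' @return Named character vector of uppercase sequences.
#' @export
read_sequences <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  setNames(toupper(as.character(x)), names(x))
}

#' Read a pair table (pair_id, gene_a, gene_b, ...)
#' @param path TSV path.
#' @return Tibble.
#' @export
read_pair_table <- function(path) read_tsv_checked(path, c("pair_id", "gene_a", "gene_b"))

#' Read a synteny anchor table (block_id, gene_a, gene_b)
#' @param path TSV path.
#' @return Tibble.
#' @export
read_anchor_table <- function(path) read_tsv_checked(path, c("block_id", "gene_a", "gene_b"))

#' Read a gene-position table (gene, chrom, rank)
#' @param path TSV path.
#' @return Tibble.
#' @export
read_position_table <- function(path) read_tsv_checked(path, c("gene", "chrom", "rank"))

#' Read a domain-hit table (protein, species, domain, start, end, evalue)
#' @param path TSV path.
#' @return Tibble.
#' @export
read_domain_hits <- function(path) {
  read_tsv_checked(path, c("protein", "species", "domain", "start", "end", "evalue"))
}

#' Read a gene x tissue expression matrix (gene + one column per tissue)
#' @param path TSV path.
#' @return Tibble.
#' @export
read_expression <- function(path) read_tsv_checked(path, "gene")

#' Read a family assignment table (gene, family_id)
#' @param path TSV path.
#' @return Tibble.
#' @export
read_family_table <- function(path) read_tsv_checked(path, c("gene", "family_id"))

#' Attach sequences to a pair table, producing scorable codon pairs
#'
#' @param pairs A pair tibble (`pair_id`, `gene_a`, `gene_b`, ...).
#' @param sequences Named character vector (or DNAStringSet) of sequences.
#' @return Codon-pair tibble ready for [fourdtv()]; unresolved genes are
#'   skipped with a logged count.
#' @export
pairs_with_sequences <- function(pairs, sequences) {
  pairs <- tibble::as_tibble(pairs)
  if (inherits(sequences, "XStringSet")) {
    sequences <- setNames(as.character(sequences), names(sequences))
  }
  ok <- pairs$gene_a %in% names(sequences) & pairs$gene_b %in% names(sequences)
  if (any(!ok)) {
    inform(paste0("skipped ", sum(!ok), " pair(s) with unresolved gene sequences"))
    pairs <- pairs[ok, , drop = FALSE]
  }
  if (nrow(pairs) == 0L) abort("no scorable pairs after sequence lookup")
  pairs$seq_a <- unname(sequences[pairs$gene_a])
  pairs$seq_b <- unname(sequences[pairs$gene_b])
  as_codon_pairs(pairs)
}

#' Write a tibble as TSV
#' @param x Tibble.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_results_tsv <- function(x, path) {
  readr::write_tsv(tibble::as_tibble(x), path)
  invisible(path)
}
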