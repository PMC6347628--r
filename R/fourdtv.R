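#' Validate a table of aligned codon pairs
#'
#' Checks the codon-alignment contract: both sequences of a pair have equal
#' length, the length is a multiple of 3, characters are drawn from
#' `{A,C,G,T,N,-}`, and gaps occur only as whole-codon triples. Violations
#' are rejected with an error naming the offending pair.
#'
#' @param pairs A data frame with columns `pair_id`, `seq_a`, `seq_b`
#'   (additional columns such as `gene_a`, `gene_b`, `cohort` pass through).
#' @return The input as a tibble, invisibly validated.
#' @export
as_codon_pairs <- function(pairs) {
  pairs <- tibble::as_tibble(pairs)
  needed <- c("pair_id", "seq_a", "seq_b")
  missing_cols <- setdiff(needed, names(pairs))
  if (length(missing_cols)) {
    abort(paste0("pairs table lacks column(s): ", paste(missing_cols, collapse = ", ")))
  }
  a <- toupper(pairs$seq_a)
  b <- toupper(pairs$seq_b)
  bad_len <- nchar(a) != nchar(b) | nchar(a) %% 3L != 0L
  if (any(bad_len)) {
    abort(paste0("unequal or non-codon sequence lengths for pair(s): ",
                 paste(head(pairs$pair_id[bad_len], 5), collapse = ", ")))
  }
  bad_char <- grepl("[^ACGTN-]", a) | grepl("[^ACGTN-]", b)
  if (any(bad_char)) {
    abort(paste0("invalid characters in pair(s): ",
                 paste(head(pairs$pair_id[bad_char], 5), collapse = ", ")))
  }
  # gaps only in whole-codon triples: after removing "---" codons no "-" left
  partial_gap <- function(s) {
    codons <- stringr::str_extract_all(s, ".{3}")
    vapply(codons, function(cs) any(grepl("-", cs) & cs != "---"), logical(1))
  }
  bad_gap <- partial_gap(a) | partial_gap(b)
  if (any(bad_gap)) {
    abort(paste0("gap characters outside whole-codon triples in pair(s): ",
                 paste(head(pairs$pair_id[bad_gap], 5), collapse = ", ")))
  }
  pairs$seq_a <- a
  pairs$seq_b <- b
  pairs
}

# Score one aligned pair; returns c(n_4d, n_tv).
score_pair_4dtv <- function(seq_a, seq_b) {
  n <- nchar(seq_a) %/% 3L
  if (n == 0L) return(c(0L, 0L))
  starts <- 3L * seq_len(n) - 2L
  ca <- substring(seq_a, starts, starts + 2L)
  cb <- substring(seq_b, starts, starts + 2L)
  four <- is_fourfold_site(ca, cb)
  if (!any(four)) return(c(0L, 0L))
  ta <- substr(ca[four], 3L, 3L)
  tb <- substr(cb[four], 3L, 3L)
  c(sum(four), sum(is_transversion(ta, tb)))
}

#' Compute 4DTv statistics for aligned coding-sequence pairs
#'
#' For each pair, codon columns passing [is_fourfold_site()] are scored; a
#' transversion is a third-position difference pairing a purine with a
#' pyrimidine. The statistic is the raw transversion proportion among scored
#' fourfold sites (no multiple-hit correction by default). Pairs with zero
#' scorable sites get `defined = FALSE` and `fourdtv = NA`.
#'
#' With `corrected = TRUE` an additional column `fourdtv_corrected` holds the
#' saturation-corrected transversion distance `-log(1 - 2 * fourdtv) / 2`,
#' the closed-form inverse of the purine/pyrimidine two-state chain (an
#' HKY-style correction). It is provided for exploration and is not used by
#' the dating defaults.
#'
#' @param pairs A codon-pair table (see [as_codon_pairs()]).
#' @param corrected Also report the corrected distance? Default `FALSE`.
#' @return The input tibble with columns `n_4d_sites`, `n_transversions`,
#'   `fourdtv`, `defined` appended (sequences columns dropped).
#' @examples
#' pairs <- tibble::tibble(pair_id = "p1", seq_a = "GGTCCTATG", seq_b = "GGACCCATG")
#' fourdtv(pairs) # 2 fourfold sites, 1 transversion, 4DTv = 0.5
#' @export
fourdtv <- function(pairs, corrected = FALSE) {
  pairs <- as_codon_pairs(pairs)
  scores <- purrr::map2(pairs$seq_a, pairs$seq_b, score_pair_4dtv)
  out <- dplyr::select(pairs, -"seq_a", -"seq_b")
  out$n_4d_sites <- vapply(scores, `[`, integer(1), 1L)
  out$n_transversions <- vapply(scores, `[`, integer(1), 2L)
  out$defined <- out$n_4d_sites > 0L
  out$fourdtv <- ifelse(out$defined, out$n_transversions / out$n_4d_sites, NA_real_)
  if (corrected) {
    out$fourdtv_corrected <- ifelse(
      out$defined & out$fourdtv < 0.5,
      -log(1 - 2 * out$fourdtv) / 2,
      ifelse(out$defined, Inf, NA_real_)
    )
  }
  out
}

#' Extract scorable codon pairs from synteny anchors
#'
#' Applies the collinear-block size rule (blocks with fewer than `min_block`
#' anchor pairs are dropped) and resolves each retained anchor to an aligned
#' codon pair. Genes missing from `sequences` are skipped with a logged
#' count.
#'
#' @param anchors Tibble with columns `block_id`, `gene_a`, `gene_b`.
#' @param sequences Named character vector (or `Biostrings::DNAStringSet`) of
#'   coding sequences, names matching anchor gene identifiers.
#' @param min_block Minimum anchors per retained block; default 5.
#' @return Codon-pair tibble (`pair_id`, `gene_a`, `gene_b`, `seq_a`,
#'   `seq_b`, `block_id`).
#' @export
extract_anchor_pairs <- function(anchors, sequences, min_block = 5L) {
  anchors <- tibble::as_tibble(anchors)
  if (inherits(sequences, "XStringSet")) {
    sequences <- setNames(as.character(sequences), names(sequences))
  }
  anchors <- dplyr::group_by(anchors, .data$block_id) |>
    dplyr::filter(dplyr::n() >= min_block) |>
    dplyr::ungroup()
  resolved <- anchors$gene_a %in% names(sequences) &
    anchors$gene_b %in% names(sequences)
  n_skip <- sum(!resolved)
  if (n_skip > 0) {
    inform(paste0("skipped ", n_skip, " anchor pair(s) with unresolved gene sequences"))
  }
  anchors <- anchors[resolved, , drop = FALSE]
  if (nrow(anchors) == 0L) {
    abort("no scorable pairs: no anchors survive block-size filtering and sequence lookup")
  }
  out <- tibble::tibble(
    pair_id = paste0(anchors$gene_a, "|", anchors$gene_b),
    gene_a = anchors$gene_a,
    gene_b = anchors$gene_b,
    seq_a = unname(sequences[anchors$gene_a]),
    seq_b = unname(sequences[anchors$gene_b]),
    block_id = anchors$block_id
  )
  as_codon_pairs(out)
}

# Assign tandem-cluster ids: genes on the same chromosome within `window`
# ranks of a cluster member join that cluster (transitive closure along the
# rank-sorted gene list).
tandem_clusters <- function(positions, window) {
  positions <- dplyr::arrange(tibble::as_tibble(positions), .data$chrom, .data$rank)
  new_cluster <- c(TRUE, diff(positions$rank) > window |
                     positions$chrom[-1] != positions$chrom[-nrow(positions)])
  positions$cluster <- paste0(positions$chrom, ":", cumsum(new_cluster))
  positions
}

#' Deduplicate tandem gene copies matched to a common homeolog
#'
#' Tandemly duplicated genes (same chromosome, within `window` gene ranks,
#' transitively closed) that are all paired against the same homeolog are
#' counted once: the result with the most scored fourfold sites is retained
#' (ties broken by lexicographically smallest tandem-side gene identifier,
#' then pair id). Results whose tandem cluster meets distinct homeologs pass
#' through unchanged. Both orientations of a pair are checked.
#'
#' @param results A [fourdtv()] result tibble (needs `pair_id`, `gene_a`,
#'   `gene_b`, `n_4d_sites`).
#' @param positions Tibble with columns `gene`, `chrom`, `rank` covering
#'   every gene in `results`.
#' @param window Tandem rank window (default 5 gene ranks).
#' @return The filtered results tibble.
#' @export
dedup_tandem <- function(results, positions, window = 5L) {
  stopifnot(window >= 1)
  results <- tibble::as_tibble(results)
  positions <- tibble::as_tibble(positions)
  genes <- unique(c(results$gene_a, results$gene_b))
  missing_pos <- setdiff(genes, positions$gene)
  if (length(missing_pos)) {
    abort(paste0("no position for gene(s): ", paste(head(missing_pos, 5), collapse = ", ")))
  }
  cl <- tandem_clusters(positions[positions$gene %in% genes, , drop = FALSE], window)
  cluster_of <- setNames(cl$cluster, cl$gene)

  keep_best <- function(df, tandem_gene_col) {
    # deterministic keep-rule: max n_4d_sites, then smallest tandem gene id,
    # then smallest pair_id
    df <- df[order(-df$n_4d_sites, df[[tandem_gene_col]], df$pair_id), , drop = FALSE]
    df[1L, , drop = FALSE]
  }
  for (side in c("a", "b")) {
    tandem_col <- paste0("gene_", side)
    homeo_col <- if (side == "a") "gene_b" else "gene_a"
    key <- paste0(results[[homeo_col]], "::", cluster_of[results[[tandem_col]]])
    results <- dplyr::bind_rows(lapply(split(results, key), function(df) {
      if (nrow(df) == 1L) df else keep_best(df, tandem_col)
    }))
  }
  dplyr::arrange(results, .data$pair_id)
}
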