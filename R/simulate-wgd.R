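#' Specification of a synthetic WGD pair-cohort scenario
#'
#' Describes the three pair cohorts an allotetraploid grass genome shows in
#' its 4DTv distribution — a recent whole-genome-duplication (homeolog)
#' cohort, a cross-species ortholog cohort, and a deep background cohort
#' (the grass rho WGD) — plus tandem duplicates that all match the same
#' homeolog. Defaults mirror the broomcorn-millet setting: homeologs at
#' ~5.8 MY with expected 4DTv 0.032, orthologs at ~18 MY with 0.081, and the
#' rho background at ~70 MY with 0.38.
#'
#' @param n_pairs_wgd,n_pairs_ortholog,n_pairs_background Cohort sizes.
#' @param t_wgd,t_ortholog,t_background Divergence times (MY).
#' @param d_wgd,d_ortholog,d_background Expected 4DTv of each cohort; used to
#'   derive per-cohort transversion rates unless a single clock is supplied
#'   to [simulate_wgd_genome()].
#' @param n_tandem_triplets Number of WGD pairs receiving two extra tandem
#'   copies of the A-side gene, all matched to the same homeolog.
#' @param seq_len_codons Codons per simulated sequence.
#' @param seed Optional integer seed.
#' @return A named list of class `wgd_cohort_spec`.
#' @export
wgd_cohort_spec <- function(n_pairs_wgd = 500L, t_wgd = 5.8, d_wgd = 0.032,
                            n_pairs_ortholog = 500L, t_ortholog = 18, d_ortholog = 0.081,
                            n_pairs_background = 500L, t_background = 70, d_background = 0.38,
                            n_tandem_triplets = 5L, seq_len_codons = 400L,
                            seed = NULL) {
  counts <- c(n_pairs_wgd, n_pairs_ortholog, n_pairs_background, n_tandem_triplets)
  times <- c(t_wgd, t_ortholog, t_background)
  if (any(counts < 0)) abort("all pair/triplet counts must be >= 0")
  if (any(times < 0)) abort("all divergence times must be >= 0")
  if (seq_len_codons < 1) abort("seq_len_codons must be >= 1")
  if (n_tandem_triplets > n_pairs_wgd) abort("n_tandem_triplets cannot exceed n_pairs_wgd")
  structure(list(
    n_pairs_wgd = n_pairs_wgd, t_wgd = t_wgd, d_wgd = d_wgd,
    n_pairs_ortholog = n_pairs_ortholog, t_ortholog = t_ortholog, d_ortholog = d_ortholog,
    n_pairs_background = n_pairs_background, t_background = t_background,
    d_background = d_background, n_tandem_triplets = n_tandem_triplets,
    seq_len_codons = seq_len_codons, seed = seed
  ), class = "wgd_cohort_spec")
}

# Per-cohort rates: either a user-supplied single clock, or betas derived by
# inverting the K2P curve so each cohort's expected 4DTv hits its target
# (transition/transversion ratio fixed at alpha = 2*beta).
cohort_rates <- function(spec, params) {
  cohorts <- c("wgd", "ortholog", "background")
  if (!is.null(params)) {
    stopifnot(inherits(params, "substitution_params"))
    beta <- rep(params$beta, 3L)
    alpha <- rep(params$alpha, 3L)
  } else {
    d <- c(spec$d_wgd, spec$d_ortholog, spec$d_background)
    t <- c(spec$t_wgd, spec$t_ortholog, spec$t_background)
    beta <- ifelse(t > 0 & d > 0, mapply(k2p_beta_for, d, pmax(t, 1e-12)), 0)
    alpha <- 2 * beta
  }
  tibble::tibble(cohort = cohorts, alpha = alpha, beta = beta,
                 t = c(spec$t_wgd, spec$t_ortholog, spec$t_background))
}

#' Simulate a WGD-structured genome: pair table, sequences, anchors, positions
#'
#' Emits three labelled cohorts of codon-aligned paralog/ortholog pairs at
#' their configured divergence times, tandem triplets as extra copies of a
#' WGD pair's A-side gene placed at adjacent gene ranks and matched to the
#' same homeolog, a synteny anchor table (blocks of `block_size` anchors),
#' and a gene-position table. Ground-truth cohort labels and times travel in
#' the pair table.
#'
#' @param spec A [wgd_cohort_spec()].
#' @param params Optional [substitution_params()] imposing a single
#'   (alpha, beta) clock on all cohorts; by default per-cohort rates are
#'   derived from the spec's expected-4DTv targets.
#' @param block_size Anchors per synthetic collinear block (default 20).
#' @return List of class `wgd_simulation` with elements `pairs`,
#'   `sequences` (named character vector), `anchors`, `positions`, `rates`.
#' @export
simulate_wgd_genome <- function(spec, params = NULL, block_size = 20L) {
  stopifnot(inherits(spec, "wgd_cohort_spec"))
  if (!is.null(spec$seed)) set.seed(spec$seed)
  rates <- cohort_rates(spec, params)
  n_by <- c(wgd = spec$n_pairs_wgd, ortholog = spec$n_pairs_ortholog,
            background = spec$n_pairs_background)
  chrom_a <- c(wgd = "chr1A", ortholog = "chr2A", background = "chr3A")
  chrom_b <- c(wgd = "chr1B", ortholog = "chrS1", background = "chr3B")
  prefix <- c(wgd = "wgd", ortholog = "ort", background = "bkg")

  pairs <- list(); seqs <- list(); pos <- list()
  for (i in seq_len(nrow(rates))) {
    co <- rates$cohort[i]
    n <- n_by[[co]]
    if (n == 0L) next
    anc <- sim_codon_matrix(n, spec$seq_len_codons)
    is4d <- matrix(substr(anc, 1L, 2L) %in% FOURFOLD_PREFIXES, nrow = n)
    a <- sim_lineage(anc, is4d, rates$alpha[i], rates$beta[i], rates$t[i])
    b <- sim_lineage(anc, is4d, rates$alpha[i], rates$beta[i], rates$t[i])
    ids <- sprintf("%s%04d", prefix[[co]], seq_len(n))
    ga <- paste0(ids, "_a"); gb <- paste0(ids, "_b")
    pr <- tibble::tibble(pair_id = ids, gene_a = ga, gene_b = gb,
                         cohort = co, true_t = rates$t[i], tandem = FALSE)
    sq <- c(setNames(collapse_rows(a), ga), setNames(collapse_rows(b), gb))
    # gene ranks: non-tandem genes spaced 10 ranks apart; tandem copies +1/+2
    rank_a <- 10L * seq_len(n)
    if (co == "wgd" && spec$n_tandem_triplets > 0L) {
      for (j in seq_len(spec$n_tandem_triplets)) {
        for (k in 1:2) {
          gt <- paste0(ga[j], ".t", k)
          tcopy <- sim_lineage(anc[j, , drop = FALSE],
                               is4d[j, , drop = FALSE],
                               rates$alpha[i], rates$beta[i], rates$t[i])
          sq[gt] <- collapse_rows(tcopy)
          pr <- dplyr::bind_rows(pr, tibble::tibble(
            pair_id = paste0(ids[j], ".t", k), gene_a = gt, gene_b = gb[j],
            cohort = co, true_t = rates$t[i], tandem = TRUE))
          pos[[gt]] <- tibble::tibble(gene = gt, chrom = chrom_a[[co]],
                                      rank = rank_a[j] + k)
        }
      }
    }
    pos[[paste0(co, "_a")]] <- tibble::tibble(gene = ga, chrom = chrom_a[[co]], rank = rank_a)
    pos[[paste0(co, "_b")]] <- tibble::tibble(gene = gb, chrom = chrom_b[[co]], rank = 10L * seq_len(n))
    pairs[[co]] <- pr
    seqs[[co]] <- sq
  }
  pairs <- dplyr::bind_rows(pairs)
  if (nrow(pairs) == 0L) abort("spec produced no pairs at all")
  sequences <- unlist(unname(seqs))
  positions <- dplyr::bind_rows(pos)
  # synthetic collinear blocks: chunk each cohort's non-tandem anchors
  anchors <- pairs |>
    dplyr::filter(!.data$tandem) |>
    dplyr::group_by(.data$cohort) |>
    dplyr::mutate(block_id = paste0(.data$cohort, "_b",
                                    (dplyr::row_number() - 1L) %/% block_size + 1L)) |>
    dplyr::ungroup() |>
    dplyr::select("block_id", "gene_a", "gene_b")
  structure(list(pairs = pairs, sequences = sequences, anchors = anchors,
                 positions = positions, rates = rates, spec = spec),
            class = "wgd_simulation")
}

#' Write a WGD simulation to disk in the pipeline's file formats
#'
#' FASTA for the sequences, and TSVs for the pair table (with ground-truth
#' cohort label and time), synteny anchors, and gene positions.
#'
#' @param sim A [simulate_wgd_genome()] result.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the named vector of file paths written.
#' @export
write_wgd_files <- function(sim, dir) {
  stopifnot(inherits(sim, "wgd_simulation"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(fasta = file.path(dir, "sequences.fasta"),
             pairs = file.path(dir, "pairs.tsv"),
             anchors = file.path(dir, "anchors.tsv"),
             positions = file.path(dir, "positions.tsv"))
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(sim$sequences), paths[["fasta"]])
  readr::write_tsv(sim$pairs, paths[["pairs"]])
  readr::write_tsv(sim$anchors, paths[["anchors"]])
  readr::write_tsv(sim$positions, paths[["positions"]])
  invisible(paths)
}
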