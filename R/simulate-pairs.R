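#' Substitution-rate parameters for the codon-pair simulator
#'
#' A Kimura two-parameter clock on third positions of fourfold-degenerate
#' codons: `alpha` is the transition rate per site per million years per
#' lineage, `beta` the rate toward *each* of the two transversion neighbours,
#' and `t` the divergence time in million years (total path between the two
#' sequences is `2 * t`). The expected observed transversion proportion at a
#' fourfold site is `0.5 * (1 - exp(-8 * beta * t))`.
#'
#' @param alpha,beta Non-negative rates (per site per MY per lineage).
#' @param t Non-negative divergence time (MY).
#' @return A named list of class `substitution_params`.
#' @export
substitution_params <- function(alpha, beta, t) {
  if (alpha < 0 || beta < 0 || t < 0) abort("alpha, beta and t must all be >= 0")
  structure(list(alpha = alpha, beta = beta, t = t), class = "substitution_params")
}

#' Expected 4DTv under the K2P clock
#'
#' Closed form for the expected observed transversion-difference proportion
#' at a fourfold site after both lineages evolve for time `t` with
#' per-neighbour transversion rate `beta`.
#'
#' @param beta,t Rate and time as in [substitution_params()].
#' @return `0.5 * (1 - exp(-8 * beta * t))`.
#' @export
k2p_expected_4dtv <- function(beta, t) 0.5 * (1 - exp(-8 * beta * t))

#' Invert the K2P curve: the beta that yields a target expected 4DTv
#'
#' @param fourdtv Target expected 4DTv in `[0, 0.5)`.
#' @param t Divergence time in MY.
#' @return Per-neighbour transversion rate `beta`.
#' @export
k2p_beta_for <- function(fourdtv, t) {
  if (fourdtv < 0 || fourdtv >= 0.5) abort("target 4DTv must lie in [0, 0.5)")
  if (t <= 0) abort("t must be > 0")
  -log(1 - 2 * fourdtv) / (8 * t)
}

#' Haldane map-distance to recombination-fraction conversion
#'
#' @param d Map distance in Morgans.
#' @return Recombination fraction `0.5 * (1 - exp(-2 * d))`.
#' @export
haldane_r <- function(d) 0.5 * (1 - exp(-2 * d))

# Evolve a vector of third-position bases (integer codes into BASES) for time
# t under (alpha, beta). The jump process has constant total rate
# alpha + 2*beta regardless of state, so the exact exponential-waiting-time
# realisation reduces to a Poisson event count per site followed by that many
# jumps; each jump is a transition w.p. alpha/(alpha+2*beta), otherwise one
# of the two transversion neighbours equiprobably.
evolve_third <- function(b, alpha, beta, t) {
  total <- alpha + 2 * beta
  if (total == 0 || t == 0 || length(b) == 0L) return(b)
  k <- rpois(length(b), total * t)
  ts_map <- c(3L, 4L, 1L, 2L) # A<->G, C<->T
  kmax <- max(k)
  step <- 0L
  while (step < kmax) {
    step <- step + 1L
    act <- which(k >= step)
    cur <- b[act]
    is_ts <- runif(length(act)) < alpha / total
    nxt <- cur
    nxt[is_ts] <- ts_map[cur[is_ts]]
    tv <- !is_ts
    if (any(tv)) {
      purine <- cur[tv] %in% c(1L, 3L)
      pick <- runif(sum(tv)) < 0.5
      nxt[tv] <- ifelse(purine, ifelse(pick, 2L, 4L), ifelse(pick, 1L, 3L))
    }
    b[act] <- nxt
  }
  b
}

# Draw an ancestral codon matrix (n_pairs x len) uniform over sense codons
# and evolve `n_lineages` descendants: only third positions of fourfold
# codons mutate, so the realised fourfold-site set equals the ancestral one.
sim_codon_matrix <- function(n_pairs, len) {
  matrix(sample(sense_codons(), n_pairs * len, replace = TRUE),
         nrow = n_pairs, ncol = len)
}

sim_lineage <- function(anc, is4d, alpha, beta, t) {
  out <- anc
  if (any(is4d)) {
    third <- substr(anc[is4d], 3L, 3L)
    b <- evolve_third(match(third, BASES), alpha, beta, t)
    out[is4d] <- paste0(substr(anc[is4d], 1L, 2L), BASES[b])
  }
  out
}

collapse_rows <- function(m) {
  if (nrow(m) == 0L) return(character(0))
  apply(m, 1L, paste0, collapse = "")
}

#' Simulate aligned codon pairs diverged for a known time
#'
#' Each pair descends from a random ancestral codon sequence (uniform over
#' the 61 sense codons, no stops). Third positions of fourfold-degenerate
#' codons evolve independently on both lineages for time `t` under
#' `(alpha, beta)`; all other positions are held fixed, so the fourfold-site
#' set is known exactly and recorded as ground truth (`n_4d_true`).
#'
#' @param params A [substitution_params()] object.
#' @param n_pairs Number of pairs (>= 1).
#' @param seq_len_codons Codons per sequence (>= 1).
#' @param seed Optional integer seed for reproducibility.
#' @return Codon-pair tibble with `pair_id`, `gene_a`, `gene_b`, `seq_a`,
#'   `seq_b`, `n_4d_true`, `true_t`.
#' @export
simulate_codon_pairs <- function(params, n_pairs, seq_len_codons, seed = NULL) {
  stopifnot(inherits(params, "substitution_params"))
  if (n_pairs < 1 || seq_len_codons < 1) abort("n_pairs and seq_len_codons must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  anc <- sim_codon_matrix(n_pairs, seq_len_codons)
  is4d <- matrix(substr(anc, 1L, 2L) %in% FOURFOLD_PREFIXES, nrow = n_pairs)
  a <- sim_lineage(anc, is4d, params$alpha, params$beta, params$t)
  b <- sim_lineage(anc, is4d, params$alpha, params$beta, params$t)
  ids <- sprintf("pair%04d", seq_len(n_pairs))
  tibble::tibble(
    pair_id = ids,
    gene_a = paste0(ids, "_a"),
    gene_b = paste0(ids, "_b"),
    seq_a = collapse_rows(a),
    seq_b = collapse_rows(b),
    n_4d_true = rowSums(is4d),
    true_t = params$t
  )
}
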