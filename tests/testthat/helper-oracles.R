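# Independent oracles used to cross-check the implementation. These are
# deliberately written by a different route than the package code: literal
# table lookups, per-column scans, brute-force definitions, and numerical
# matrix powers.

# --- 64-entry degeneracy oracle -------------------------------------------
# A codon is fourfold degenerate iff all four third-base variants encode the
# same amino acid, read straight off the standard-code table.
oracle_code <- Biostrings::GENETIC_CODE

oracle_is_fourfold_codon <- function(codon) {
  if (grepl("[^ACGT]", codon)) return(FALSE)
  prefix <- substr(codon, 1, 2)
  aas <- oracle_code[paste0(prefix, c("A", "C", "G", "T"))]
  length(unique(aas)) == 1 && !any(aas == "*")
}

# Per-column brute-force 4DTv scan of one aligned pair.
oracle_4dtv <- function(seq_a, seq_b) {
  n <- nchar(seq_a) / 3
  n4 <- 0L; ntv <- 0L
  purine <- c("A", "G")
  for (i in seq_len(n)) {
    ca <- substr(seq_a, 3 * i - 2, 3 * i)
    cb <- substr(seq_b, 3 * i - 2, 3 * i)
    if (grepl("[^ACGT]", ca) || grepl("[^ACGT]", cb)) next
    if (substr(ca, 1, 2) != substr(cb, 1, 2)) next
    if (!oracle_is_fourfold_codon(ca) || !oracle_is_fourfold_codon(cb)) next
    n4 <- n4 + 1L
    ta <- substr(ca, 3, 3); tb <- substr(cb, 3, 3)
    if ((ta %in% purine) != (tb %in% purine)) ntv <- ntv + 1L
  }
  list(n_4d = n4, n_tv = ntv)
}

# Random codon-aligned pair over {A,C,G,T} with occasional N and whole-codon
# gaps, for oracle-equivalence testing.
random_codon_pair <- function(n_codons) {
  mk <- function() {
    codons <- replicate(n_codons, paste(sample(c("A", "C", "G", "T"), 3,
                                               replace = TRUE), collapse = ""))
    gap <- runif(n_codons) < 0.02
    codons[gap] <- "---"
    nmask <- runif(n_codons) < 0.02 & !gap
    codons[nmask] <- sub("^.", "N", codons[nmask])
    paste(codons, collapse = "")
  }
  list(seq_a = mk(), seq_b = mk())
}

# --- lumped purine/pyrimidine Markov-chain oracle -------------------------
# Two-state chain (R, Y) with switch rate 2*beta per lineage; the observed
# transversion-difference probability after both lineages run for time t is
# obtained by numerically powering the discretised transition matrix, never
# by the closed form the implementation tests against.
oracle_k2p_tv_prob <- function(beta, t, n_steps = 20000) {
  dt <- t / n_steps
  P1 <- matrix(c(1 - 2 * beta * dt, 2 * beta * dt,
                 2 * beta * dt, 1 - 2 * beta * dt), 2, 2)
  P <- diag(2)
  M <- P1
  k <- n_steps
  while (k > 0) {          # fast exponentiation of the step matrix
    if (k %% 2 == 1) P <- P %*% M
    M <- M %*% M
    k <- k %/% 2
  }
  # both lineages evolve independently from a common state
  sum(P[1, ] * P[1, c(2, 1)])  # prob the two endpoints differ in R/Y class
}

# --- brute-force Benjamini-Hochberg ---------------------------------------
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  for (i in seq_len(m)) {
    j_range <- i:m
    adj[o[i]] <- min(1, min(p[o[j_range]] * m / j_range))
  }
  adj
}

# --- exhaustive two-sided Fisher by table enumeration ---------------------
# Probabilities via lchoose products (not dhyper), summed over all tables
# with the observed margins whose probability <= observed.
oracle_fisher2 <- function(a, b, c, d) {
  r1 <- a + b; r2 <- c + d; c1 <- a + c; n <- a + b + c + d
  lo <- max(0, c1 - r2); hi <- min(r1, c1)
  logp <- function(x) {
    lchoose(r1, x) + lchoose(r2, c1 - x) - lchoose(n, c1)
  }
  probs <- exp(logp(lo:hi))
  obs <- exp(logp(a))
  sum(probs[probs <= obs * (1 + 1e-7)])
}
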