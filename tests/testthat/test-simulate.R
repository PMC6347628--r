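test_that("codon-pair simulator honours its degenerate limits", {
  p0 <- substitution_params(0.003, 0.0015, 0)
  pairs <- simulate_codon_pairs(p0, 10, 50, seed = 1)
  res <- fourdtv(pairs)
  expect_true(all(res$fourdtv[res$defined] == 0))  # t = 0: no substitutions
  expect_identical(pairs$seq_a, pairs$seq_b)

  # saturation: beta * t = 100 drives mean 4DTv to 0.5
  psat <- substitution_params(0, 1, 100)
  sat <- fourdtv(simulate_codon_pairs(psat, 50, 100, seed = 2))
  expect_lt(abs(mean(sat$fourdtv) - 0.5), 0.02)

  expect_error(simulate_codon_pairs(p0, 0, 50), ">= 1")
  expect_error(substitution_params(-1, 0, 0), ">= 0")
})

test_that("simulated ancestral sequences contain no stop codons", {
  pairs <- simulate_codon_pairs(substitution_params(0.01, 0.005, 5), 5, 200,
                                seed = 3)
  has_stop <- function(s) {
    codons <- substring(s, seq(1, nchar(s), 3), seq(3, nchar(s), 3))
    any(oracle_code[codons] == "*")
  }
  expect_false(any(vapply(pairs$seq_a, has_stop, logical(1))))
  expect_false(any(vapply(pairs$seq_b, has_stop, logical(1))))
})

test_that("mean simulated 4DTv matches the K2P closed form and the lumped-chain oracle", {
  beta <- 0.0015; t <- 18
  pairs <- simulate_codon_pairs(substitution_params(0.003, beta, t), 300, 300,
                                seed = 4)
  res <- fourdtv(pairs)
  pooled <- sum(res$n_transversions) / sum(res$n_4d_sites)
  expected <- k2p_expected_4dtv(beta, t)
  se <- sqrt(expected * (1 - expected) / sum(res$n_4d_sites))
  expect_lt(abs(pooled - expected), 3 * se)
  # the closed form itself agrees with the numerically-powered lumped chain
  expect_lt(abs(expected - oracle_k2p_tv_prob(beta, t)), 1e-6)
})

test_that("mean 4DTv is non-decreasing in divergence time", {
  means <- vapply(c(1, 5, 18, 70), function(t) {
    res <- fourdtv(simulate_codon_pairs(substitution_params(0.003, 0.0015, t),
                                        120, 300, seed = 5))
    mean(res$fourdtv)
  }, numeric(1))
  expect_true(all(diff(means) > 0))
})

test_that("generators are seed-reproducible", {
  p <- substitution_params(0.003, 0.0015, 10)
  expect_identical(simulate_codon_pairs(p, 5, 30, seed = 9),
                   simulate_codon_pairs(p, 5, 30, seed = 9))
  spec <- wgd_cohort_spec(n_pairs_wgd = 10, n_pairs_ortholog = 5,
                          n_pairs_background = 5, n_tandem_triplets = 1,
                          seq_len_codons = 20, seed = 9)
  expect_identical(simulate_wgd_genome(spec), simulate_wgd_genome(spec))
  cfg <- ril_sim_config(n_lines = 20, n_markers = 50, missing_rate = 0.1,
                        error_rate = 0.05, seed = 9)
  expect_identical(simulate_ril_population(cfg), simulate_ril_population(cfg))
  ecfg <- expression_sim_config(c("2" = 5, "4" = 3), seed = 9)
  expect_identical(simulate_expression_families(ecfg),
                   simulate_expression_families(ecfg))
  arch <- list(list(domains = c("MATH", "BTB"), n = 3))
  expect_identical(simulate_domain_table(arch, seed = 9),
                   simulate_domain_table(arch, seed = 9))
})

test_that("WGD genome simulation constructs cohorts, tandems and anchors as specified", {
  spec <- wgd_cohort_spec(n_pairs_wgd = 12, n_pairs_ortholog = 6,
                          n_pairs_background = 7, n_tandem_triplets = 2,
                          seq_len_codons = 30, seed = 21)
  sim <- simulate_wgd_genome(spec)
  expect_setequal(unique(sim$pairs$cohort), c("wgd", "ortholog", "background"))
  expect_equal(sum(sim$pairs$cohort == "wgd"), 12 + 2 * 2) # tandem extras
  expect_equal(sum(sim$pairs$tandem), 4)

  # exactly 2 homeologs matched by >= 2 A-side genes at adjacent ranks
  tgroups <- sim$pairs |>
    dplyr::filter(.data$cohort == "wgd") |>
    dplyr::count(.data$gene_b) |>
    dplyr::filter(.data$n >= 2)
  expect_equal(nrow(tgroups), 2L)
  pos <- sim$positions
  for (hb in tgroups$gene_b) {
    genes <- sim$pairs$gene_a[sim$pairs$gene_b == hb]
    ranks <- sort(pos$rank[pos$gene %in% genes])
    expect_true(all(diff(ranks) == 1))
  }

  # ortholog cohort absent when its count is zero
  spec0 <- wgd_cohort_spec(n_pairs_wgd = 6, n_pairs_ortholog = 0,
                           n_pairs_background = 6, n_tandem_triplets = 0,
                           seq_len_codons = 20, seed = 22)
  sim0 <- simulate_wgd_genome(spec0)
  expect_false("ortholog" %in% sim0$pairs$cohort)

  # every anchor block has >= 5 pairs only when cohort sizes allow
  blocks <- dplyr::count(sim$anchors, .data$block_id)
  expect_true(all(blocks$n <= 20))
  expect_true(all(sim$pairs$gene_a %in% names(sim$sequences)))
  expect_true(all(sim$pairs$gene_b %in% names(sim$sequences)))
})

test_that("RIL genotype marginals follow the F_g expectation", {
  # F2: (1/4, 1/2, 1/4)
  cfg2 <- ril_sim_config(n_lines = 400, n_markers = 50, generation = 2, seed = 31)
  counts2 <- genotype_counts(simulate_ril_population(cfg2))
  het_frac <- sum(counts2$n_het) / (400 * 50)
  expect_lt(abs(het_frac - 0.5), 3 * sqrt(0.25 / (400 * 50)))

  # F6 pooled heterozygote fraction ~ 2/64
  cfg6 <- ril_sim_config(n_lines = 132, n_markers = 2000, generation = 6, seed = 32)
  counts6 <- genotype_counts(simulate_ril_population(cfg6))
  n <- 132 * 2000
  p <- 2 / 64
  expect_lt(abs(sum(counts6$n_het) / n - p), 3 * sqrt(p * (1 - p) / n))

  # goodness of fit across 20 seeds: pooled counts fit F_g in >= 19 cases
  ok <- 0
  for (s in 1:20) {
    cfg <- ril_sim_config(n_lines = 132, n_markers = 200, generation = 6, seed = 100 + s)
    cc <- genotype_counts(simulate_ril_population(cfg))
    pooled <- tibble::tibble(n_homA = sum(cc$n_homA), n_het = sum(cc$n_het),
                             n_homB = sum(cc$n_homB))
    ok <- ok + (segregation_test(pooled)$p > 0.001)
  }
  expect_gte(ok, 19)
})

test_that("RIL overlays behave: missing, miscalls, distortion, linkage", {
  cfg <- ril_sim_config(n_lines = 30, n_markers = 40, missing_rate = 1, seed = 41)
  expect_true(all(is.na(simulate_ril_population(cfg)$genotypes)))

  cfgd <- ril_sim_config(n_lines = 200, n_markers = 100, distorted_fraction = 0.5,
                         distortion_proportions = c(0, 1, 0), seed = 42)
  sim <- simulate_ril_population(cfgd)
  cc <- genotype_counts(sim)
  expect_equal(sum(cc$distorted), 50)
  expect_true(all(cc$n_het[cc$distorted] == 200))

  expect_error(ril_sim_config(distortion_proportions = c(0.5, 0.2, 0.2)),
               "summing to 1")
  expect_error(ril_sim_config(generation = 1), ">= 2")

  # linkage: adjacent markers are positively correlated; the marginal is
  # preserved (SE accounts for the chain's autocorrelation: two markers with
  # keep-probability 1 - 2r have genotype correlation about 1 - 2r)
  cfgl <- ril_sim_config(n_lines = 2000, n_markers = 2, linkage = 0.1, seed = 43)
  g <- simulate_ril_population(cfgl)$genotypes
  expect_gt(mean(g[1, ] == g[2, ]), 0.7) # keep prob 0.8 plus chance re-draws
  het <- mean(g == 1L)
  p <- 2 / 64
  se <- sqrt(p * (1 - p) * (1 + 0.8) / (2 * 2000))
  expect_lt(abs(het - p), 3 * se)
})

test_that("expression simulator responds to the specificity parameter", {
  # near-uniform limit
  cfg_hi <- expression_sim_config(c("1" = 100), n_tissues = 8,
                                  specificity = 1e6, seed = 51)
  ent_hi <- tissue_entropy(simulate_expression_families(cfg_hi)$expression)
  expect_lt(abs(mean(ent_hi$H) - 3), 0.01)

  # lower concentration -> strictly lower mean entropy
  mk <- function(s, seed) {
    cfg <- expression_sim_config(c("1" = 250), n_tissues = 8, specificity = s,
                                 seed = seed)
    mean(tissue_entropy(simulate_expression_families(cfg)$expression)$H)
  }
  expect_lt(mk(0.1, 52), mk(10, 52))

  # family bookkeeping
  cfg1 <- expression_sim_config(c("1" = 50), seed = 53)
  fam <- simulate_expression_families(cfg1)$families
  expect_equal(dplyr::n_distinct(fam$family_id), 50L)
  expect_true(all(table(fam$family_id) == 1))
  expect_error(expression_sim_config(c("2" = 5), n_tissues = 1), ">= 2")
  expect_error(expression_sim_config(c("2" = 5), specificity = 0), "> 0")
})

test_that("domain-table simulator emits ordered hits below the E-value cutoff", {
  arch <- list(list(domains = c("MATH", "BTB", "BACK"), n = 3))
  hits <- simulate_domain_table(arch, seed = 61)
  expect_equal(dplyr::n_distinct(hits$protein), 3L)
  by_prot <- split(hits, hits$protein)
  for (h in by_prot) {
    expect_equal(h$domain[order(h$start)], c("MATH", "BTB", "BACK"))
    expect_true(all(h$evalue <= 1e-5))
    expect_true(all(h$start <= h$end))
  }
  empty <- simulate_domain_table(list())
  expect_equal(nrow(empty), 0L)
  expect_named(empty, c("protein", "species", "domain", "start", "end", "evalue"))
  expect_error(simulate_domain_table(list(list(domains = "KELCH", n = 1))),
               "unknown domain")
})
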