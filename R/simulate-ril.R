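#' Configuration for simulating an F_g RIL genotype matrix
#'
#' Single-seed-descent selfing from a fully heterozygous F1: at generation
#' `g` the per-marker genotype expectation is
#' `((1 - h)/2, h, (1 - h)/2)` with `h = (1/2)^(g-1)` (31:2:31 at F6).
#' A configurable fraction of markers can instead segregate under an
#' alternative distribution (`distortion_proportions`), and missingness and
#' symmetric genotype miscalls are overlaid afterwards. Defaults mirror the
#' mapping population used for the broomcorn-millet genetic map: 132 F6
#' lines.
#'
#' @param n_lines Progeny lines (default 132).
#' @param n_markers Marker count.
#' @param generation Selfing generation `g` of F_g (>= 2; default 6).
#' @param missing_rate,error_rate Per-call rates in `[0, 1]`.
#' @param distorted_fraction Fraction of markers drawn from
#'   `distortion_proportions` instead of the F_g expectation.
#' @param distortion_proportions Length-3 genotype proportions (homA, het,
#'   homB) summing to 1.
#' @param linkage Optional recombination fraction between adjacent markers;
#'   when set, genotypes follow a stationary Markov chain along marker order
#'   (see the methods vignette). `NULL` = independent markers.
#' @param qual VCF QUAL per marker (scalar or length `n_markers`; default 999).
#' @param seed Optional integer seed.
#' @return A named list of class `ril_sim_config`.
#' @export
ril_sim_config <- function(n_lines = 132L, n_markers = 1000L, generation = 6L,
                           missing_rate = 0, error_rate = 0,
                           distorted_fraction = 0,
                           distortion_proportions = c(0.35, 0.30, 0.35),
                           linkage = NULL, qual = 999, seed = NULL) {
  if (generation < 2) abort("generation must be >= 2")
  rates <- c(missing_rate, error_rate, distorted_fraction)
  if (any(rates < 0 | rates > 1)) abort("rates must lie in [0, 1]")
  if (length(distortion_proportions) != 3L ||
      abs(sum(distortion_proportions) - 1) > 1e-12) {
    abort("distortion_proportions must be three proportions summing to 1")
  }
  if (!is.null(linkage) && (linkage < 0 || linkage > 0.5)) {
    abort("linkage recombination fraction must lie in [0, 0.5]")
  }
  structure(list(n_lines = n_lines, n_markers = n_markers,
                 generation = generation, missing_rate = missing_rate,
                 error_rate = error_rate, distorted_fraction = distorted_fraction,
                 distortion_proportions = distortion_proportions,
                 linkage = linkage, qual = qual, seed = seed),
            class = "ril_sim_config")
}

# Draw genotypes (0 = homA, 1 = het, 2 = homB) for one marker set.
draw_genotypes <- function(n_markers, n_lines, probs) {
  matrix(sample(0:2, n_markers * n_lines, replace = TRUE, prob = probs),
         nrow = n_markers)
}

#' Simulate an F_g RIL genotype matrix
#'
#' @param cfg A [ril_sim_config()].
#' @return List of class `ril_simulation`: `genotypes` (marker x line integer
#'   matrix, 0/1/2 with `NA` missing), `markers` tibble (`marker_id`,
#'   `chrom`, `pos`, `qual`, `distorted`), and the config.
#' @export
simulate_ril_population <- function(cfg) {
  stopifnot(inherits(cfg, "ril_sim_config"))
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  exp_null <- expected_genotype_proportions(cfg$generation)
  p0 <- c(exp_null$p_homA, exp_null$p_het, exp_null$p_homB)
  n_dist <- round(cfg$distorted_fraction * cfg$n_markers)
  distorted <- rep(FALSE, cfg$n_markers)
  if (n_dist > 0) distorted[sample.int(cfg$n_markers, n_dist)] <- TRUE

  if (is.null(cfg$linkage)) {
    g <- draw_genotypes(cfg$n_markers, cfg$n_lines, p0)
  } else {
    # stationary mixing chain: keep previous genotype w.p. 1 - min(1, 2r),
    # else redraw from the marginal; preserves the F_g marginal exactly
    mix <- min(1, 2 * cfg$linkage)
    g <- matrix(0L, cfg$n_markers, cfg$n_lines)
    g[1L, ] <- sample(0:2, cfg$n_lines, replace = TRUE, prob = p0)
    for (m in seq_len(cfg$n_markers)[-1L]) {
      redraw <- runif(cfg$n_lines) < mix
      g[m, ] <- ifelse(redraw,
                       sample(0:2, cfg$n_lines, replace = TRUE, prob = p0),
                       g[m - 1L, ])
    }
  }
  if (any(distorted)) {
    g[distorted, ] <- draw_genotypes(sum(distorted), cfg$n_lines,
                                     cfg$distortion_proportions)
  }
  # symmetric miscalls: relabel to each of the other two states w.p. error/2
  if (cfg$error_rate > 0) {
    err <- runif(length(g)) < cfg$error_rate
    if (any(err)) {
      shift <- sample(1:2, sum(err), replace = TRUE)
      g[err] <- (g[err] + shift) %% 3L
    }
  }
  if (cfg$missing_rate > 0) {
    g[runif(length(g)) < cfg$missing_rate] <- NA_integer_
  }
  markers <- tibble::tibble(
    marker_id = sprintf("M%05d", seq_len(cfg$n_markers)),
    chrom = "chr1",
    pos = 1000L * seq_len(cfg$n_markers),
    qual = rep_len(cfg$qual, cfg$n_markers),
    distorted = distorted
  )
  structure(list(genotypes = g, markers = markers, config = cfg),
            class = "ril_simulation")
}

#' Pool simulated genotype calls into per-marker counts
#'
#' @param sim A [simulate_ril_population()] result.
#' @return Tibble with `marker_id`, `n_homA`, `n_het`, `n_homB`, `n_missing`,
#'   `qual`, `distorted`.
#' @export
genotype_counts <- function(sim) {
  stopifnot(inherits(sim, "ril_simulation"))
  g <- sim$genotypes
  dplyr::mutate(sim$markers,
                n_homA = rowSums(g == 0L, na.rm = TRUE),
                n_het = rowSums(g == 1L, na.rm = TRUE),
                n_homB = rowSums(g == 2L, na.rm = TRUE),
                n_missing = rowSums(is.na(g)),
                .after = "marker_id")
}

#' Write a simulated RIL population as a plain-text VCF v4.2
#'
#' One biallelic SNP record per marker (`REF = A`, `ALT = G`), GT-only
#' FORMAT, genotypes `0/0`, `0/1`, `1/1`, `./.`, and the configured QUAL.
#'
#' @param sim A [simulate_ril_population()] result.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_ril_vcf <- function(sim, path) {
  stopifnot(inherits(sim, "ril_simulation"))
  gt_code <- c("0/0", "0/1", "1/1")
  g <- sim$genotypes
  gt <- matrix(gt_code[g + 1L], nrow = nrow(g))
  gt[is.na(g)] <- "./."
  samples <- sprintf("RIL%03d", seq_len(ncol(g)))
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=milletevol::write_ril_vcf",
    "##contig=<ID=chr1>",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t")
  )
  body <- paste(sim$markers$chrom, sim$markers$pos, sim$markers$marker_id,
                "A", "G", format(sim$markers$qual, trim = TRUE, scientific = FALSE),
                ".", ".", "GT",
                apply(gt, 1L, paste, collapse = "\t"), sep = "\t")
  writeLines(c(header, body), path)
  invisible(path)
}
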