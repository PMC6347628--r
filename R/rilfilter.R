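#' Expected genotype proportions of an F_g RIL marker
#'
#' Under single-seed-descent selfing from a fully heterozygous F1 with no
#' selection, heterozygosity halves each generation:
#' `p_het = (1/2)^(g-1)` and the two homozygote classes share the remainder
#' equally. At F6 this is the 31:2:31 expectation used for the
#' broomcorn-millet genetic map.
#'
#' @param generation Integer `g` of F_g, `>= 2`.
#' @return One-row tibble with `generation`, `p_homA`, `p_het`, `p_homB`.
#' @examples
#' expected_genotype_proportions(6) # 31/64, 2/64, 31/64
#' @export
expected_genotype_proportions <- function(generation) {
  if (length(generation) != 1L || !is.finite(generation) || generation < 2 ||
      generation != round(generation)) {
    abort("generation must be a single integer >= 2")
  }
  p_het <- 0.5^(generation - 1)
  p_hom <- (1 - p_het) / 2
  tibble::tibble(generation = as.integer(generation),
                 p_homA = p_hom, p_het = p_het, p_homB = p_hom)
}

#' Chi-squared segregation test of observed genotype counts
#'
#' Pearson chi-squared goodness of fit (df = 2, no continuity correction) of
#' observed genotype counts against an F_g expectation; expected counts are
#' the expectation proportions times the non-missing total. For df = 2 the
#' upper-tail probability has the closed form `p = exp(-chi2 / 2)`.
#'
#' Vectorised over markers.
#'
#' @param counts Tibble (or data frame) with columns `n_homA`, `n_het`,
#'   `n_homB`.
#' @param expectation An [expected_genotype_proportions()] row.
#' @return The input with `n_tested`, `chi2`, `df`, `p` appended.
#' @export
segregation_test <- function(counts, expectation = expected_genotype_proportions(6)) {
  counts <- tibble::as_tibble(counts)
  n <- counts$n_homA + counts$n_het + counts$n_homB
  if (any(n < 1)) abort("untestable marker: all genotype calls missing")
  probs <- c(expectation$p_homA, expectation$p_het, expectation$p_homB)
  chi2 <- (counts$n_homA - n * probs[1])^2 / (n * probs[1]) +
    (counts$n_het - n * probs[2])^2 / (n * probs[2]) +
    (counts$n_homB - n * probs[3])^2 / (n * probs[3])
  dplyr::mutate(counts, n_tested = n, chi2 = chi2, df = 2L,
                p = pchisq(chi2, df = 2, lower.tail = FALSE))
}

#' Marker filter criteria for RIL genetic-map construction
#'
#' The three-criterion SNP pre-filter: (a) progeny missing-call fraction
#' strictly below `max_missing`; (b) chi-squared segregation p strictly
#' above `min_p` against the F_g expectation; (c) variant QUAL at least
#' `min_qual` (inclusive). Only biallelic single-base SNPs are eligible.
#'
#' @param max_missing Maximum progeny missing fraction (strict; default 0.20).
#' @param min_p Minimum segregation p (strict; default 1e-5).
#' @param min_qual Minimum VCF QUAL (inclusive; default 999).
#' @param require_biallelic Require exactly one single-base ALT (default TRUE).
#' @return A named list of class `filter_criteria`.
#' @export
filter_criteria <- function(max_missing = 0.20, min_p = 1e-5, min_qual = 999,
                            require_biallelic = TRUE) {
  if (max_missing < 0 || max_missing > 1) abort("max_missing must lie in [0, 1]")
  structure(list(max_missing = max_missing, min_p = min_p, min_qual = min_qual,
                 require_biallelic = require_biallelic),
            class = "filter_criteria")
}

# Parse a GT matrix (vcfR style, possibly with :-separated extra fields)
# into 0/1/2/NA codes. Heterozygote = two distinct alleles; phasing ignored.
parse_gt_codes <- function(gt) {
  core <- sub(":.*$", "", gt)
  core <- gsub("\\|", "/", core)
  code <- rep(NA_integer_, length(core))
  code[core %in% c("0/0")] <- 0L
  code[core %in% c("0/1", "1/0")] <- 1L
  code[core %in% c("1/1")] <- 2L
  matrix(code, nrow = nrow(gt), dimnames = dimnames(gt))
}

#' Filter RIL SNP markers by the three-criterion rule
#'
#' Reads a VCF, computes per-marker progeny genotype counts (parents, if
#' named, are excluded from all progeny statistics), applies the
#' biallelic-SNP, missing-rate, segregation and quality criteria, and
#' optionally writes the passing records to a filtered VCF with input lines
#' preserved verbatim. Markers whose progeny calls are all missing are
#' untestable by criterion (b); they are tallied separately and necessarily
#' fail the missing-rate criterion.
#'
#' @param vcf_path Path to a VCF (v4.2, GT genotypes).
#' @param criteria A [filter_criteria()].
#' @param expectation An [expected_genotype_proportions()] row (default F6).
#' @param parent_ids Optional character vector of parent sample IDs to
#'   exclude from progeny statistics (error if absent from the VCF).
#' @param out_vcf Optional path for the filtered VCF.
#' @return An object of class `ril_filter_report`: list with `markers`
#'   (per-marker tibble incl. counts, `chi2`, `p` and per-criterion pass
#'   flags), `summary` (one-row tally tibble), `criteria`.
#' @export
filter_markers <- function(vcf_path, criteria = filter_criteria(),
                           expectation = expected_genotype_proportions(6),
                           parent_ids = NULL, out_vcf = NULL) {
  stopifnot(inherits(criteria, "filter_criteria"))
  if (!file.exists(vcf_path)) abort(paste0("cannot read VCF: ", vcf_path))
  vcf <- vcfR::read.vcfR(vcf_path, verbose = FALSE)
  fix <- tibble::as_tibble(as.data.frame(vcfR::getFIX(vcf), stringsAsFactors = FALSE))
  gt_raw <- vcfR::extract.gt(vcf, element = "GT")
  if (!is.null(parent_ids)) {
    absent <- setdiff(parent_ids, colnames(gt_raw))
    if (length(absent)) {
      abort(paste0("named parent sample(s) absent from VCF: ",
                   paste(absent, collapse = ", ")))
    }
    gt_raw <- gt_raw[, setdiff(colnames(gt_raw), parent_ids), drop = FALSE]
  }
  codes <- parse_gt_codes(gt_raw)
  n_prog <- ncol(codes)
  qual <- suppressWarnings(as.numeric(fix$QUAL))

  markers <- tibble::tibble(
    marker_id = fix$ID,
    chrom = fix$CHROM,
    pos = suppressWarnings(as.integer(fix$POS)),
    qual = qual,
    n_homA = unname(rowSums(codes == 0L, na.rm = TRUE)),
    n_het = unname(rowSums(codes == 1L, na.rm = TRUE)),
    n_homB = unname(rowSums(codes == 2L, na.rm = TRUE)),
    n_missing = unname(rowSums(is.na(codes)))
  )
  single_base <- function(x) !is.na(x) & nchar(x) == 1L & x %in% BASES
  markers$biallelic <- single_base(fix$REF) & single_base(fix$ALT)
  markers$missing_frac <- markers$n_missing / n_prog
  n_called <- markers$n_homA + markers$n_het + markers$n_homB
  markers$untestable <- n_called == 0L
  markers$chi2 <- NA_real_
  markers$p <- NA_real_
  testable <- !markers$untestable
  if (any(testable)) {
    st <- segregation_test(markers[testable, c("n_homA", "n_het", "n_homB")],
                           expectation)
    markers$chi2[testable] <- st$chi2
    markers$p[testable] <- st$p
  }
  markers$pass_biallelic <- if (criteria$require_biallelic) markers$biallelic else TRUE
  markers$pass_missing <- markers$missing_frac < criteria$max_missing
  markers$pass_segregation <- !markers$untestable & markers$p > criteria$min_p
  # untestable markers are not counted against criterion (b)
  markers$pass_segregation[markers$untestable] <- TRUE
  markers$pass_quality <- !is.na(markers$qual) & markers$qual >= criteria$min_qual
  markers$pass <- markers$pass_biallelic & markers$pass_missing &
    markers$pass_segregation & markers$pass_quality

  summary <- tibble::tibble(
    n_markers = nrow(markers),
    n_progeny = n_prog,
    n_pass = sum(markers$pass),
    fail_biallelic = sum(!markers$pass_biallelic),
    fail_missing = sum(!markers$pass_missing),
    fail_segregation = sum(!markers$pass_segregation),
    fail_quality = sum(!markers$pass_quality),
    n_untestable = sum(markers$untestable)
  )
  if (!is.null(out_vcf)) {
    lines <- readLines(vcf_path)
    header <- grepl("^#", lines)
    body <- lines[!header]
    if (length(body) != nrow(markers)) {
      abort("VCF record count does not match parsed marker count")
    }
    writeLines(c(lines[header], body[markers$pass]), out_vcf)
  }
  structure(list(markers = markers, summary = summary, criteria = criteria,
                 expectation = expectation),
            class = "ril_filter_report")
}

#' @export
tidy.ril_filter_report <- function(x, ...) x$markers

#' @export
glance.ril_filter_report <- function(x, ...) x$summary

#' @export
print.ril_filter_report <- function(x, ...) {
  s <- x$summary
  cat("RIL marker filter report\n")
  cat(sprintf("  markers: %d (progeny: %d)\n", s$n_markers, s$n_progeny))
  cat(sprintf("  passing: %d (%.1f%%)\n", s$n_pass, 100 * s$n_pass / max(1, s$n_markers)))
  cat(sprintf("  failing biallelic/missing/segregation/quality: %d / %d / %d / %d\n",
              s$fail_biallelic, s$fail_missing, s$fail_segregation, s$fail_quality))
  invisible(x)
}
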