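# Shannon entropy in bits of a non-negative profile; 0*log2(0) = 0.
shannon_entropy <- function(x) {
  total <- sum(x)
  if (total == 0) return(NA_real_)
  p <- x[x > 0] / total
  -sum(p * log2(p))
}

#' Tissue-specificity Shannon entropy per gene
#'
#' For each gene, expression values across tissues are normalised to
#' proportions and the Shannon entropy (base 2) is computed; low entropy
#' means tissue-specific expression, the maximum `log2(n_tissues)` means a
#' uniform profile. Genes with zero total expression get `defined = FALSE`.
#'
#' @param expr Tibble with a `gene` column and one numeric column per
#'   tissue (all values non-negative).
#' @param gene_col Name of the gene identifier column (default `"gene"`).
#' @return Tibble (`gene`, `total`, `H`, `defined`).
#' @examples
#' expr <- tibble::tibble(gene = "g1", t1 = 1, t2 = 1, t3 = 1, t4 = 1)
#' tissue_entropy(expr) # H = 2 bits
#' @export
tissue_entropy <- function(expr, gene_col = "gene") {
  expr <- tibble::as_tibble(expr)
  if (!gene_col %in% names(expr)) abort(paste0("missing column: ", gene_col))
  m <- as.matrix(expr[setdiff(names(expr), gene_col)])
  if (ncol(m) < 2) abort("at least 2 tissue columns are required")
  if (!is.numeric(m) || any(!is.finite(m)) || any(m < 0)) {
    abort("expression values must be finite and non-negative")
  }
  h <- apply(m, 1L, shannon_entropy)
  tibble::tibble(gene = expr[[gene_col]], total = rowSums(m), H = h,
                 defined = !is.na(h))
}

#' Per-family-size summaries of expression entropy and magnitude
#'
#' Joins per-gene entropies onto a family assignment and summarises each
#' copy-number class: number of families, mean per-gene entropy (over
#' defined genes) and mean per-gene total expression. Genes in the family
#' table but absent from the matrix are logged and skipped; zero-expression
#' genes are excluded from `mean_H` and tallied in `n_undefined`.
#'
#' @param expr Expression tibble as in [tissue_entropy()].
#' @param families Tibble (`gene`, `family_id`).
#' @param gene_col Gene identifier column name.
#' @return Tibble (`size_class`, `n_families`, `n_genes`, `mean_H`,
#'   `mean_expression`, `n_undefined`) sorted by size class.
#' @export
family_size_summaries <- function(expr, families, gene_col = "gene") {
  families <- tibble::as_tibble(families)
  if (nrow(families) == 0L) abort("empty family assignment")
  ent <- tissue_entropy(expr, gene_col)
  missing <- setdiff(families$gene, ent$gene)
  if (length(missing)) {
    inform(paste0("skipped ", length(missing),
                  " gene(s) in families but absent from the expression matrix"))
    families <- families[!families$gene %in% missing, , drop = FALSE]
  }
  dplyr::inner_join(families, ent, by = setNames("gene", "gene")) |>
    dplyr::group_by(.data$family_id) |>
    dplyr::mutate(size_class = dplyr::n()) |>
    dplyr::ungroup() |>
    dplyr::group_by(.data$size_class) |>
    dplyr::summarise(
      n_families = dplyr::n_distinct(.data$family_id),
      n_genes = dplyr::n(),
      mean_H = mean(.data$H[.data$defined]),
      mean_expression = mean(.data$total),
      n_undefined = sum(!.data$defined),
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$size_class)
}

#' Two-proportion z test (pooled, with continuity correction)
#'
#' Pooled-proportion z statistic for `k1/n1` vs `k2/n2` with a Yates-style
#' continuity correction of `(1/n1 + 1/n2)/2` applied to the absolute
#' difference (never past zero); the two-tailed p comes from the normal
#' tail. `correct = FALSE` gives the uncorrected pooled z.
#'
#' @param k1,n1,k2,n2 Successes and totals of the two samples.
#' @param correct Apply the continuity correction? Default `TRUE`.
#' @return One-row tibble (`estimate1`, `estimate2`, `z`, `p`).
#' @export
two_proportion_test <- function(k1, n1, k2, n2, correct = TRUE) {
  if (n1 < 1 || n2 < 1) abort("both sample sizes must be >= 1")
  if (k1 < 0 || k1 > n1 || k2 < 0 || k2 > n2) abort("counts must satisfy 0 <= k <= n")
  p1 <- k1 / n1
  p2 <- k2 / n2
  pooled <- (k1 + k2) / (n1 + n2)
  se <- sqrt(pooled * (1 - pooled) * (1 / n1 + 1 / n2))
  d <- abs(p1 - p2)
  if (correct) d <- max(0, d - (1 / n1 + 1 / n2) / 2)
  z <- if (se == 0) 0 else sign(p1 - p2) * d / se
  tibble::tibble(estimate1 = p1, estimate2 = p2, z = z,
                 p = if (se == 0) 1 else 2 * pnorm(-abs(z)))
}

#' Two-sided Fisher exact p for a 2x2 enrichment table
#'
#' Exact hypergeometric two-sided p under the standard convention: the sum
#' of probabilities of all tables (same margins) whose probability does not
#' exceed the observed table's. Parameterised by enrichment counts:
#' `k_study` of `n_study` study genes carry the term, `k_pop` of `n_pop`
#' population genes do.
#'
#' Vectorised over its arguments.
#'
#' @param k_study,n_study,k_pop,n_pop Counts with
#'   `0 <= k_study <= n_study <= n_pop` and `k_study <= k_pop <= n_pop`.
#' @return Numeric vector of two-sided p values.
#' @export
fisher_exact2 <- function(k_study, n_study, k_pop, n_pop) {
  args <- data.frame(k_study, n_study, k_pop, n_pop)
  bad <- args$k_study < 0 | args$k_study > args$n_study |
    args$k_pop > args$n_pop | args$k_study > args$k_pop |
    args$n_study > args$n_pop |
    (args$k_pop - args$k_study) > (args$n_pop - args$n_study)
  if (any(bad)) abort("inconsistent 2x2 enrichment counts")
  mapply(function(x, n, K, N) {
    lo <- max(0L, n + K - N)
    hi <- min(n, K)
    probs <- dhyper(lo:hi, K, N - K, n)
    obs <- dhyper(x, K, N - K, n)
    sum(probs[probs <= obs * (1 + 1e-7)])
  }, args$k_study, args$n_study, args$k_pop, args$n_pop)
}

#' Benjamini-Hochberg adjusted p values
#'
#' Step-up false-discovery-rate adjustment: with p sorted ascending,
#' `adj_i = min over j >= i of p_j * m / j`, capped at 1.
#'
#' @param p Numeric vector of raw p values.
#' @return Adjusted p values in the input order.
#' @export
adjust_bh <- function(p) p.adjust(p, method = "BH")

#' Fisher + Benjamini-Hochberg term enrichment
#'
#' For each term, builds the 2x2 table of in-study/in-term membership
#' against the population, computes the two-sided Fisher exact p
#' ([fisher_exact2()]) and BH-adjusts across terms.
#'
#' @param terms Tibble (`term`, `gene`) mapping terms to population genes.
#' @param study Character vector of study genes (must be a subset of
#'   `population`).
#' @param population Character vector of population genes.
#' @return Tibble (`term`, `k_study`, `n_study`, `k_pop`, `n_pop`, `p_raw`,
#'   `p_adj`) sorted by `p_adj` then term.
#' @export
fisher_bh_enrichment <- function(terms, study, population) {
  terms <- tibble::as_tibble(terms)
  study <- unique(study)
  population <- unique(population)
  if (!all(study %in% population)) {
    abort("study genes must be a subset of the population")
  }
  terms <- terms[terms$gene %in% population, , drop = FALSE]
  out <- terms |>
    dplyr::group_by(term = .data$term) |>
    dplyr::summarise(k_study = sum(.data$gene %in% study),
                     k_pop = dplyr::n_distinct(.data$gene),
                     .groups = "drop") |>
    dplyr::mutate(n_study = length(study), n_pop = length(population))
  if (nrow(out) == 0L) {
    return(tibble::tibble(term = character(), k_study = integer(),
                          n_study = integer(), k_pop = integer(),
                          n_pop = integer(), p_raw = double(), p_adj = double()))
  }
  out$p_raw <- fisher_exact2(out$k_study, out$n_study, out$k_pop, out$n_pop)
  out$p_adj <- adjust_bh(out$p_raw)
  dplyr::arrange(dplyr::select(out, "term", "k_study", "n_study", "k_pop",
                               "n_pop", "p_raw", "p_adj"),
                 .data$p_adj, .data$term)
}

#' Plot mean entropy against family copy number
#'
#' @param summaries A [family_size_summaries()] result.
#' @return A ggplot object.
#' @export
plot_entropy_by_size <- function(summaries) {
  ggplot2::ggplot(summaries, ggplot2::aes(x = factor(.data$size_class),
                                          y = .data$mean_H)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "gene-family copy number", y = "mean Shannon entropy (bits)") +
    ggplot2::theme_minimal()
}
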