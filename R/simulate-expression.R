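#' Configuration for simulating gene-family expression matrices
#'
#' Each gene's tissue profile is a draw from a symmetric Dirichlet
#' composition with concentration `specificity` (small values concentrate
#' expression in few tissues, i.e. low Shannon entropy; large values
#' approach a uniform profile), scaled by a log-normal magnitude. Family
#' sizes are configured as counts of families per copy-number class, so the
#' generator can produce data with or without the copy-number vs entropy
#' relationship depending on how `specificity` is varied across classes.
#'
#' @param family_sizes Named numeric vector: names are copy-number classes,
#'   values the number of families of that size (e.g. `c("2" = 100, "8" = 50)`).
#' @param n_tissues Number of tissues (>= 2; default 8, matching the eight
#'   tissues profiled for broomcorn millet).
#' @param specificity Dirichlet concentration (> 0). Either a scalar applied
#'   to all families or a named vector parallel to `family_sizes`.
#' @param magnitude_location,magnitude_scale Mean and sd of log total
#'   expression (natural log of an RPKM-like total).
#' @param seed Optional integer seed.
#' @return A named list of class `expression_sim_config`.
#' @export
expression_sim_config <- function(family_sizes, n_tissues = 8L, specificity = 1,
                                  magnitude_location = 3, magnitude_scale = 1,
                                  seed = NULL) {
  if (n_tissues < 2) abort("n_tissues must be >= 2")
  if (any(specificity <= 0)) abort("specificity must be > 0")
  sizes <- as.integer(names(family_sizes))
  if (any(is.na(sizes)) || any(sizes < 1)) {
    abort("family_sizes must be named by integer copy numbers >= 1")
  }
  if (length(specificity) > 1L && !setequal(names(specificity), names(family_sizes))) {
    abort("a vector specificity must be named like family_sizes")
  }
  structure(list(family_sizes = family_sizes, n_tissues = n_tissues,
                 specificity = specificity,
                 magnitude_location = magnitude_location,
                 magnitude_scale = magnitude_scale, seed = seed),
            class = "expression_sim_config")
}

rdirichlet <- function(n, alpha, k) {
  x <- matrix(rgamma(n * k, shape = alpha, rate = 1), nrow = n)
  x / rowSums(x)
}

#' Simulate a gene x tissue expression matrix with family structure
#'
#' @param cfg An [expression_sim_config()].
#' @return List of class `expression_simulation`: `expression` (tibble with
#'   `gene` + one column per tissue), `families` (tibble `gene`,
#'   `family_id`, `size_class`).
#' @export
simulate_expression_families <- function(cfg) {
  stopifnot(inherits(cfg, "expression_sim_config"))
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  classes <- names(cfg$family_sizes)
  fam <- list()
  for (cl in classes) {
    n_fam <- cfg$family_sizes[[cl]]
    if (n_fam == 0) next
    size <- as.integer(cl)
    fam[[cl]] <- tibble::tibble(
      family_id = rep(sprintf("fam_%s_%03d", cl, seq_len(n_fam)), each = size),
      size_class = size,
      spec = if (length(cfg$specificity) > 1L) cfg$specificity[[cl]] else cfg$specificity
    )
  }
  fam <- dplyr::bind_rows(fam)
  if (nrow(fam) == 0L) abort("family_sizes configured zero families")
  fam$gene <- sprintf("g%05d", seq_len(nrow(fam)))
  n_genes <- nrow(fam)
  profiles <- matrix(0, n_genes, cfg$n_tissues)
  for (s in unique(fam$spec)) {
    idx <- fam$spec == s
    profiles[idx, ] <- rdirichlet(sum(idx), s, cfg$n_tissues)
  }
  magnitude <- exp(rnorm(n_genes, cfg$magnitude_location, cfg$magnitude_scale))
  expr <- profiles * magnitude
  colnames(expr) <- sprintf("tissue%02d", seq_len(cfg$n_tissues))
  structure(list(
    expression = dplyr::bind_cols(tibble::tibble(gene = fam$gene),
                                  tibble::as_tibble(expr)),
    families = dplyr::select(fam, "gene", "family_id", "size_class")
  ), class = "expression_simulation")
}

# Vocabulary of recognised BTB-associated domains.
DOMAIN_VOCAB <- c("BTB", "MATH", "BACK", "NPH3", "TAZ", "TPR", "ANK",
                  "F5_F8", "PENT")

#' Simulate a protein domain-hit table with known architectures
#'
#' Emits per-protein domain hits whose coordinates respect the requested
#' left-to-right domain order, with E-values drawn below the cutoff, for use
#' as a classifier fixture with exactly known subgroup counts.
#'
#' @param architectures A list whose elements are lists with fields
#'   `domains` (character vector of labels from the module vocabulary),
#'   `n` (number of proteins with this architecture) and optionally
#'   `species` (default `"P_miliaceum"`).
#' @param seed Optional integer seed.
#' @param evalue_cutoff Upper bound for simulated E-values (default 1e-5).
#' @return Tibble (`protein`, `species`, `domain`, `start`, `end`, `evalue`);
#'   empty architectures list gives an empty tibble with the same columns.
#' @export
simulate_domain_table <- function(architectures, seed = NULL, evalue_cutoff = 1e-5) {
  if (!is.null(seed)) set.seed(seed)
  empty <- tibble::tibble(protein = character(), species = character(),
                          domain = character(), start = integer(),
                          end = integer(), evalue = double())
  if (length(architectures) == 0L) return(empty)
  rows <- list()
  p <- 0L
  for (arch in architectures) {
    domains <- arch$domains
    unknown <- setdiff(domains, DOMAIN_VOCAB)
    if (length(unknown)) {
      abort(paste0("unknown domain label(s): ", paste(unknown, collapse = ", ")))
    }
    species <- arch$species %||% "P_miliaceum"
    for (i in seq_len(arch$n)) {
      p <- p + 1L
      width <- sample(60:120, length(domains), replace = TRUE)
      gap <- sample(5:30, length(domains), replace = TRUE)
      start <- cumsum(gap + c(0L, head(width, -1L)))
      rows[[length(rows) + 1L]] <- tibble::tibble(
        protein = sprintf("prot%04d", p),
        species = species,
        domain = domains,
        start = as.integer(start),
        end = as.integer(start + width - 1L),
        evalue = runif(length(domains), 0, evalue_cutoff)
      )
    }
  }
  dplyr::bind_rows(rows)
}
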