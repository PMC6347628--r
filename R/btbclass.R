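#' Filter protein domain hits by E-value and merge overlaps
#'
#' Keeps hits with `evalue <= evalue_cutoff` (inclusive boundary), merges
#' overlapping hits of the same domain on the same protein into the union
#' interval (minimum E-value retained), and drops proteins left without a
#' BTB hit from downstream classification with a logged count.
#'
#' @param hits Tibble (`protein`, `species`, `domain`, `start`, `end`,
#'   `evalue`).
#' @param evalue_cutoff Inclusive E-value threshold (default 1e-5).
#' @return The filtered, merged hit tibble.
#' @export
filter_domain_hits <- function(hits, evalue_cutoff = 1e-5) {
  hits <- tibble::as_tibble(hits)
  if (nrow(hits) &&
      (any(!is.finite(hits$start)) || any(!is.finite(hits$end)) ||
       any(hits$start < 1) || any(hits$start > hits$end))) {
    abort("malformed hit coordinates: need 1 <= start <= end")
  }
  input_proteins <- unique(hits$protein)
  hits <- hits[hits$evalue <= evalue_cutoff, , drop = FALSE]
  if (nrow(hits) == 0L) {
    if (length(input_proteins)) {
      inform(paste0("dropped ", length(input_proteins),
                    " protein(s) without a qualifying BTB hit"))
    }
    return(hits)
  }
  # union of overlapping same-protein same-domain intervals
  hits <- hits |>
    dplyr::group_by(.data$protein, .data$species, .data$domain) |>
    dplyr::arrange(.data$start, .data$end, .by_group = TRUE) |>
    dplyr::mutate(new_run = cumsum(c(TRUE, .data$start[-1] > cummax(.data$end)[-dplyr::n()]))) |>
    dplyr::group_by(.data$new_run, .add = TRUE) |>
    dplyr::summarise(start = min(.data$start), end = max(.data$end),
                     evalue = min(.data$evalue), .groups = "drop") |>
    dplyr::select(-"new_run")
  with_btb <- unique(hits$protein[hits$domain == "BTB"])
  dropped <- setdiff(input_proteins, with_btb)
  if (length(dropped)) {
    inform(paste0("dropped ", length(dropped),
                  " protein(s) without a qualifying BTB hit"))
    hits <- hits[hits$protein %in% with_btb, , drop = FALSE]
  }
  dplyr::arrange(hits, .data$protein, .data$start, .data$end, .data$domain)
}

#' Classify an ordered domain-label sequence into a BTB subgroup
#'
#' The subgroup is the hyphen-joined sequence of recognised domain labels in
#' left-to-right order with consecutive duplicates collapsed (two tandem
#' BTBs still read "BTB"). Labels outside the vocabulary map to `other`,
#' and any architecture containing `other` reports as `"BTB-other"`. At
#' least one BTB label must be present.
#'
#' @param domains Character vector of domain labels ordered by start
#'   coordinate.
#' @return A single subgroup label.
#' @examples
#' classify_architecture(c("MATH", "BTB", "BACK")) # "MATH-BTB-BACK"
#' @export
classify_architecture <- function(domains) {
  if (!length(domains) || !any(domains == "BTB")) {
    abort("architecture must contain at least one BTB domain")
  }
  labels <- ifelse(domains %in% DOMAIN_VOCAB, domains, "other")
  if (any(labels == "other")) return("BTB-other")
  keep <- c(TRUE, labels[-1] != labels[-length(labels)])
  paste(labels[keep], collapse = "-")
}

#' Per-protein domain architectures and subgroup labels
#'
#' Orders each protein's filtered hits by start coordinate (ties by end,
#' then label) and assigns the subgroup via [classify_architecture()].
#'
#' @param hits A [filter_domain_hits()] result.
#' @return Tibble (`protein`, `species`, `architecture`, `subgroup`) where
#'   `architecture` is the comma-joined ordered label sequence.
#' @export
architecture_table <- function(hits) {
  hits <- tibble::as_tibble(hits)
  if (nrow(hits) == 0L) {
    return(tibble::tibble(protein = character(), species = character(),
                          architecture = character(), subgroup = character()))
  }
  hits |>
    dplyr::group_by(.data$protein, .data$species) |>
    dplyr::arrange(.data$start, .data$end, .data$domain, .by_group = TRUE) |>
    dplyr::summarise(architecture = paste(.data$domain, collapse = ","),
                     subgroup = classify_architecture(.data$domain),
                     .groups = "drop")
}

#' Subgroup-by-species copy numbers with expansion flags
#'
#' Counts classified proteins per (subgroup, species) and flags a subgroup
#' as expanded in the focal species when its focal copy number is at least
#' `fold` times the maximum count among the other species and at least 1.
#' When every other species has zero copies, any focal copy flags.
#'
#' @param architectures An [architecture_table()] result.
#' @param focal_species Focal species label (must be present).
#' @param fold Expansion fold threshold (default 2).
#' @return Tibble with `subgroup`, one count column per species,
#'   `max_other`, and `expanded` (logical), sorted by subgroup.
#' @export
copy_number_table <- function(architectures, focal_species, fold = 2) {
  architectures <- tibble::as_tibble(architectures)
  species <- sort(unique(architectures$species))
  if (length(species) < 2L) abort("at least 2 species are required")
  if (!focal_species %in% species) {
    abort(paste0("focal species absent from data: ", focal_species))
  }
  counts <- architectures |>
    dplyr::count(.data$subgroup, .data$species) |>
    tidyr::pivot_wider(names_from = "species", values_from = "n",
                       values_fill = 0L)
  others <- setdiff(species, focal_species)
  counts$max_other <- do.call(pmax, c(as.list(counts[others]), list(0L)))
  counts$expanded <- counts[[focal_species]] >= fold * counts$max_other &
    counts[[focal_species]] >= 1L
  dplyr::arrange(counts, .data$subgroup)
}

#' Plot subgroup copy numbers across species
#'
#' @param counts A [copy_number_table()] result.
#' @return A ggplot object (grouped bar chart; expanded subgroups outlined).
#' @export
plot_subgroup_counts <- function(counts) {
  long <- tidyr::pivot_longer(
    dplyr::select(counts, -"max_other"),
    cols = -c("subgroup", "expanded"),
    names_to = "species", values_to = "copies")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$subgroup, y = .data$copies,
                                     fill = .data$species)) +
    ggplot2::geom_col(position = "dodge",
                      ggplot2::aes(colour = .data$expanded), linewidth = 0.4) +
    ggplot2::scale_colour_manual(values = c(`TRUE` = "red", `FALSE` = NA),
                                 na.value = NA, guide = "none") +
    ggplot2::labs(x = "BTB subgroup", y = "gene copies") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
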