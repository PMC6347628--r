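Package: milletevol
Title: Paralog Divergence Dating and Comparative-Genomics Statistics for
    Allotetraploid Grass Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the comparative-genomics statistics used in
    allotetraploid grass genome projects such as broomcorn millet (Panicum
    miliaceum): fourfold-degenerate transversion (4DTv) distances between
    aligned coding-sequence pairs, kernel-density mode detection and linear
    molecular-clock dating of whole-genome-duplication peaks, chi-squared
    segregation filtering of recombinant-inbred-line (RIL) SNP markers,
    Shannon-entropy tissue-specificity summaries of gene families with
    two-proportion and Fisher/Benjamini-Hochberg enrichment tests, and
    classification of BTB-domain proteins into subgroups by domain
    architecture with lineage-specific expansion flags. A full set of
    seeded synthetic-data generators with known ground truth makes every
    stage testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    vcfR
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
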