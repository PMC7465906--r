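Package: regionstrat
Title: Phylostratigraphy of Mutation-Hotspot Regions in Disordered Proteins
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Dates the evolutionary origin of cancer mutation-hotspot regions
    at gene and sub-gene resolution from event-annotated gene trees.
    Provides readers for NHX gene trees with duplication/speciation
    annotations, a built-in progressive protein aligner with affine gaps,
    a mutation-weighted BLOSUM62 conservation statistic that decides
    whether a region is conserved in each homolog, position-specific
    profile scanning as a second line of evidence, region-age assignment
    on a nested taxonomy ladder, classification of the emergence mechanism
    (duplication-induced neofunctionalization versus de novo) and of the
    post-emergence fate across later duplications, and mapping of
    positive-selection sites onto regions and hotspots. A synthetic
    gene-family generator with planted ground truth makes the whole
    pipeline testable without database downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    stringr,
    readr,
    jsonlite,
    generics,
    ggplot2,
    stats,
    utils,
    withr,
    Biostrings,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
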