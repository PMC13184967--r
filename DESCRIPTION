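Package: ecoassembly
Title: Null-Model Partitioning of Microbial Community Assembly from Dense
    Time Series
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Quantitative tools for dissecting the ecological processes that
    structure microbial communities sampled as replicated treatment-by-time
    series. Implements phylogenetic (betaMNTD/betaNTI) and taxonomic
    (Raup-Crick on Bray-Curtis) null models with a five-way process
    classification, abundance-stratified (main/rare subcommunity)
    re-analysis, standardized effect sizes of mean pairwise phylogenetic
    distance, indicator species analysis, and time-delayed local similarity
    networks with permutation significance. A synthetic community generator
    produces count tables, phylogenies and phylogenetically conserved traits
    under known assembly regimes (homogeneous and variable selection,
    dispersal limitation, homogenizing dispersal, drift) so every stage of
    the pipeline can be validated against planted ground truth.
License: MIT
Encoding: UTF-8
Imports:
    ape,
    jsonlite,
    Rcpp,
    stats,
    utils,
    vegan,
    yaml
LinkingTo:
    Rcpp
Suggests:
    biomformat,
    picante,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
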