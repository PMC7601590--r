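Package: ruminet
Title: Cross-Kingdom Co-Occurrence Networks for Rumen Microbiome Crossover Studies
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: An end-to-end statistical pipeline for paired fungal (ITS) and
    bacterial (16S) amplicon sequence variant (ASV) count tables from
    crossover grazing trials: compositional preprocessing (taxonomy and
    prevalence filtering, rarefaction, Bayesian-multiplicative zero
    replacement, centred log-ratio transform), alpha diversity with
    matched-pairs tests, constrained ordination (redundancy analysis and
    PERMANOVA), ensemble cross-kingdom co-occurrence network inference with a
    compositionality-aware permutation null, bootstrap stability filtering,
    Brown's method for merging dependent p-values and hub detection, and
    blocked permutation differential abundance.  A synthetic-data generator
    emulating the crossover design with planted fungus-bacterium couplings
    supports testing every stage without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    tools,
    utils,
    vegan,
    igraph,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    xml2
Config/testthat/edition: 3
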