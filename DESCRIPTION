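Package: mirmodnet
Title: Module Network Inference from Joint mRNA and microRNA Expression
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Infers regulatory module networks from expression matrices that
    mix messenger RNA and microRNA rows. An ensemble of Gibbs-sampled two-way
    (gene x condition) clusterings is averaged into a co-clustering frequency
    matrix, tight gene modules are extracted with a graph-spectral peeling
    method, and per-module regulatory programs are learned as fuzzy decision
    trees over condition clusters. Candidate regulators (transcription
    factors, signal transducers, microRNAs) are scored on their standardized
    expression only, so regulators measured on different absolute scales
    compete on equal footing; significance is judged against a
    randomly-assigned-regulator null. Includes a synthetic-data generator
    that plants modules, condition clusters, and direct and indirect
    regulators (routed through hidden intermediates) with full ground truth
    for recovery benchmarking, plus hypergeometric gene-set enrichment.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    mclust,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
Config/testthat/edition: 3
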