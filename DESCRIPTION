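Package: cbci
Title: Community-Based Collective Influence for Network Immunization
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Targeted immunization (network dismantling) by sequential node
    removal. Implements collective influence (CI) scoring with greedy
    reinsertion, and its community-based variant (CbCI) in which CI is
    computed on a weighted coarse-grained community network and allocated
    to nodes through their inter-community degree. Ships comparator
    strategies (adaptive degree, adaptive betweenness, community-based
    dynamical importance, Laplacian spectral partitioning), percolation
    style evaluation (largest-component curves, critical removal fraction,
    integrated largest-component size), partition diagnostics (entropy,
    modularity, clustering coefficients), synthetic generators
    (Barabasi-Albert and a scale-free model with built-in community
    structure), and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    igraph,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
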