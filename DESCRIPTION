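Package: reneel
Title: Reduced Network Extremal Ensemble Learning for Modularity
    Maximization
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Community detection in undirected networks by modularity
    maximization with an extremal ensemble learning scheme. An ensemble of
    partitions produced by a randomized greedy agglomerative base algorithm
    is iteratively improved: core groups of nodes that every ensemble
    partition places together are collapsed into a weighted reduced network,
    the reduced network is re-partitioned, and the ensemble is updated by
    extremal criteria until it reaches consensus on a single partition.
    Includes co-clustering diagnostics with simulated-annealing seriation of
    the node order, synthetic benchmark generators (planted partitions,
    rings of cliques), readers and writers for edge-list and METIS graph
    formats, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    dplyr,
    generics,
    ggplot2,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo:
    Rcpp
Suggests:
    igraph,
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
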