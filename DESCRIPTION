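Package: percolink
Title: Percolation Clustering Trajectories for Association Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Explore weighted association networks by edge percolation:
    admit edges in decreasing strength order through a union-find merge
    process and record the complete clustering trajectory, i.e. the
    isolated-subgraph structure at every possible strength cutoff.
    Provides per-threshold summary statistics (subgraph counts, sizes,
    densities, the relative size of the largest subgraph), a
    percolation-based optimal threshold chosen just before the giant
    component forms, random and planted-module network generators for
    null-model comparison, and JSON export of any clustering snapshot
    for downstream visualization.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    dplyr,
    generics,
    ggplot2,
    grDevices,
    jsonlite,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
LinkingTo: Rcpp
Suggests:
    igraph,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
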