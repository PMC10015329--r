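Package: sentinet
Title: Sentinel-Node Early Warning Signals for Multi-Stage Tipping
    Transitions on Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates coupled double-well stochastic dynamics on undirected
    networks over a quasi-static sweep of a bifurcation parameter, computes
    early warning signals (dominant covariance eigenvalue, node-level
    standard deviation and lag-1 autocorrelation) from configurable
    "sentinel" node sets, and scores each signal/node-set combination by
    Kendall rank correlation within stable parameter ranges. Includes
    model-network generators (configuration-model power law,
    Erdos-Renyi, planted communities), network file input/output, and a
    small command-line interface for end-to-end runs.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    igraph,
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
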