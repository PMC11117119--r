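Package: perturbflow
Title: Perturbative Analysis of Network-Dynamical Interactions on
    Structural Connectomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulates whole-brain node dynamics (a reduced Wong-Wang
    dynamic mean-field model and a linear stochastic model) on weighted
    undirected structural connectomes; applies clamped perturbations and
    functional lesions to compute the linear response matrix, net
    influence, and flow centrality; generates simulated BOLD signals with
    a Balloon-Windkessel forward model to fit the global coupling against
    an empirical functional-connectivity matrix; and summarizes node
    metrics over the seven canonical resting-state networks. Ships a
    synthetic connectome generator so all analyses can be exercised
    without external imaging data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    withr,
    testthat (>= 3.0.0),
    Matrix,
    pracma,
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
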