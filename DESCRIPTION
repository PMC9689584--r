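Package: ctbsi
Title: Continuous-Time Bayesian Structural Inference for Discrete-Event
    Processes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Inference, prediction, and entropy-rate estimation for
    continuous-time, discrete-event stochastic processes such as neural
    spike trains and animal behavior records.  Implements unifilar hidden
    semi-Markov models (epsilon-machines with state-specific dwell-time
    densities), maximum-likelihood fitting of candidate topologies with
    neural-network dwell-density estimation, BIC model selection,
    model-based and model-free differential entropy-rate estimators
    (Kozachenko-Leonenko k-nearest-neighbor entropy on trajectory
    ensembles), and a causal-state k-nearest-neighbor predictor of future
    symbols.  Ships simulators for the benchmark generators used in the
    package's validation experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
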