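Package: fanoreg
Title: Inferring Gene Autoregulation from Single-Cell Expression Dispersion
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Exact continuous-time Markov chain machinery and a decision
    procedure for inferring gene autoregulation from single-cell,
    non-interventional, one-time expression count data.  Provides
    product-form stationary solvers for birth-death chains, sparse exact
    solvers for multi-gene one-step chains, Gillespie stochastic
    simulation of birth-death, network, telegraph (bursting) and
    multi-step gene-cycle models, the variance-to-mean ratio (Fano
    factor) statistics with a Gamma null significance test, regulatory
    network topology predicates (ancestors, feedback loops), a
    ground-truth-labelled synthetic benchmark generator, and
    hypergeometric random-classifier comparisons for evaluation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    jsonlite,
    Matrix,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
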