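Package: burstrep
Title: Bursty Transcription and Repressor Kinetics for the Simple Repression Motif
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models of stochastic gene expression for the bacterial
    simple-repression motif. Provides the effective two-parameter fold-change
    theory onto which thermodynamic and kinetic promoter models collapse, a
    generic steady-state solver for finite promoter-state chemical master
    equations with single-transcript or geometric-burst production, closed-form
    steady-state mRNA distributions (Poisson, negative binomial, and the
    repressed bursty distribution built on a numerically stable Gauss
    hypergeometric evaluation), exact stochastic simulation of promoter models,
    synthetic single-cell mRNA-count study generation emulating smFISH designs,
    Bayesian inference of burst parameters and repressor binding/unbinding
    rates by ensemble MCMC, and posterior predictive ECDF model checking.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    MASS,
    coda,
    methods,
    stats,
    utils,
    yaml,
    Rcpp
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
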