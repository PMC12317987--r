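Package: ncreann
Title: Nonlinear Multivariate Autoregressive Directed Connectivity from
    Source Time Courses
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates linear and non-linear directed connectivity between
    source-level electrophysiological time courses with a neural-network
    realization of a nonlinear multivariate autoregressive (nMVAR) model.
    A one-hidden-layer perceptron trained by incremental error
    back-propagation with momentum, an adaptive learning rate and early
    stopping is decomposed into a linear part (via a first-order Taylor
    expansion) and a non-linear remainder, yielding unitless directed
    strengths lC and NC per region pair. Edge significance is assessed
    with time-shifted circular surrogates. The package also provides the
    surrounding analysis stages: band-pass filtering and epoching of
    multichannel series, VAR model-order selection by information
    criteria, neural-activity-index volumes with top-percentile
    thresholding and DBSCAN cluster extraction, repeated-measures
    behavioral statistics with Benjamini-Hochberg control, and a seeded
    synthetic-data generator with known ground-truth coupling for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    signal,
    nortest,
    jsonlite,
    yaml,
    Rcpp
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
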