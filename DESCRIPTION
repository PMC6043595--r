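Package: marshretreat
Title: Tidal-Marsh Retreat Risk from Holocene Sea-Level Tendencies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Infers the probability that a tidal marsh retreats (records a
    positive sea-level tendency) as a monotone function of the rate of
    relative sea-level rise, from databases of Holocene sea-level index
    points. Provides index-point database ingestion and filtering, rate
    assignment from coarse glacial-isostatic-adjustment relative sea-level
    curves by centered differencing, a Bayesian monotone cubic penalized
    B-spline Bernoulli model fitted by an adaptive Metropolis-within-Gibbs
    sampler, and coupling of the fitted probability curve with Monte Carlo
    sea-level projection ensembles to date future marsh vulnerability.
    Includes seed-deterministic synthetic-data generators for every
    pipeline stage.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    splines,
    stats,
    utils,
    tools,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
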