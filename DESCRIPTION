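Package: wcflux
Title: Weakly Supervised Normality Analysis of Whole-Cell Model Metabolic Fluxes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for metabolic reaction-flux time series produced
    by whole-cell-model gene-knockout simulations. Reduces each flux trajectory
    to linear-regression features, builds wild-type boundaries in a 2-D
    principal-component space to weakly label knockout behaviour as normal or
    abnormal, trains one multilayer-perceptron classifier per reaction on the
    weak labels, summarises each simulation as a binary flux profile, and
    interprets the profiles through the stoichiometric reaction network:
    driver nodes from maximum (or greedy maximal) matching, exponential noise
    thresholds for consistently abnormal reactions, per-class affected
    sub-networks, and phenotype markers scored by phi coefficients and linear
    separability. Includes a synthetic-data generator with known ground truth
    so the whole pipeline is testable at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    igraph,
    e1071,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
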