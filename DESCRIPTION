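Package: ouconv
Title: Detection and Quantification of Phenotypic Convergence on Phylogenies
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: A pipeline for detecting and measuring convergent evolution in
    continuous (landmark-derived) traits on time-calibrated phylogenies.
    Provides generalized Procrustes superimposition and principal component
    analysis of 2-D landmark configurations, branch-length-weighted
    squared-change parsimony reconstruction of ancestral states, stepwise
    forward/backward Ornstein-Uhlenbeck adaptive-regime search with AICc
    model comparison (Brownian motion, single-optimum, multi-regime and
    convergent-regime Hansen models), the distance-based convergence
    measures C1-C5 with Brownian-motion simulation nulls, the Wheatsheaf
    strength-of-convergence index with bootstrap inference, and a synthetic
    data generator (Yule trees, Brownian and Ornstein-Uhlenbeck trait
    simulation, landmark synthesis) so the whole pipeline is testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    ape,
    Matrix,
    jsonlite,
    Rcpp,
    grDevices,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
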