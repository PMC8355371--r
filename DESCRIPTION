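Package: dhpc
Title: Deep Hebbian Predictive Coding Networks for Modeling the Visual Cortical Hierarchy
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds, trains and analyzes deep Hebbian predictive coding (DHPC)
    networks: multi-area generative models of the visual cortical hierarchy in
    which higher areas send top-down predictions of lower-area activity through
    receptive-field-structured feedback weights, lower areas return prediction
    errors, and both inference (activity updates) and learning (weight updates)
    follow gated Hebbian rules performing gradient descent on squared prediction
    error with L1 regularization. Includes a fully connected variant for
    top-down image reconstruction, a seeded synthetic-image generator with
    naturalistic (1/f) statistics and two oriented-structure object classes, and
    a response-property analysis suite: kurtosis-based image selectivity and
    population sparseness, dynamic range, selectivity/dynamic-range ablations,
    activity correlations, area-wise Mann-Whitney comparisons and linear SVM
    readout of object class.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    e1071,
    png,
    yaml,
    jsonlite
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
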