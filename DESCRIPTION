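Package: shellmark
Title: Carapace Landmark Detection with Coordinate-Regression Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects the 37 named landmark points of the Chinese mitten crab
    (Eriocheir sinensis) carapace -- twelve marginal teeth, rear edge and the
    M-shaped neck groove -- from images, using three coordinate-regression
    strategies over a shared lightweight convolutional backbone: direct
    fully-connected regression, Gaussian-heatmap regression with argmax
    decoding, and a differentiable spatial-to-numerical transform (soft-argmax)
    head. Ships a procedural synthetic-carapace generator with exact ground
    truth, the four-transform augmentation protocol with landmark remapping,
    a loss suite (L1, Smooth L1, Wing, combined coordinate/heatmap loss),
    pooled MAE/MSE/R-squared evaluation, a seven-group parallel experiment
    design and per-network resource accounting. The convolutional engine
    (grouped and depthwise convolution, inverted residuals, global depthwise
    convolution, semantic embedding blocks, batch normalisation, Adam) is
    implemented in single-precision 'RcppArmadillo' code.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    generics,
    ggplot2,
    jsonlite,
    yaml,
    png
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
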