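Package: spectratraits
Title: Physiological Trait Prediction from Leaf Hyperspectral Reflectance
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Maps leaf hyperspectral reflectance spectra (400-2400 nm, 1 nm
    resolution) to ten wheat physiological traits (LMA, Narea, SPAD, Nmass,
    Vcmax, Vcmax25, J, A, gs, Vcmax25/Narea). Implements a dilated 1D
    convolutional neural network trained with multi-task masked mean-squared
    error, spectral-shift and spectral-trimming data augmentation, early
    stopping on a validation partition, and classical baselines (partial least
    squares regression, gradient-boosted trees, multilayer perceptron,
    bidirectional LSTM) plus a mean ensemble. Includes detector splice ("jump")
    correction for multi-detector spectroradiometers, CSV spectra input/output,
    reproducible train/validation/test partitioning, chemometrics evaluation
    metrics (R-squared, absolute percent bias, relative error of prediction),
    and a synthetic leaf-spectra generator with trait-linked optical features
    so the full pipeline is trainable and testable without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    Rcpp,
    mixOmics,
    xgboost
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
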