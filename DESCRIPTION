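Package: ppgnet
Title: PPG Scalogram Pipeline for Hypertension Stage Classification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end pipeline for classifying blood-pressure stages
    (normal, prehypertension, stage 1, stage 2) from single-channel
    photoplethysmography (PPG) segments. Provides adaptive wavelet
    denoising, equiripple (Parks-McClellan) FIR bandpass filtering and
    min-max normalization; analytic Morlet continuous-wavelet-transform
    scalogram images; SMOTE oversampling and majority undersampling with
    subject-aware train/test splitting and five-fold cross-validation; a
    compact depthwise-separable convolutional network (PPG-NET) with an
    SGD trainer and early stopping; a per-class and overall metric suite
    (accuracy, precision, sensitivity, specificity, F1); and a seeded
    synthetic PPG cohort generator so the whole pipeline is testable
    without access to clinical recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    grDevices,
    tools,
    png,
    EBImage,
    e1071,
    jsonlite,
    yaml,
    withr
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
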