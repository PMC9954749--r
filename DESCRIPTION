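Package: fabnet
Title: Feature-Agglomeration Networks for Patch-Based Histopathology Classification
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Implements a multi-branch feature-agglomeration convolutional
    network for hematoxylin-and-eosin (H&E) histopathology image
    classification, together with the full patch-based pipeline around it:
    Macenko stain normalization in optical-density space, class-balanced
    patch budgeting and seeded patch extraction, patient-aware cohort
    manifests with leakage-free train/test splits and cross-validation
    folds, a small from-scratch training engine (Adam, batch normalization,
    softmax cross-entropy) with compiled convolution kernels, and
    patch/image/patient-level evaluation metrics (accuracy, precision,
    recall, F1, ROC/AUC, confusion matrices). A seeded synthetic H&E image
    generator based on two-stain Beer-Lambert color mixing provides ground
    truth so the entire pipeline is testable without external datasets.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    yaml,
    png,
    stats,
    utils,
    graphics,
    grDevices,
    tools
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
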