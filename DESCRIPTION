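Package: dscradiomics
Title: Time-Dimension Radiomics of DSC Perfusion MRI for Ischemic Stroke
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing dynamic susceptibility contrast
    perfusion-weighted imaging (DSC-PWI) in the time dimension. The 4D
    series is decomposed into per-timepoint 3D images and a full
    radiomics vector (shape, first-order, texture-matrix, Laplacian-of-
    Gaussian and wavelet-filtered families) is computed per timepoint for
    hypoperfused and mirrored normal regions of interest. A bank of 13
    feature-selection methods (mutual-information, similarity,
    statistical and sparse-learning families), a ten-classifier
    cross-validation harness with a composite score, and a
    lesion-proportion classification experiment over a sliding volume
    threshold are included, together with a synthetic 4D perfusion
    phantom generator with ground-truth lesion masks so the whole
    pipeline is testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite,
    RNifti,
    glmnet,
    e1071,
    rpart,
    nnet,
    randomForest,
    xgboost,
    MASS,
    class,
    pROC
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
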