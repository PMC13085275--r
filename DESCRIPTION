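Package: cytodx
Title: Attention-Augmented Lightweight CNN Feature Fusion for Cervical Cytology
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A computer-aided diagnosis (CADx) toolkit for Pap-smear cervical
    cytology image classification. Implements multi-head self-attention modules
    inserted into lightweight convolutional backbones, dual deep-layer feature
    extraction (last pooling layer and self-attention layer), feature fusion by
    one-dimensional Haar discrete wavelet transform, cross-network ensembling
    with one-way ANOVA F-ratio feature selection, a seven-classifier evaluation
    harness under repeated stratified cross-validation (macro sensitivity,
    specificity, precision, F1, MCC, one-vs-rest ROC/AUC), and Grad-CAM
    explainability heatmaps. Ships a synthetic cytology fixture generator so the
    whole pipeline is testable without external image datasets.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    MASS,
    e1071,
    png,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
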