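Package: mammoband
Title: Subband-Descriptor CNN Pipelines for Mammogram Patch Classification
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Three-class (normal / benign / malignant) classification of
    128x128 mammogram patches via an end-to-end feature pipeline:
    eight-fold geometric augmentation, block-wise contrast-limited
    adaptive histogram equalization (CLAHE), one-level 2-D wavelet or
    frequency-wedge curvelet subband decomposition, dense SIFT
    descriptors per subband, six-statistic aggregation, weighted subband
    fusion, and a small convolutional network whose softmax head can be
    replaced by a linear SVM on the penultimate features. Includes a
    synthetic phantom generator so the whole pipeline is testable
    without clinical data, grouped stratified cross-validation that
    keeps augmented variants of a patch in one fold, and per-class
    one-vs-rest validity metrics (accuracy, PPV, NPV, sensitivity,
    specificity, MCC, ROC-AUC).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    e1071,
    jsonlite,
    png
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse,
    withr
Config/testthat/edition: 3
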