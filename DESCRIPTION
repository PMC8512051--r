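Package: imbfall
Title: Class-Imbalanced Fall Detection from Wearable Accelerometry with
    Residual Networks and Output-Threshold Moving
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for detecting falls in class-imbalanced tri-axial
    accelerometer data. Simulates wearable sensor trials with the
    free-fall/impact signature of real falls, segments them into labeled
    signal-magnitude-vector windows, fits a small 1D residual
    convolutional network classifier, and converts posterior
    probabilities into decisions with an imbalance-ratio-driven output
    threshold. Includes imbalance-aware evaluation (sensitivity,
    specificity, F-beta, ROC/AUC) and runnable alternatives for
    comparison: class-weighted loss, focal loss, and SMOTE oversampling.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    graphics,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
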