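Package: ramanEmbryo
Title: Raman Spectral Metabolomics of Spent Embryo Culture Medium
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Chemometric analysis of Raman spectra of spent (discarded) embryo
    culture medium for non-invasive prediction of pregnancy outcome after
    embryo transfer. Provides a synthetic cohort generator with known ground
    truth, a spectral preprocessing chain (cosmic-ray despiking, fingerprint
    band clipping, Savitzky-Golay smoothing, SNIP baseline correction, min-max
    normalization, PCA-Mahalanobis outlier screening), internal-standard
    amino-acid quantification against the phenylalanine 1003 cm-1 band,
    PCA feature extraction, sample-grouped train/test splitting with
    grid-search cross-validation over four classifier families (1D
    convolutional neural network, support vector machine, random forest,
    XGBoost), and full performance evaluation (confusion matrix, precision,
    recall, F1, ROC/AUC).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    signal,
    e1071,
    randomForest,
    xgboost,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr,
    yaml
Config/testthat/edition: 3
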