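Package: pdxmm
Title: Multimodal Drug Response Prediction for Patient-Derived Xenografts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for predicting binary drug response in patient-derived
    xenograft (PDX) cohorts from gene expression profiles, H&E histology
    whole-slide images, and molecular drug descriptors. Implements
    modified-RECIST response labeling from tumor-volume growth curves,
    landmark-gene and descriptor preprocessing, ROI-constrained tile
    extraction with Reinhard stain normalization, two drug-treatment
    augmentation schemes (homogenization of single-drug arms into pseudo
    drug-pairs and position-swap augmentation of drug pairs), leakage-safe
    grouped cross-validation splits, a family of multimodal and unimodal
    prediction models with tile-level training and sample-level aggregated
    evaluation, and imbalance-aware evaluation metrics (MCC, AUROC, AUPRC)
    with cross-split model comparison. A fully synthetic PDX cohort
    generator with planted, tunable signal makes the entire pipeline
    testable without access to any repository data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    jsonlite,
    png,
    tiff,
    mgcv,
    EBImage,
    xgboost
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC
Config/testthat/edition: 3
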