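Package: sonoclean
Title: Training-Set Cleaning and Soft-Label Enhancement for Ultrasound Lesion Classification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A data-enhancement toolkit for multiclass lesion classification from
    2-D ultrasound images. Implements leakage-free out-of-fold feature extraction
    over patient-grouped folds, consensus training-set cleaning with three anomaly
    detectors (Isolation Forest, Local Outlier Factor, One-Class SVM) merged by a
    unanimity rule, cluster-distance soft labels with an adjustable temperature,
    soft-target classifier training with AdamW, probability-weighted model
    ensembling with patient-level aggregation, and macro-AUC evaluation. Ships a
    deterministic synthetic ultrasound-like cohort generator with planted outliers
    so the full pipeline is testable without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    png,
    EBImage,
    e1071,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
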