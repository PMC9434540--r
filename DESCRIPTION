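Package: xrayid
Title: Patient Verification and Re-Identification for Chest Radiographs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Siamese convolutional networks for auditing the biometric
    content of frontal chest radiographs. Implements offline and online
    image-pair mining, a verification model that scores whether two
    radiographs depict the same patient, a metric-learning retrieval model
    trained with a contrastive loss, cross-batch memory and a 1cycle
    learning-rate policy, and the full evaluation suite: confusion-derived
    statistics, ROC/AUC with bootstrap confidence intervals, subgroup
    true-positive-rate analyses, mAP@R, R-Precision and Precision@1, and
    gradient-weighted class-activation attention maps. A synthetic chest
    phantom generator produces identity-structured cohorts with realistic
    acquisition nuisance so the whole pipeline can be exercised at desk
    scale on one CPU.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    EBImage,
    png,
    jpeg,
    jsonlite,
    yaml,
    stats,
    utils,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
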