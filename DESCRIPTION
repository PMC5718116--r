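Package: hccradiomics
Title: Radiomic Texture Features and Outcome Modelling for Hepatocellular
    Carcinoma Radiotherapy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Extraction of three-dimensional radiomic features (shape,
    intensity histogram, grey-level co-occurrence, run-length, zone-length
    and neighbourhood grey-level difference families) from planning-CT
    volumes with binary target masks, followed by mobile-threshold
    univariate screening against binary local-control and right-censored
    survival endpoints, cross-correlation pruning into groups of mutually
    uncorrelated covariates, multivariate logistic modelling with backward
    elimination, elastic-net-regularised Cox selection with stepwise
    refitting, and discrimination/calibration evaluation (ROC AUC with
    confidence intervals, Hosmer-Lemeshow test, survival calibration
    tables). A seeded synthetic-cohort generator with planted
    feature-outcome effects stands in for patient data, so every stage of
    the pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    survival,
    glmnet,
    pROC,
    MASS,
    RNifti,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
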