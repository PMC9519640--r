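Package: tbict
Title: Validation of Admission CT Scoring Systems for Traumatic Brain Injury
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for external validation of admission computed-tomography
    (CT) severity scores in traumatic brain injury (TBI) against 6-month
    mortality. Implements rule-based scoring of structured CT findings into
    the Marshall CT classification, the Helsinki CT score, and the
    NeuroImaging Radiological Interpretation System (NIRIS); first-level
    logistic recalibration of each score; a clinical base model (age, GCS,
    modified SAPS II, chronic comorbidity) and combined clinical + CT models;
    and a discrimination/calibration battery (Mann-Whitney AUC with DeLong
    confidence intervals, DeLong AUC comparison, Nagelkerke's R-squared,
    Hosmer-Lemeshow test, integrated discrimination improvement, Pearson
    chi-square on cross-tabulations). A seeded synthetic-cohort generator
    calibrated to published Finnish ICU TBI cohort marginals makes every
    pipeline stage testable without registry access.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    jsonlite,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
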