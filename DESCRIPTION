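Package: penrisk
Title: Histological Risk Grading for Inguinal Lymph Node Metastasis in Penile Cancer
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements a point-based histological risk grading system for
    predicting inguinal lymph node metastasis in penile squamous cell
    carcinoma from four primary-tumour features (worst pattern of invasion,
    lymphocytic host response, lymphovascular invasion, perineural
    invasion), alongside the European Association of Urology (EAU)
    pT-stage/grade comparator. Provides cohort table reading and
    validation, contingency aggregation, diagnostic test evaluation
    (sensitivity, specificity, PPV, NPV with several confidence-interval
    conventions), odds ratios (closed form and logistic regression),
    ordinal ROC AUC with tie correction, Cohen's kappa, association tests,
    a seeded synthetic-cohort simulator with a calibrated dose-response
    metastasis model, and a one-shot reproduction report for the published
    development-cohort results.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    broom,
    optparse,
    pROC,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
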