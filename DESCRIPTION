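Package: vteram
Title: Venous Thromboembolism Risk Assessment Models for Lung Cancer Cohorts
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Implements four additive risk assessment models (RAMs) for
    predicting venous thromboembolism (VTE) in ambulatory lung-cancer
    patients receiving chemotherapy - the Khorana risk score, the PROTECHT
    score, the CONKO score and the COMPASS-CAT score - together with the
    statistical machinery used to validate them on a patient cohort: 2x2
    diagnostic metrics (sensitivity, specificity, PPV, NPV), cross-product
    odds ratios with Woolf confidence intervals and Haldane-Anscombe
    zero-cell correction, Pearson chi-square and Mann-Whitney U tests, ROC
    curves with the C statistic and Youden-optimal cutoffs, and univariate
    screening followed by multivariate logistic regression. A seeded
    synthetic-cohort generator reproduces the marginal structure of a
    118-patient lung-cancer cohort with a logistic VTE outcome model, so the
    whole pipeline is testable without access to patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    pROC,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
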