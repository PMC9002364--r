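Package: metsindex
Title: Obesity- and Lipid-Related Indices for Predicting Metabolic
    Syndrome in Chronic Kidney Disease
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Tools for evaluating obesity- and lipid-related indices
    (body mass index, waist circumference, visceral and subcutaneous fat
    area, visceral adiposity index, Chinese visceral adiposity index and
    lipid accumulation product) as predictors of metabolic syndrome in
    chronic kidney disease cohorts, with and without type 2 diabetes.
    Provides sex-specific index calculators including CKD-EPI estimated
    glomerular filtration rate, rule engines for three metabolic-syndrome
    definitions (Chinese 2020 guideline, revised NCEP-ATPIII, IDF), ROC
    analysis with DeLong confidence intervals and Youden-index optimal
    cut-offs, Firth bias-reduced penalized logistic regression with
    collinearity diagnostics, a synthetic cohort generator calibrated to
    published stratum summaries, and a stratified end-to-end study
    pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
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
    utils
Suggests:
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
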