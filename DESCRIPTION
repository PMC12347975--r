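Package: metinflam
Title: Metabolic-Inflammatory Indices for Acute Appendicitis Severity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes nine metabolic-inflammatory indices (NLR, PLR, SII,
    IMI, GLR, NLCR, CLR, GCNLI, MISI) from routine admission labs and
    provides the full severity-stratification pipeline around them:
    univariate screening between perforated/non-perforated and
    complicated/uncomplicated appendicitis groups, Kaiser-Meyer-Olkin
    guided factor analysis of candidate variable sets, ROC curves with
    Youden-optimal and published fixed cutoffs, 2x2 diagnostic performance
    with odds ratios, and post-hoc power analysis from odds ratios via the
    logistic-to-normal effect-size transformation. Ships a synthetic
    cohort generator that emulates the group-conditional lab distributions
    and latent three-factor correlation structure (coagulation,
    renal-metabolic, immune) the analysis assumes, so every stage is
    testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    nortest,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
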