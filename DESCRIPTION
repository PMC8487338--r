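Package: phonenorms
Title: Normative Standardization and Psychometrics for Telephone Cognitive Screens
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Regression-based demographic norming and psychometric validation
    for telephone-administered cognitive screening tests, built around the
    Equivalent Score (ES) tradition: covariate-transformed adjustment
    equations, non-parametric tolerance limits on ranked adjusted scores,
    five-level ES banding, reliability (Cronbach's alpha, intraclass
    correlations), convergent validity, principal-component structure,
    ROC accuracy against criterion screens, paired-equivalence (TOST)
    testing between administration formats, and two-parameter logistic
    item calibration by marginal maximum likelihood. Ships the published
    adjustment equations and ES band tables for the Italian ALS Cognitive
    Behavioral Screen Phone Version (ALS-CBS-PhV) plus a synthetic-cohort
    generator so the full pipeline runs without external data.
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
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
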