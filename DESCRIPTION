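Package: anthrorisk
Title: Anthropometric Risk Index and Metabolic Syndrome Mortality Modelling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes allometric anthropometric indices (body mass index, a
    body shape index, hip index) from basic body measurements, standardizes
    them to age- and sex-specific Z scores, estimates smooth per-index log
    mortality-hazard curves by penalized-spline Cox regression with age as
    the timescale, and sums the evaluated curves into an anthropometric risk
    index (ARI). Scores the five ATP III metabolic syndrome (MS) components,
    fits the roster of survey-weighted Cox proportional-hazards models that
    combine ARI with MS predictors, and compares them by AIC differences,
    explained variation, and concordance. Includes a synthetic NHANES-like
    cohort generator with known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
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
    survival,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
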