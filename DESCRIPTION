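Package: heatcco
Title: Case-Crossover Analysis of Heat Illness Risk Under WBGT-Based
    Heat Safety Thresholds
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for time-stratified case-crossover analysis of
    exertional heat illness during school sports club activities.
    Estimates wet-bulb globe temperature (WBGT) from standard weather
    variables, assigns guideline heat categories and daily-mean lag
    bins, links incident records to nearby monitoring sites, builds
    time-stratified matched sets (year, month, day of week, hour),
    fits conditional logistic regression models from the conditional
    likelihood with optional group-lasso variable selection, compares
    stratum-specific odds ratios with pairwise Wald tests under
    Bonferroni and Benjamini-Hochberg corrections, and derives
    one-category heat-safety-threshold adjustments for high-risk
    strata. Includes a synthetic-data generator with known ground
    truth so that every pipeline stage is testable without
    confidential incident data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    geosphere,
    stats,
    utils
Suggests:
    jsonlite,
    survival,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
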