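Package: metaboaging
Title: Serum Metabolomics Analysis of Aging with Breakpoint Detection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for cohort-scale serum metabolomics studies of chronological
    aging: LC-HRMS feature-table quality control with QC-anchored LOESS drift
    normalization, multiple imputation and grid-searched Box-Cox transformation
    with train-anchored scaling, BMI-adjusted partial Pearson correlation
    screening under a dual Benjamini-Hochberg plus nominal-alpha significance
    rule, hypergeometric pathway over-representation analysis, forward stepwise
    age modeling with train/test cross-validation, and detection of an aging
    metabolism breakpoint from first-principal-component scores by two-segment
    regression maximizing the product of the segment coefficients of
    determination. Includes a calibrated synthetic cohort generator so every
    stage is testable without access to subject-level data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    MASS,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
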