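Package: gwgcohort
Title: Pseudo-Cohort Estimation of Gestational Weight Gain from
    Cross-Sectional Surveys
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reconstructs gestational weight gain (GWG) trajectories from
    cross-sectional survey microdata using a pseudo-cohort design: pregnant
    women observed at different gestational months stand in for a cohort
    followed through pregnancy, and non-pregnant women at risk of conception
    supply the pre-pregnancy baseline. Provides eligibility filtering with
    auditable exclusion tallies, combined sampling/post-stratification
    weighting normalised to the unweighted sample size, month-wise weighted
    mean trajectories, linear extrapolation of third-trimester gain to the
    estimated date of delivery with delta-method standard errors, trimester
    gains with 95% confidence intervals, subgroup comparison via
    confidence-interval overlap, two-period trend comparison on a common
    country panel, and a synthetic multi-country survey generator with
    closed-form ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
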