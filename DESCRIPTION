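Package: spatrec
Title: Spatial Pattern Recognition for Small-Area Premature Mortality
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Quantifies the strength of specified spatial patterns
    (geo-coordinate location, centrality, contiguity, proximity, urbanity)
    in a small-area health outcome, re-measures them in the residuals of a
    covariate-enriched regression, and reports the percent decline of each
    pattern. Includes period life-table computation of standardized
    premature mortality from an artificial cohort, spatial weights
    (queen contiguity and inverse centroid distance) with row
    standardization, heteroskedasticity-robust ordinary least squares,
    stochastic imputation of missing covariates, and a synthetic-geography
    generator with known ground truth for end-to-end testing.
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
    rlang,
    sandwich,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
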