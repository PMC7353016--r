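Package: selmapr
Title: Geostatistical Mapping of Population Selenium Status from Serum Biomarker Surveys
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the spatial analysis of serum selenium surveys:
    survey-weighted summaries and deficiency prevalence, aggregation of
    individual records to enumeration-area means, robust empirical
    variography (Matheron, Cressie-Hawkins and Dowd estimators) on
    great-circle distances, exponential variogram fitting by weighted
    least squares, ordinary kriging prediction and variance surfaces,
    leave-one-out cross-validation with standardized squared prediction
    errors, and probability-of-deficiency maps expressed with calibrated
    likelihood phrases. A synthetic-survey generator with a spatially
    correlated Gaussian field of enumeration-area means lets the whole
    pipeline run end-to-end without access to restricted serum data.
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
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
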