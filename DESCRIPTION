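Package: iscore
Title: Consensus Immunoscore Scoring and Survival Analysis for Colon Cancer Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements the consensus Immunoscore: CD3+ and CD8+ T-cell
    densities measured in the tumor core and invasive margin are converted
    to percentiles against a reference distribution, averaged, and binned
    into the two-, three-, and five-category consensus schemes. Provides
    quality control of marker measurements, construction of the time to
    recurrence, overall survival and disease-free survival endpoints,
    center-stratified Cox proportional-hazards modelling, Kaplan-Meier
    landmark rates, log-rank and trend tests, restricted mean survival
    time comparisons, Harrell's concordance, chi-squared relative
    importance, and a synthetic-cohort generator with a known outcome
    model for validating the whole pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    stats,
    survival,
    generics,
    ggplot2,
    jsonlite,
    readr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
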