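Package: pfctools
Title: Proportion of Females Calving as a Population-Level Reproductive Indicator
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for computing and interpreting the annual proportion of
    females calving (PFC) in megaherbivore populations monitored through
    complete individual life histories. Builds annual PFC series from dated
    life-history records with stage-based adulthood rules, applies
    variance-stabilising transformations for proportions, fits second-order
    autoregressive regressions with density and rainfall covariates by
    maximum likelihood, and ranks all covariate subsets by AICc with Akaike
    weights, model averaging and relative importance. An individual-based
    demographic simulator generates synthetic reintroduced populations with
    realistic gestation, inter-birthing intervals and staged import
    schedules, supporting false-signal and variance experiments that probe
    how demographic stochasticity and founding effects shape PFC time
    series.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    broom,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
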