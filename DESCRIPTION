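Package: outagecco
Title: Case-Crossover Analysis of Power Outage Exposure and
    Cardiorespiratory Hospitalizations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for estimating short-term associations between
    county-level electrical power outages and cause-specific emergency
    hospitalization rates.  Builds county-day outage exposure from hourly
    customers-without-power feeds (customer-base estimation, gap
    imputation, run detection at configurable duration and percentage
    thresholds), tabulates cause-specific hospitalization counts from
    claim records, assembles time-stratified case-crossover strata with
    distributed exposure and temperature lags, and fits stratum-
    conditioned Poisson models with spline-constrained distributed lag
    terms, quasi-AIC model selection, effect-modification and
    attributable-hospitalization estimation.  Includes a synthetic-data
    generator with fully known ground truth for validating the whole
    pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    splines,
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
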