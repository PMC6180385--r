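Package: msmdelay
Title: Marginal Structural Models for Delayed COPD Maintenance-Therapy Initiation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: A tested pipeline for estimating the effect of delaying initiation of a
    COPD maintenance therapy (umeclidinium/vilanterol) on 12-month medical costs and
    severe-exacerbation risk from administrative claims, using stabilized inverse
    probability of treatment weights from pooled monthly logistic treatment-selection
    models and weighted generalized estimating equations with sandwich variances.
    Includes a new-user cohort builder (index dates, eligibility, month-of-initiation
    cohorts, baseline covariates, cost aggregation), a claims-based exacerbation episode
    algorithm (severity classification, 5-day prescription qualification, 14-day episode
    merging), and a seeded synthetic-claims generator with a known time-varying
    confounding structure so every stage is validated by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    data.table,
    sandwich,
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
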