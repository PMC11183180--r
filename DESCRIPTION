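Package: agflow
Title: Provenance Choice for Assisted Gene Flow in Stage-Structured Tree Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for choosing seed sources (provenances) for assisted gene
    flow of long-lived trees under climate warming. Models a planted cohort
    with a stage-structured life cycle in which annual survival declines as a
    Gaussian function of the mismatch between a provenance's thermal optimum
    and the yearly temperature, with stage-specific tolerance widths. Provides
    closed-form predictions of expected harvest for fixed and stochastic life
    histories, a deterministic cohort projection engine, calibration of
    tolerance-ontogeny profiles against a fixed cumulative tolerance, grid
    search for the best provenance, comparison of seed-sourcing strategies
    (local, model-best, quarter-rotation rule), and Monte-Carlo ensembles
    under interannual temperature fluctuations.
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
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
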