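Package: spdsmoke
Title: Compartmental Modelling of Smoking Disparities by Serious
    Psychological Distress Status
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Deterministic annual-step compartmental simulation of cigarette
    smoking (never, current, and former smokers binned by years since
    quitting) for populations with and without serious psychological
    distress (SPD). Provides calibration of gender- and age-band-specific
    initiation and cessation scaling factors to survey prevalence targets by
    least squares, projection of smoking prevalence under Status Quo, No
    Initiation, and maximum-potential-reduction (MPRPM) counterfactual
    scenarios, smoking-attributable deaths and years of life lost built from
    baseline mortality and hazard ratios, cessation-versus-initiation
    decomposition of averted deaths, and absolute and relative disparity
    metrics. Includes a synthetic-data generator emulating the statistical
    structure of the survey and rate inputs so the full pipeline is testable
    without external data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
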