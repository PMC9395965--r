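Package: psmcea
Title: Partitioned Survival Cost-Effectiveness Modelling with Indirect
    Comparison and Treatment-Switching Adjustment
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for three-state partitioned survival cost-effectiveness
    analysis of oncology treatments when the two strategies have never been
    compared head to head.  Provides synthetic individual-patient-data (IPD)
    trial simulation, parametric survival extrapolation over six families
    with correlated parameter sampling for probabilistic analysis, two-stage
    accelerated-failure-time adjustment for control-arm treatment switching,
    anchored matching-adjusted indirect comparison (MAIC) with Bucher
    combination, deterministic (tornado) and probabilistic (Monte Carlo)
    sensitivity analysis with cost-effectiveness acceptability curves, and
    mapping of EORTC QLQ-C30 scores to EQ-5D-5L health-state utilities.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    flexsurv,
    survival,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
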