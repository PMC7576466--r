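Package: markovcea
Title: Markov Cohort Cost-Utility Analysis for Integrated Domiciliary Care
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Cost-utility analysis of telehealth-enhanced integrated
    domiciliary care for older multimorbid patients, built around a
    three-state Markov cohort model (baseline disease stage, deteriorated
    disease stage, dead) with period life-table mortality scaled by
    state-specific relative risks, discounted quality-adjusted life years
    and costs over a lifetime horizon, and incremental cost-effectiveness
    statistics (ICER, net monetary benefit). Includes a synthetic
    two-arm cohort simulator for patient-level demographics, functional
    scores (Barthel, IADL, GDS) and resource use; clinical-effectiveness
    statistics and transition-probability estimation; perspective-aware
    costing (health-care and societal); deterministic one-way sensitivity
    sweeps, cost-effectiveness plane export and an optional probabilistic
    sensitivity analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
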