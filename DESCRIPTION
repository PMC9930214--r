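Package: coronaryCEA
Title: Cost-Effectiveness Analysis of Coronary Revascularization Strategies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A decision-analytic engine for comparing coronary artery bypass
    grafting (CABG) against percutaneous coronary intervention (PCI) with
    drug-eluting stents. Implements a six-state Markov cohort model with
    per-cycle cost and utility rewards and annual discounting; computes
    quality-adjusted life years (QALYs), incremental and average
    cost-effectiveness ratios (ICER, ACER) and net monetary benefit (NMB)
    with GDP-based willingness-to-pay thresholds; performs one-way
    deterministic (tornado) and probabilistic (Monte Carlo, gamma/beta)
    sensitivity analysis with cost-effectiveness acceptability curves; and
    generates synthetic patient cohorts (demographics, length of stay,
    billing categories, SF-36 and Seattle Angina Questionnaire scores) so
    the costing and effectiveness stages run end-to-end without access to
    hospital records.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.0)
Imports:
    ggplot2,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
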