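# coronaryCEA

A decision-analytic engine for cost-utility comparison of two coronary
revascularization strategies: **CABG** (coronary artery bypass grafting)
versus **PCI** (percutaneous coronary intervention with a drug-eluting
stent), from the patients' perspective, with costs in 2014 USD and
effectiveness in quality-adjusted life years (QALYs) derived from SF-36
and Seattle Angina Questionnaire (SAQ) scores.

It is aimed at health economists and HTA analysts who want the full
pipeline — parameters with uncertainty ranges, a Markov cohort engine,
CEA ratio arithmetic, deterministic and probabilistic sensitivity
analysis, and a synthetic patient cohort — as composable, tested R
functions rather than a point-and-click model.

## The model

A cohort enters one arm at age 59 and transitions among six health states
in 6-month cycles — Stable, Repeat CABG, Repeat PCI, CVA, CAD death,
Other death (the death states absorbing) — under a row-stochastic matrix
built from the packaged base-case probabilities. Each living state accrues
a per-cycle cost and an instrument-specific utility weight; death states
charge a one-time transition cost. Cycle-*k* rewards are discounted by
`(1 + r)^(-k/2)` at `r = 0.03`/year.

The comparison is summarized by

* `ICER = ΔCost / ΔEffect` (CABG − PCI), with *dominant* flagged when
  CABG is cheaper and more effective;
* `ACER = Cost / Effect` per strategy;
* `NMB = W·QALY − Cost` at willingness to pay `W`, defaulting to three
  times GDP per capita (3 × 8,329 = 24,987 USD/QALY), the threshold below
  which an ICER counts as cost-effective.

Probabilistic sensitivity analysis draws every ranged parameter per trial
(gamma for costs, beta for probabilities and utilities; ranges are read as
95% CIs, so `sd = (high − low)/3.92`) and summarizes the trials as a
cost-effectiveness plane, an acceptability curve, and the fraction of
trials with positive incremental NMB. A one-way (tornado) analysis probes
each parameter's range at base case. See
`vignettes/cost-effectiveness-methods.Rmd` for conventions and rationale.

## Worked example

```r
library(coronaryCEA)
params <- default_parameters()                 # packaged base case
res <- cea_table(compare_arms(params, "SAQ"))  # both arms, SAQ utilities
print(res)
```

```
Cost-effectiveness, CABG vs PCI (SAQ utilities):
 strategy     qaly incremental_qaly    cost incremental_cost   icer  verdict
      PCI 0.263538               NA 65020.9               NA     NA     <NA>
     CABG 2.029455          1.76592 38655.3         -26365.6 -14930 dominant
   acer      nmb
 246723 -58435.8
  19047  12054.7
verdict: dominant at WTP 24987 USD/QALY
```

Over the default 30-cycle (15-year) horizon CABG accrues about 1.77 more
discounted QALYs while costing about 26,400 USD less, so it *dominates*
PCI: the ICER of −14,930 USD/QALY is a saving per QALY gained, and no
willingness-to-pay threshold is needed to prefer CABG. (Absolute QALY and
cost levels depend on the horizon calibration; the signs and the verdict
do not.)

```r
psa <- run_psa(params, 1000, seed = 42, instrument = "SAQ")
print(psa)
```

```
PSA: 1000 trials, seed 42, SAQ utilities
  mean dCost -26341.1 USD, mean dQALY 1.7608; acceptance at WTP 24987: 100.0%
```

Every one of the 1,000 joint parameter draws keeps CABG in the acceptance
region at the reference threshold — parameter uncertainty at the stated
ranges does not overturn the verdict. `ceac(psa)`, `plot_ce_plane(psa)`
and `tornado(params)` give the standard figures;
`report_base_case()` / `report_psa()` / `report_synth()` write everything
as CSV, and `generate_cohort()` produces a synthetic patient-level cohort
(demographics, length of stay, billing, pre/post questionnaire scores)
for end-to-end runs without hospital data.

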