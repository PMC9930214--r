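---
title: "Methods: the CABG vs PCI Markov cost-effectiveness model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the CABG vs PCI Markov cost-effectiveness model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coronaryCEA)
```

## The decision problem

Coronary artery disease can be revascularized surgically (coronary artery
bypass grafting, CABG) or percutaneously (PCI with a drug-eluting stent).
The two strategies differ in up-front cost, in the rate of repeat
revascularization, and in the quality of life patients report afterwards.
`coronaryCEA` encodes a cost-utility comparison of the two from the
patients' perspective, with costs in 2014 US dollars (converted from
Iranian Rials at 26,509 IRR/USD) and effectiveness in quality-adjusted life
years (QALYs) derived from two instruments: the generic SF-36 (8 dimensions)
and the disease-specific Seattle Angina Questionnaire (SAQ, 5 dimensions),
each scored 0–100 per dimension.

## The cohort model

A simulated cohort enters one arm at age 59 and moves among six health
states in 6-month cycles: **Stable**, **Repeat CABG**, **Repeat PCI**,
**CVA** (cerebrovascular accident), **CAD death**, and **Other death**. The
two death states are absorbing.

Per-cycle transition probabilities come from the packaged base-case
parameter set (`default_parameters()`), in which every entry carries a
point value and a low–high range. Three structural conventions close the
gaps that a bare table of per-arm probabilities leaves open:

* **Row renormalization.** The six printed Stable-row probabilities sum to
  0.9997 (CABG) and 0.9996 (PCI) rather than 1; `build_matrix()`
  renormalizes each row by its sum, preserving the printed ratios while
  producing a valid stochastic matrix.
* **Tunnel repeat states.** No outgoing probabilities are given for the
  repeat-procedure states, so they are one-cycle tunnels: the Repeat-CABG
  row equals the CABG-arm Stable row and the Repeat-PCI row the PCI-arm
  Stable row, in either arm. A patient who undergoes a repeat procedure
  therefore faces that procedure's transition profile for one cycle and
  then continues from wherever it sends them.
* **CVA survivors return to Stable.** The CVA row sends 0.074 to CAD death
  and 0.004 to background death; the remainder (0.922) returns to Stable,
  since no post-stroke state is distinguished.

Rewards are attached per state and cycle: a utility weight (the QALY
accrued per cycle in that state, instrument-specific, possibly negative —
the SAQ weight for repeat CABG after initial PCI is −0.357) and a recurring
cost in USD. The two death states instead carry a one-time transition cost
charged to the cohort fraction entering them in a cycle. Both accruals for
cycle *k* (*k* = 0, …, *H*−1) are earned by the occupancy at the start of
the cycle and discounted by (1 + *r*)^(−*k*·*c*) with *r* = 0.03/year and
*c* = 0.5 years. No half-cycle correction is applied by default; the
trapezoid variant is available via
`cea_settings(half_cycle_correction = TRUE)` because neither convention is
canonical and the choice shifts absolute totals, not the comparison's sign.

**Time horizon.** The horizon is a required setting with a default of 30
cycles (15 years). The default is a calibration, not ground truth: the
base-case discounted QALY totals imply roughly 25 discounted
stable-state-cycle equivalents (3.33/0.135 ≈ 24.7 and 1.57/0.063 ≈ 24.9),
and 30 six-month cycles with 3% annual discounting and the model's
attrition reproduce that order of magnitude. Absolute cost/QALY levels
therefore depend on this choice; incremental signs and verdicts are robust
to it (see the tornado results below).

**Background mortality** is the constant per-cycle value 0.004 rather than
age-indexed, because no life table accompanies the base case. Over a
15-year horizon starting at 59 this understates late-life mortality; it
affects both arms symmetrically.

## Effectiveness scoring

`score_instrument()` averages an instrument's dimension scores (unweighted,
since no weighting scheme is specified) and `to_utility()` maps the 0–100
summary linearly onto [0, 1]. This linear mapping is a deliberate,
documented simplification: no preference-based tariff (EQ-5D- or
SF-6D-style value set) is available for these instruments in this
population, and the packaged per-state utility weights are already on a
0–1-like scale. The scoring path exists chiefly so the synthetic-cohort
round trip can exercise the same pipeline raw questionnaire data would
take; the Markov model itself consumes the packaged per-state weights
directly.

`qalys_gained()` implements the discounted pre/post comparison
Qⁱ·(1−e^(−r·Lⁱ))/r − Q·(1−e^(−r·L))/r, with the analytic limit Qⁱ·Lⁱ − Q·L
substituted below r = 1e−9 so the function is continuous at r = 0.

## Costing

Patient-level costs aggregate into four categories: hospitalization and
medication (direct medical), travel/hotel (direct non-medical), and lost
productivity (indirect). Lost productivity values a hospital day at the
2014 average minimum wage, 311 USD/month over 26 working days
(`lost_productivity()`). Ongoing medication is costed by doubling a
six-month bill to an annual amount and discounting ten annual payments at
3% (`medication_present_value()`); payments fall at the start of each year
by default (annuity-due), with an in-arrears switch, because the
description "annual cost … discounted for 10 years" does not fix the
timing and the two differ by one discount factor. Reported ledgers round
totals to one decimal and per-capita values to two; internal arithmetic is
unrounded, so two observed per-capita cells that were truncated rather
than rounded in the original reporting (321.74, 96.32) differ from this
package's output by ≤ 0.01.

## Cost-effectiveness arithmetic

`icer()` computes ΔCost/ΔEffect (CABG minus PCI) and flags dominance —
cheaper and more effective — on the *unrounded* deltas; ratios are
reported rounded to whole USD/QALY. `acer()` is cost/effect per strategy.
`threshold_verdict()` applies the willingness-to-pay rule: an intervention
is cost-effective when its ICER is strictly below three times GDP per
capita (3 × 8,329 = 24,987 USD/QALY); the boundary itself is
not cost-effective, a convention that only matters on a set of measure
zero.

`sample_size()` evaluates the net-monetary-benefit sample-size formula
n = 2(z_α + z_β)^k · [sd_c² + (W·sd_q)² − 2W·ρ·sd_c·sd_q] / NMB_min².
The formula as published carries the quantile sum unsquared (k = 1), which
with the stated inputs gives 69 per group — inconsistent with the
study-scale recruitment of ~215 per arm. The conventional power
calculation squares the quantile term (k = 2) and gives 201 per group,
consistent with that scale, so `z_term = "squared"` is the default and
both variants are exposed.

## Sensitivity analysis

**One-way / tornado.** `one_way()` re-runs both arms with a single
parameter at its low and high bound (all else at base case, row
renormalization reapplied, probability endpoints clamped to [0, 1] — one
stay-stable bound is printed as 1.04236) and records the incremental NMB
at the reference WTP of 24,987 USD/QALY. `tornado()` does this for all 43
ranged parameters and sorts by swing. Under the packaged base case the
dominant verdict survives every endpoint, which the test suite asserts as
a (deterministic) property of the calibrated model.

**Probabilistic.** `run_psa()` draws every ranged parameter per trial —
gamma for costs, beta for probabilities and utilities, ranges read as 95%
confidence intervals so sd = (high − low)/3.92 — with moment matching that
preserves each entry's mean exactly. A utility whose support lies outside
[0, 1] (the negative SAQ weight) is rescaled affinely onto [0, 1] using
its own bounds, sampled, and mapped back, keeping the beta-for-utilities
rule applicable. Each trial reseeds the generator from a deterministic
function of (seed, trial index), so trial *i* is reproducible regardless
of how many trials are requested. `ceac()` and `acceptance_fraction()`
summarize the trials: the acceptance region of the cost-effectiveness
plane is operationalized as positive incremental NMB, which covers both
the dominant (south-east) quadrant and the below-threshold part of the
north-east quadrant; no purely geometric definition is used. The
conventional run is 5,000 trials; at that size the share of trials in the
acceptance region at the reference WTP is reported alongside the curve as
an exploratory summary rather than asserted, because it depends on the
horizon calibration.

## The synthetic cohort generator

`generate_cohort()` emulates the *marginal* structure of the observed
study arms — 210 CABG / 200 PCI patients; ages 60.23 ± 12.53 and
58.65 ± 11.19 years; lengths of stay 8.05 ± 5.438 and 3.19 ± 2.843 days;
per-capita billing targets per category; pre/post questionnaire scores
whose summary difference centres on each arm's stable-state utility gain —
so the costing and effectiveness stages can run end-to-end with no
hospital records. Distributional choices: ages are truncated normal
(≥ 18); length of stay and billing are gamma (right-skewed, non-negative,
as stay and cost data are), stay truncated at half a day with the gamma's
scale calibrated by root-finding so the *truncated* mean still hits the
target; dimension scores are logit-normal on [0, 100] (bounded support),
with the logit-scale location calibrated by quadrature so the expected
summary score hits its target. Lost productivity is never drawn: it is
computed from the drawn length of stay through `lost_productivity()`, so
the generator preserves that accounting identity exactly.

What the generator does **not** emulate: within-patient correlation beyond
the stay → lost-productivity link, between-category billing correlation,
comorbidity effects on cost or utility (sex and age are descriptive
payload only), and survival follow-up — the Markov model is
parameter-driven, not fitted to these records. Passing round-trip tests
therefore shows that the aggregation and scoring pipeline is correct, not
that real billing data would behave this way.

`roundtrip_check()` reports the relative error of every recovered
statistic; at 10,000 patients per arm all targets are recovered within 5%
(the test suite checks three seeds), and mean length of stay within 2%.

## Numerical and testing choices

* Transition matrices must be row-stochastic within 1e−12 at construction
  and 1e−8 at simulation entry; cohort propagation agrees with an explicit
  matrix-power oracle to 1e−10 over 100 cycles.
* Dominance and verdicts are evaluated on unrounded quantities; rounding
  happens only in the reporting layer.
* Degenerate ranges (high = low) yield point-mass "distributions" so a
  fully degenerate PSA reproduces the base case bitwise.
* Problem sizes exercised by the test suite: 5,000 PSA trials, 10,000
  patients per synthetic arm, 100-cycle oracle horizons.

## Known limitations

Absolute discounted totals depend on the horizon and half-cycle
conventions, which are calibration choices here; only ratio arithmetic on
published strategy outcomes, signs, and dominance verdicts are treated as
reproducible. Background mortality is age-constant. The observed cost
ledger (what patients actually paid, per category) and the model's
per-state costs are kept as separate surfaces and are not forced to agree;
notably they order the two arms differently, and the package does not
attempt to reconcile them. Extended dominance and efficiency frontiers
over more than two strategies, EVPI, and correlated parameter sampling are
out of scope.
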