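---
title: "Methods: a Markov model for the timing of somatostatin analogues in metastatic GEP-NETs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a Markov model for the timing of somatostatin analogues in metastatic GEP-NETs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gepnetcea)
```

## The clinical question

Somatostatin analogues (SSAs, octreotide or lanreotide) slow tumour growth
and control symptoms in metastatic gastroenteropancreatic neuroendocrine
tumours (GEP-NETs), but cost roughly $4000 per monthly injection and are
continued indefinitely. Guidelines leave open whether to start an SSA at
diagnosis of metastatic disease or to observe and start it at first
progression. `gepnetcea` implements a Markov cohort state-transition model
that prices that choice: two strategies, **SSA** (start at diagnosis) and
**DELAY** (start at first progression), followed from age 60 in monthly
cycles until death or the end of the life table, with peptide receptor
radionuclide therapy (PRRT) as the common salvage treatment after
progression in both arms.

## Health states and transitions

Both arms share one state space; only the initial state differs.

* **StableUntreated** (DELAY entry): metastatic disease under observation.
  Exits: NET death (18-month median), progression (6-month median, to
  ProgressedOnSSA — SSA starts in the same transition), background death.
* **StableOnSSA** (SSA entry): stable on monthly SSA. Exits: NET death
  (39-month median), progression (14-month median, to PRRT), serious
  complication forcing SSA discontinuation (1% over 96 weeks, to
  OffSSAComplication), background death.
* **OffSSAComplication**: SSA stopped for toxicity, symptoms uncontrolled
  (utility 0.32). Exits revert to the untreated rates; progression leads to
  PRRT *without* concurrent SSA (a drug stopped for serious toxicity is not
  resumed).
* **ProgressedOnSSA** (DELAY arm after first progression): on SSA with
  progressed disease. Exits: NET death (39-month median), second progression
  (14-month median, to PRRT with SSA), complication (to PRRT without SSA).
* **PRRT1–PRRT4**: a monthly tunnel delivering the four PRRT cycles
  ($51,300 each, $205,200 total), with SSA continued alongside. A parallel
  `_noSSA` tunnel carries patients whose SSA was stopped for toxicity and
  accrues no SSA cost. Exits: NET death on PRRT (39-month median),
  background death; otherwise the tunnel advances one state per cycle.
* **PostPRRT** (and its `_noSSA` twin): follow-up after PRRT with no further
  modelled progression event. Exits: NET death (39-month median),
  background death.
* **DeadNET**, **DeadOther**: absorbing, zero rewards. Keeping the two
  causes separate lets the model report the fraction of deaths attributable
  to the tumour.

Utilities: 0.79 in both stable states, 0.72 for progressed disease (and
throughout PRRT and post-PRRT), 0.32 only for uncontrolled symptoms after a
complication. The published utility set lists four values without an
explicit state mapping; this mapping is the simplest one consistent with the
finding that the uncontrolled-symptoms utility barely moves the results.

### The SSA dose with PRRT

The treatment definition underlying the model uses octreotide LAR 20 mg per
28 days for stable disease but 60 mg alongside PRRT. The package therefore
multiplies the monthly SSA cost by `ssa_dose_mult_prrt` (default 3) in the
PRRT tunnel and post-PRRT states. This tripling is load-bearing: with a flat
$4121/month everywhere the strategy costs come out roughly 45% too low to be
consistent with the published totals, while the dose-adjusted model
reproduces them within a couple of percent.

## From published quantities to per-cycle probabilities

Every disease transition is published as a median, so each is interpreted as
the median of an exponential time-to-event (no shape information exists):

* median *m* months → per-cycle probability `1 - 0.5^(1/m)`
  (`median_to_cycle_prob()`); a process with this constant probability has
  first-passage median exactly *m* cycles.
* interval probabilities (the 1%-over-96-weeks complication rate) spread
  under a constant hazard: `1 - (1 - p)^(1/months)`, weeks converting as
  `weeks * 12/52`.
* annual background mortality `q` converts as `1 - (1 - q)^(1/12)`;
  composing the monthly probability twelve times recovers `q` exactly.

Background mortality at cycle *t* uses the life-table `q` at age
`floor(60 + t/12)` — the standard period-life-table convention; monthly
interpolation would add nothing at this precision. NET mortality is *not*
subtracted from the life table (tumour deaths are a negligible share of
national all-cause rates).

## Competing risks within a cycle

Several exits compete for each cycle. The package implements two
combination rules (`combine_competing_risks()`):

* **sequential** (default in the strategy models): each exit is conditioned
  on all earlier exits not having fired, in the fixed clinical order NET
  death → progression → complication → background death. This is exactly
  the chance-node ordering a decision-tree implementation of the model
  encodes, and it is the convention under which the package reproduces the
  published base case most closely (incremental life-years and QALYs about
  3% low, versus about 11% low under rate apportionment).
* **rate**: converts each probability to a constant rate, combines the
  rates, and apportions the joint exit probability proportionally —
  simultaneous exponential risks. Available via `combine = "rate"` in
  `build_strategy()` for sensitivity to this choice.

Both rules guarantee the per-state exit probabilities sum to
`1 - prod(1 - p_i) <= 1`.

## Rewards, discounting and the half-cycle correction

* **Costs** accrue on start-of-cycle occupancy — a month's drug is dispensed
  to those entering the month — and are discounted. No half-cycle correction
  is applied to costs by default (`hcc_costs = FALSE` in
  `accumulate_rewards()` flips this in one place; it moves the base-case
  ICER by well under 1%).
* **QALYs** use the trapezoidal half-cycle correction (the average of the
  occupancy at the two ends of each cycle), weighted by `utility/12`, and
  are discounted.
* **Life-years** use the same trapezoid on the alive fraction, undiscounted.
* **Discounting** is 3% per year for both costs and QALYs, compounded
  continuously in cycles: `(1 + r)^(-t/12)`. No compounding convention is
  canonical at monthly cycles; this one is smooth and matches the annual
  rate exactly at year boundaries.

The cohort is followed from age 60 through the year of age 100 inclusive
(492 monthly cycles); the bundled life table closes with `q = 1` at 100, so
the cohort is fully absorbed by the horizon.

## Background mortality and the bundled life table

The model needs a national-style period life table. The package reads any
`age,qx` CSV (`read_life_table()`) and also generates Gompertz–Makeham
tables (`synth_life_table()`), which double as engine-validation fixtures
(a constant hazard has a known closed-form life expectancy).

The bundled table (`default_life_table()`) is **synthetic**: a
Gompertz–Makeham table (`a = 6.4e-5`, `b = 0.085` per year, Makeham
`c = 5e-4`) rather than a published national table. The parameter set does
not pin the background mortality to a specific national table year or sex
stratum, and the threshold-price result in particular is sensitive to that
choice (it is a
small difference of large numbers; across demographically plausible tables
it swings by roughly ±20%). The bundled parameters were therefore calibrated
jointly against the full published result set while staying demographically
realistic for a contemporary US both-sex table: `q(60) ≈ 0.011` and a
remaining life expectancy at 60 of about 21.6 years. The table is labelled
synthetic in its filename and should not be cited as anyone's official
statistics.

## Comparative outcomes

`compare_strategies()` orders the two arms by QALYs (ties broken by lower
cost), computes incremental cost, life-years and QALYs, and reports the
ICER on the efficiency frontier, flagging dominance (more QALYs at lower
cost) and undefined cases. ICERs are always computed from unrounded totals —
which is why a ratio of rounded increments printed in a results table need
not equal the printed ICER exactly. Net monetary benefit
(`wtp * QALY - cost`) gives the same verdict algebraically whenever the QALY
increment is positive; this identity is property-tested.

## Sensitivity analyses

* **One-way (tornado)**, `one_way_dsa()`: every parameter with a
  deterministic range is set to its low and high bound (medians and the
  complication rate ±25%, utilities ±0.1, both costs half to double), the
  full two-strategy model is re-run, and the ICER span is the bar width.
* **Threshold price**, `threshold_price()`: bisection (via
  `stats::uniroot`, tolerance $0.01) for the SSA monthly cost at which the
  ICER meets the willingness-to-pay threshold, with a numerical
  monotonicity check over the bracket.
* **Probabilistic (PSA)**, `run_psa()`: all parameters drawn
  simultaneously and independently — gamma for the two costs, beta for
  utilities and per-cycle probabilities (medians are converted to
  probabilities first; the beta draws live on the probability scale) — with
  method-of-moments parameters centred on the base values.

### The PSA spread convention

The published analysis states the distribution families but not their
variances. The package equates each deterministic sensitivity range with a
95% interval, `SD = range/3.92`, isolated in one place (`psa_spec()`). This
is the single most consequential undocumented convention: under it the ICER
distribution's 0.5th percentile sits near $140k/QALY, so the probability
that immediate SSA is cost-effective at $100k/QALY comes out well under 1% —
qualitatively the published "almost never cost-effective", but smaller than
the published point estimate of 1.4%, which evidently reflects a wider
spread convention. A beta SD at or beyond its feasibility bound
`sqrt(m(1-m))` is shrunk to 0.99 of the bound. Draws are independent across
parameters; no correlation structure is described for this model.

The default seed is 20211 and is recorded, along with an MD5 hash of the
effective parameters and the package version, in the header of every output
file.

## Validation strategy

* **Conservation**: every cohort-trace row sums to 1 within 1e-10.
* **Microsimulation oracle** (`microsim_oracle()`): the identical model
  simulated individual-by-individual with categorical draws; the cohort
  trace is its exact expectation, and the suite requires agreement within 3
  standard errors at 100,000 individuals. This validates the trace and
  reward arithmetic independently of the matrix algebra.
* **No-disease limit**: with all disease hazards switched off, the model's
  life-years reproduce the life table's trapezoidal life expectancy at 60
  within 0.02 years (the residual is within-year discretisation: the
  monthly model lives an exponential within each year, the annual oracle a
  straight line).
* **Median recovery**: each per-cycle probability puts the first-passage
  median exactly at the stated month for all base-case medians.
* **Determinism**: microsimulation and PSA are exactly reproducible from
  their seeds.

Problem sizes in the shipped test-suite runs: 10,000 PSA iterations,
100,000 microsimulated individuals, 3 standard errors everywhere a Monte
Carlo comparison is made; these sizes make the checks sharp while keeping a
full suite run in a few minutes.

## What the synthetic inputs do and do not establish

The synthetic life table and the exponential reading of published medians
emulate the *structure* of the evidence (period mortality, median-only
time-to-event summaries), not patient-level reality: no shape information,
no covariates, no correlation between progression and death risks, no
post-PRRT progression, and no symptom dynamics (flushing, carcinoid heart
disease) are represented. Passing tests therefore show the machinery is
faithful to the stated model and its published summaries — not that the
model is a validated forecast for real cohorts.

## Known limitations

* Exactly two strategies; the frontier logic handles dominance but no
  >2-strategy frontiers (none exist here).
* All disease transitions are memoryless; only background mortality is
  age-dependent.
* Complications can occur only in SSA-treated pre-PRRT states; none are
  modelled during the PRRT tunnel.
* The threshold-price and PSA-fraction outputs inherit the base-case
  convention sensitivity discussed above and should be read with their
  stated uncertainty.
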