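---
title: "A decision tree + Markov cost-utility model of 10 kHz versus low-frequency spinal cord stimulation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A decision tree + Markov cost-utility model of 10 kHz versus low-frequency spinal cord stimulation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The decision problem

Chronic back and leg pain (CBLP), including failed back surgery syndrome, is
commonly treated with spinal cord stimulation (SCS) when conventional medical
management (CMM) fails. Devices differ in stimulation frequency and battery
technology: 10 kHz high-frequency SCS (a rechargeable system), rechargeable
low-frequency SCS (RLF-SCS) and non-rechargeable low-frequency SCS (NRLF-SCS),
whose battery must be replaced surgically every few years. `scscea` implements
a full economic evaluation of 10 kHz SCS against both low-frequency variants
from a UK NHS perspective: a cost-consequence analysis (which device pathway
costs less over 15 years) and a cost-utility analysis (cost per
quality-adjusted life year, QALY, with dominance classification), with
deterministic, one-way, threshold, scenario and probabilistic sensitivity
analyses.

## Model structure

The model is a classical two-stage structure.

**Six-month decision tree.** All patients first undergo an SCS screening trial
(external stimulator, up to 14 days). Successes receive a permanent implant;
failures have the trial electrode removed and revert to CMM alone. Implanted
patients are classified at month 6 by pain response — *optimal* (≥ 50%
reduction in leg-pain VAS) or *sub-optimal* — crossed independently with
*with/without non-serious complications* (events such as lead migration or
implant-site infection that do not require removal). Implanted patients may
also have an early explant in the first six months; the Year-1 annual explant
probability is split by constant hazard, so the tree consumes
$1-(1-p_{yr1})^{1/2}$ and the first two Markov cycles consume the per-cycle
remainder. CMM-alone patients achieve optimal relief with a small probability;
the rest perceive no relief.

**Markov cohort model.** From month 6 to the 15-year horizon the cohort moves
through 3-month cycles over seven states: four implanted states
(optimal/sub-optimal × with/without complication), CMM with optimal relief,
CMM with no perceived relief, and death. Pain-response classification on SCS
is fixed at month 6; patients leave it only by explant (to the CMM states),
or death. Per cycle:

* all-cause mortality (state-independent, annual 0.81% converted per cycle);
* device explant, with time-varying annual rates (Year 1 residual, Year 2,
  then a common 3.2% from Year 3 onwards), converted per-cycle under a
  constant hazard; explanted patients split between the two CMM states by the
  CMM optimal-relief probability;
* transient non-serious complications: with-complication status is re-drawn
  each cycle from the late annual complication probability, pricing the event
  cost and applying the with-complication utility for that cycle only;
* spinal reoperation for patients in the no-relief CMM state (5.0% per
  cycle), after which 19% achieve optimal relief under CMM. We model this as
  a recurring per-cycle branch: the event list of the state-transition
  structure places reoperation among the things that can happen *during each
  cycle*, and treating it as a single one-off branch at entry leaves
  long-term QALYs implausibly low relative to the cost-consequence structure
  (the no-relief state, utility 0.168, becomes almost absorbing);
* scheduled device replacement at integer multiples of the device longevity
  (10 years for the rechargeable systems, 4 for NRLF), priced at the
  reimplantation cost on the surviving implanted mass. Longevity is rounded
  to the nearest whole cycle because procedures fall on cycle boundaries.

## Accrual and discounting conventions

Costs and QALYs are both discounted at 3.5% per annum. Within the tree,
up-front procedure costs (trial, implant, removal) fall at time zero and are
booked undiscounted, and half a year of state utility is discounted at the
0.25-year mid-period factor. In the Markov phase each cycle's post-transition
occupancy accrues utilities and therapy costs at the cycle-midpoint discount
factor (so a complication that occurs in a cycle carries its utility decrement
in that same cycle); event costs are discounted at the cycle midpoint and
replacement procedures at their scheduled date. No additional half-cycle
correction is applied beyond midpoint discounting. Mortality is not applied
inside the six-month tree (six-month all-cause mortality ≈ 0.4% is below the
resolution of the tree and the tree has no death branch).

Utility values attach to states, not arms: 0.598 (optimal, no complication),
0.528 (optimal with complication), 0.258 (sub-optimal, either), 0.168 (no
perceived relief). CMM responders use the optimal-relief utility; whether CMM
and SCS responders share a utility is not fixed by the state definitions, and
we take them as equal. Therapy costs run at the SCS+CMM rates for implanted
states and the (higher-drug-cost) CMM-alone rates otherwise, at half the
six-month figures per cycle.

## Parameters

All inputs live in a flat registry (`parameter_registry()`), each with a
base-case value, 95% CI (or plausible range) and a sampling family, and are
serialized to/from a JSON configuration (`inst/extdata/base_case.json`).
Clinical probabilities are per-arm (`hf10.*`) or pooled across the two
low-frequency arms (`lf.*`), which differ only in device cost and longevity.
Key defaults: trial success 92.8% vs 88.0%; optimal relief at 6 months 80.9%
vs 54.4% (CMM alone 9.3%); non-serious complications 33.7% vs 35.8% at 6
months and 3.7% vs 12.8% per year thereafter; explants 4.4/4.7/3.2% vs
11.1/9.7/3.2% per year (Years 1/2/3+); implant £16,648 / £11,281 / £17,422
(10 kHz / NRLF / RLF), reimplantation priced at the implant cost in the base
case; therapy, trial, explant, complication costs as configured (2016 GBP).
The reoperation cost for the CMM pathway is not separately priced in the cost
set and defaults to £0 (configurable); the reoperation branch therefore
affects QALYs, not costs, in the base case.

CI bounds are converted to standard errors with the normal divisor 3.92, and
distributions are fitted by the method of moments: beta for probabilities
($\nu = m(1-m)/SE^2 - 1$, shapes $m\nu$ and $(1-m)\nu$) and gamma for costs
and longevity (shape $m^2/SE^2$, scale $SE^2/m$). Asymmetric printed ranges
(e.g. £0–£3,015) are used as-is; a CI too wide for a valid beta falls back to
a uniform on the bounds with a warning.

## Sensitivity analyses

**One-way (tornado).** Every bounded parameter is set to its lower and upper
bound with the rest at base case; entries are ranked by outcome span and the
top ten flagged. The cost-consequence outcome is the incremental cost
(comparator minus 10 kHz); the cost-utility outcome is the net-monetary-
benefit difference at £20,000/QALY, which remains well defined under
dominance where an ICER does not.

**Threshold.** Bisection on one parameter for cost-neutrality (incremental
cost zero) or for NMB parity at the willingness-to-pay threshold, to a £1
residual; endpoints that do not bracket the objective return an explicit
"no threshold within plausible range" result. Bisection is used uniformly
(rather than closed forms) so nonlinear parameters such as explant rates and
longevity are treated identically to linear ones.

**Scenarios.** Packaged multiway scenarios: equal explant rate of 3.2% per
year for all devices; equal non-serious complication rates (the
low-frequency rates set to the 10 kHz values, removing the LF excess — the
conservative direction for the dominance question being probed); the
alternative system costing (RLF implant priced at the 10 kHz system cost and
explicit, lower, reimplantation prices); and time-horizon variation
(`horizon_<N>y`).

## Probabilistic sensitivity analysis

Each of 5000 draws samples the clinical probabilities (beta) and the costs
and device longevities (gamma) jointly and re-evaluates the full model for
the three arms. Utilities are held at base case: the probabilistic exercise
varies clinical probabilities, costs and longevity, while utility CIs feed
the one-way analyses. Pooled low-frequency clinical parameters are drawn once
per draw and shared between NRLF and RLF. Two quantities are deliberately
correlated rather than independent:

* the two rechargeable systems (10 kHz and RLF) carry a single longevity
  assumption (10 years, range 8–25) and therefore share one draw — their
  replacement schedules move together, which is what makes the 10 kHz-vs-RLF
  cost difference far less dispersed than the 10 kHz-vs-NRLF one;
* the two drug pain-therapy costs (CMM alone £3,167 and SCS+CMM £2,012) carry
  the identical uncertainty range £0–£8,412 — one drug-cost uncertainty
  measured in two care settings — and are drawn comonotonically by matched
  gamma percentiles.

Sampled longevity is floored at one cycle. Draws are reproducible in
isolation: each `(seed, draw_index)` deterministically seeds the draw, with
parameters sampled in registry order. Summaries report the probability of
10 kHz SCS being cost-saving, the mean cost difference with both a
normal-approximation 95% CI of the mean (the headline) and a percentile
interval, and cost-effectiveness acceptability curves,
$\Pr[\mathrm{NMB}_{10k} > \mathrm{NMB}_{comp}]$ over a WTP grid.

## Synthetic trial generator

`simulate_trial()` stands in for the patient-level randomized-trial analysis
from which the clinical inputs were derived; it is entirely synthetic.
Per patient it draws screening success, then (among implanted) independent
6-month responder and complication indicators, a late complication over a
one-year window, and an explant time from a two-piece constant-hazard model
matching the Year-1 and Year-2 annual probabilities over months 0–24, with
paresthesia-weighted explant reasons in Year 1 (50/30/20
paresthesia/ineffective-pain/other) and ineffective-pain-weighted reasons in
Year 2 (60/20/20) — the weights reproduce the reported qualitative pattern
(early removals driven by intolerable paresthesia, later ones by inadequate
pain relief) and are otherwise a modelling choice. `estimate_inputs()`
recovers proportions with Wald 95% CIs, with Year-2 explants estimated among
patients still at risk at month 12 (the at-risk convention is the
generator's, stated here because trial reports rarely print denominators),
and `apply_estimates()` feeds them back into a configuration.

What the round trip does and does not show: it validates the estimator
(consistency, CI coverage near nominal at trial-scale n, sub-1% impact on
model outputs at large n) against data whose generating process exactly
matches the model's independence assumptions. Real trial data would carry
correlation between response, complications and explant, informative dropout
and between-centre heterogeneity, none of which the generator emulates —
passing these checks says the pipeline is self-consistent, not that the
trial-derived inputs are unbiased.

## Numerical choices and degenerate inputs

* Mass conservation is asserted inside the engine: transition rows must sum
  to 1 within 1e-12, and occupancies stay non-negative by construction.
* Dominance is classified on strict inequalities; exact cost or QALY ties
  report an ICER of 0 or signed infinity with a tie flag rather than a
  dominance label.
* Replacement times must be at least one cycle and strictly inside the
  horizon; a longevity beyond the horizon schedules nothing.
* Zero denominators in the synthetic-trial estimator yield `NA` (undefined)
  estimates, never zero; degenerate proportions (0 or 1) produce degenerate
  Wald CIs.
* Probabilities are validated to [0, 1] with the offending field named;
  utility ordering (with-complication ≤ without) is enforced for full
  configurations but deliberately not for one-way excursions or independent
  PSA draws.

## Problem sizes used in verification

The test-suite cross-checks run at sizes chosen to keep Monte-Carlo error
well below the tolerances they enforce: the decision-tree microsimulation
oracle uses 10^6 patients, the full tree-plus-Markov oracle 2×10^5, CI
coverage of the synthetic-trial estimator 500 replicates of a 100-per-arm
trial, and the end-to-end parameter-recovery run 10^5 patients per arm. The
probabilistic analysis uses the full 5000 draws.

## Known limitations

* The model reproduces a published evaluation whose workbook-level
  conventions (accrual timing, event pricing) are not fully documented;
  choices made here are stated above, and the residual structural
  differences are visible mainly in small cost categories.
* Flat all-cause mortality (no age dependence), no patient-level
  heterogeneity in utilities or costs, and no re-trial of SCS after
  explant.
* Complications are transient one-cycle events; chronic device-related
  morbidity is not modelled.
* The "remitter" response level (VAS < 3.0), opioid-sparing effects and
  currency conversion are out of scope.
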