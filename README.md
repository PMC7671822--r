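# scscea

Cost-utility and cost-consequence modelling of 10 kHz high-frequency spinal
cord stimulation (SCS) versus traditional low-frequency SCS — non-rechargeable
(NRLF-SCS) and rechargeable (RLF-SCS) — for chronic back and leg pain, from a
UK NHS perspective.

Health-economics analysts and HTA reviewers can use the package to reproduce,
probe and extend the evaluation: every input is a configurable parameter with
a 95% CI and a sampling family, and every analysis stage (base case, tornado,
threshold, scenario, probabilistic) is a plain R function over the same model
engine.

## The model

A six-month decision tree feeds a Markov cohort model run in 3-month cycles
to a 15-year horizon, discounting costs and QALYs at 3.5% per annum.

* **Decision tree (months 0–6):** SCS screening trial (success probability
  $p_{trial}$); successes receive a permanent implant, failures revert to
  conventional medical management (CMM). Implanted patients split into
  optimal (≥ 50% leg-pain VAS reduction) vs sub-optimal response, crossed
  independently with non-serious complications, and may explant early (the
  half-year share $1-(1-p_{yr1})^{1/2}$ of the Year-1 explant rate).
* **Markov model (months 6–180):** seven states — {optimal, sub-optimal} ×
  {with, without complication} on SCS, CMM with optimal relief, CMM with no
  perceived relief, dead. Per cycle: all-cause mortality; device explant at
  annual rates $p_{yr1}, p_{yr2}, p_{yr3+}$ converted by
  $1-(1-p)^{1/4}$; transient complications re-drawn from the late annual
  rate; reoperation from the no-relief CMM state (5% per cycle, 19%
  achieving optimal relief); scheduled battery/device replacement at
  multiples of the device longevity (10 y for the rechargeable systems, 4 y
  for NRLF), priced on surviving implanted mass.
* **Outputs:** per-arm discounted totals, incremental cost and QALYs, ICER
  or dominance ("dominated" = costlier and fewer QALYs), net monetary
  benefit $\mathrm{NMB} = \lambda \cdot \mathrm{QALY} - \mathrm{cost}$ at
  $\lambda$ = £20,000/QALY.
* **Uncertainty:** one-way (tornado) analysis over 95% CI bounds, bisection
  threshold search (cost-neutrality, ICER-at-WTP), named multiway scenarios,
  and a 5000-draw PSA (beta for clinical probabilities, gamma for costs and
  device longevity) with cost-effectiveness acceptability curves.
* **Synthetic trial:** a patient-level generator with the same probabilistic
  structure (screening, response, complications, two-piece constant-hazard
  explant times over 24 months) and a Wald-CI estimator, used to validate
  the input-estimation pipeline end to end.

See `vignettes/cost-utility-model.Rmd` for the full model account, accrual
conventions and design decisions.

## Worked example

```r
library(scscea)

ps  <- default_parameters()        # Tables of base-case inputs, 2016 GBP
res <- evaluate_all(ps)            # decision tree + Markov, all three arms
res$arms$HF10
#> <scs_arm_result> HF10: total cost £86,924, total QALYs 5.149
res$comparisons$NRLF_vs_HF10
#> <scs_comparison> NRLF vs HF10: Δcost £7659, ΔQALY -0.926 — NRLF dominated by HF10
```

Over 15 years the 10 kHz strategy costs £86,924 per patient and yields 5.149
QALYs, against £94,583 / 4.223 for NRLF-SCS and £91,817 / 4.223 for RLF-SCS:
both low-frequency strategies cost more and deliver fewer QALYs, so 10 kHz
SCS is economically dominant and no ICER is reported. The probabilistic
analysis (`run_psa(ps, n = 5000, seed = 2026)`) prints

```
NRLF_vs_HF10: P(cost-saving) = 74.0%, mean saving £6,378 (95% CI £6,033-£6,724)
RLF_vs_HF10:  P(cost-saving) = 76.0%, mean saving £4,571 (95% CI £4,380-£4,761)
CEAC at £20,000/QALY: NRLF_vs_HF10 93.5%, RLF_vs_HF10 95.3%
```

i.e. 10 kHz SCS is cost-saving in about three quarters of joint parameter
draws and cost-effective at the £20,000/QALY threshold in over 90% of them.

The numbered drivers under `analysis/` run the full workflow and write
tables under `results/`:

```sh
Rscript analysis/01_synthetic_trial.R          # generator + input re-estimation
Rscript analysis/02_base_case.R                # deterministic totals and breakdowns
Rscript analysis/03_deterministic_sensitivity.R# tornado, threshold, scenarios
Rscript analysis/04_psa.R                      # 5000-draw PSA, CE plane, CEACs
```

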