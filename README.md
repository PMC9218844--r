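# prcea — cost-effectiveness microsimulation of pulmonary rehabilitation after COPD hospitalization

Pulmonary rehabilitation (PR) — supervised exercise training and education
started within 90 days of discharge from a hospitalization for chronic
obstructive pulmonary disease (COPD) — reduces first-year mortality and
readmission, but its uptake among US Medicare beneficiaries is very low.
`prcea` implements a patient-level Markov microsimulation that weighs the
cost of a PR program against the downstream savings and health gains, for
health-economics analysts who want to reproduce, probe, or extend the
published US cost-effectiveness case for PR.

## Model

Three Markov states with 1-year cycles: *alive in year 1 after the index
hospitalization*, *alive in subsequent years*, *dead*. For each simulated
patient (age ~ truncated normal 77 y [60–92], 58.6 % women, GOLD stage
2/3/4 = 30/48/22 %):

- **Year 1.** Death ~ Bernoulli(p₀ · HR_mort), readmission ~
  Bernoulli(r₀ · HR_readm), with p₀ = 0.141 (beta(382, 2328)), HR_mort = 0.50
  (log-normal, 95 % CI 0.42–0.59), r₀ = 0.638 (beta(1732, 972)), HR_readm =
  0.83 (0.77–0.90). Hazard ratios act multiplicatively on the probability
  scale and apply only under PR. Hospital days, ED visits and SNF days are
  drawn from arm-specific gamma distributions fitted to the published means
  and 95 % intervals (e.g. hospital days 7.9 [0–63] with PR, 11.7 [2.3–45.3]
  without). Survivors accrue the GOLD-stage EQ-5D utility
  (0.832/0.803/0.731), plus 0.065 under PR; decedents accrue zero QALYs.
- **After year 1.** PR has no further effect. Annual mortality = life-table
  baseline(age, sex) + a GOLD-stage excess (men 2.17–3.97 %, women
  1.68–3.07 %), scaled by a single multiplier calibrated so the no-PR
  cohort's mean life expectancy hits a target (8.85 y in the published
  base case). Survivors accrue the stage utility and a stage-stratified
  annual COPD cost ($3858/$5908/$6721).
- **Costs (2020 USD).** PR sessions (Poisson, mean 9; or a fixed count)
  at $89.04 reimbursement + $22.28 copay per 2-h session, plus round-trip
  travel (9.9 miles each way at fuel cost/fleet-mpg) under the societal
  perspective; hospital days at age-tiered daily rates ($2385/$2326/$2338);
  ED visits at $922; SNF days at $255. Costs and QALYs discounted at 3 %/y,
  first year undiscounted.

Incremental results (PR minus no PR) report Δcost, ΔQALY, dominance, and
net monetary benefit; the probabilistic sensitivity analysis (PSA) samples
the effect-estimate distributions in an outer loop over inner
common-random-number microsimulations and reports prediction intervals, the
probability PR dominates, and a cost-effectiveness acceptability curve.

## Worked example

```r
library(prcea)
registry <- default_registry()
draw     <- base_draw(registry)
model    <- calibrate_excess_mortality(8.85, mortality_model(draw = draw),
                                       draw, seed = 1)
cmp <- run_comparison(20000, draw, model, seed = 1)
cmp$incremental
#> <incremental_result: delta cost -5138, delta QALY 0.552, PR dominant, NMB(50000) = 32756>
```

PR costs $5,138 less per patient over a lifetime while adding 0.552
discounted QALYs, so it *dominates* no PR (better and cheaper; the ICER is
undefined). Strategy-level means from the same run — year-1 hospitalization
costs $27,154 (no PR) vs $18,352 (PR), ED $1,010 vs $918, readmission
63.3 % vs 52.2 %, year-1 QALYs 0.684 vs 0.801, life expectancy 8.90 vs
9.65 y — sit on the analytic values implied by the inputs (e.g. 11.7 days ×
$2326/day = $27,214). The PSA:

```r
psa <- run_psa(200, 2000, registry, seed = 1, model = model)
psa
#> <psa_result: 200 draws x 2000 patients>
#>   P(PR dominant) = 1.000
```

Scenario, one-way-sensitivity and threshold analyses are available through
`scenario_analysis()`, `one_way_sensitivity()` and
`threshold_cost_per_session()`; YAML-driven runs through `load_config()` /
`run_from_config()`, with tabular export via `write_results()` and
`write_psa()`. See the methods vignette (`vignettes/copd-pr-model.Rmd`) for
the modelling assumptions and their rationale.

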