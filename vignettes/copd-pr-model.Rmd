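---
title: "Modelling methods: pulmonary rehabilitation after COPD hospitalization"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling methods: pulmonary rehabilitation after COPD hospitalization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(prcea)
```

## The decision problem

After a hospitalization for an acute COPD exacerbation, starting pulmonary
rehabilitation (PR) within 90 days is associated with roughly halved
first-year mortality, a 17% relative reduction in first-year readmission,
fewer hospital/ED/SNF days, and a 0.065 gain in EQ-5D utility. A PR program
itself costs on the order of $1,000 per patient (observed attendance of ~9
two-hour sessions at $89.04 reimbursement plus $22.28 copay, plus travel).
`prcea` asks: over a lifetime, does universal PR after COPD hospitalization
save money and/or buy QALYs at an acceptable price, from the societal and
the health-system perspectives?

## Model structure and assumptions

The model is a three-state Markov microsimulation with annual cycles:
alive in the first year after the index admission, alive in subsequent
years, dead. Its central structural assumptions:

- **PR affects the first year only.** Mortality and readmission hazard
  ratios, arm-specific utilization distributions, and the utility increment
  apply in year 1; afterwards both arms face identical mortality, utility
  and cost processes. This is conservative: any durable benefit of PR is
  ignored.
- **Hazard ratios act multiplicatively on the probability scale**
  (`apply_hazard_ratio()`), capped at 1 — not through the rate-scale
  transform `1 - exp(HR * log(1 - p))`. The published PR readmission rate
  (53.3%) equals 0.638 × 0.83 = 53.0% on the probability scale, while the
  rate-scale transform would give 57.0%, so the probability-scale reading is
  the one consistent with the source model's arithmetic.
- **Utilization is arm-specific, not HR-adjusted.** Hospital days, ED visits
  and SNF days are drawn from the early-PR or late/no-PR gamma
  distributions; those distributions already embody the utilization effect
  of PR. The readmission Bernoulli exists to report the readmission *rate*;
  costs flow from the day/visit quantities. The two are sampled
  independently — the sources publish no joint structure.
- **Death-year accruals are zero** and there is no half-cycle correction:
  year-1 decedents collect no QALYs, and a patient who dies at the start of
  post-year-1 cycle *k* collects nothing in that cycle. This convention
  reproduces the published year-1 QALY arithmetic
  ((1 − 0.141) × 0.796 ≈ 0.68).
- **GOLD stage is fixed for life.** No disease progression is modelled.
- **Discounting** is 3% per year with the first cycle undiscounted
  (`discount(x, k, r) = x / (1 + r)^(k - 1)`), again matching the year-1
  QALY arithmetic; the rate is a registry parameter and can be set to any
  value, including 0.

## Parameters

`default_registry()` holds every model quantity with its base value and
uncertainty distribution (40 entries; see `?default_registry`). Three
fitting rules convert published summaries into distributions:

- **Gamma from mean and 95% interval** (`fit_gamma_from_summary()`): the
  analytic mean is constrained exactly (scale = mean/shape) and the shape
  minimizes the squared error of the 2.5th/97.5th percentiles against the
  printed interval. The mean is constrained exactly because it is the
  quantity that drives expected costs. Least squares is run on the raw
  percentile scale: several printed intervals (e.g. hospital days
  11.7 [2.3–45.3]) are not jointly attainable by any mean-11.7 gamma, and on
  the log scale the unattainable lower bound dominates the fit, dragging the
  upper percentile ~35% below its printed value; on the raw scale the fitted
  97.5th percentile lands within a fraction of a percent of the printed one
  while the lower tail absorbs the incompatibility. When the printed lower
  bound is 0 (e.g. 7.9 [0–63]) the lower constraint is dropped and the shape
  solves q97.5 = upper bound exactly; that equation has two roots because
  the mean-preserving q97.5 is unimodal in the shape, and the larger-shape
  root is taken — the near-zero-shape root is a degenerate spike-at-zero
  gamma whose cohort means would be dominated by rare extreme draws.
- **Log-normal from a ratio and 95% CI** (`fit_lognormal_from_ratio()`):
  location = log(point), spread = CI width on the log scale divided by
  2 × 1.959964.
- **Beta from mean and 95% CI** (`fit_beta_from_mean_ci()`): mean exact,
  concentration by least squares on the two percentiles (used for the
  EQ-5D utilities).

Counts with stated beta/Dirichlet parameters (sex beta(115 690, 81 686),
GOLD Dirichlet(75, 121, 57), mortality beta(382, 2328), readmission
beta(1732, 972)) are carried verbatim. PR session counts use the stated
Poisson family with mean 9; the printed IQR (4–14) is wider than Poisson
dispersion allows, but the stated family is followed. The fixed-session
mode (16, varied 8–36; 36 for threshold analysis) is available via
`strategy_spec(session_mode = "fixed")`.

## The synthetic cohort

`generate_cohort()` emulates the study population: age from a truncated
normal (main analysis mean 77, bounds 60–92; younger sensitivity population
mean 65, bounds 50–85), sex Bernoulli(0.586), GOLD stage categorical on
(0.30, 0.48, 0.22). The sources publish only the age mean and range, so the
pre-truncation SD is set to range/6 (≈ 5.33 y), the conventional
range-to-SD heuristic; the model's age dependence (hospital-cost tier,
life-table baseline) is mild, so this choice has little leverage. The range
is treated as hard truncation. The generator reproduces marginal moments
only — it carries no comorbidity, smoking, geography, or correlation
between age, sex and stage, none of which enter the model. Passing
distribution-recovery tests therefore validates the simulation machinery,
not the realism of any joint structure in real Medicare data.

## Post-year-1 mortality and calibration

Annual mortality after year 1 is baseline life-table mortality by age and
sex plus a sex- and GOLD-stage-specific excess (men 2.17–3.97%, women
1.68–3.07% across stages 2–4; stage 3 at the midpoint of each range, since
only the stage-2 and stage-4 endpoints are published). The packaged life
table (`life_table_synthetic.csv`) is a synthetic Gompertz–Makeham
construction at current US mortality levels — the original source table is
not published — and any table with columns `age, qx_female, qx_male` can be
supplied instead. Because the baseline is synthetic,
`calibrate_excess_mortality()` scales the excess rates by a single shared
multiplier (bisection on [0.1, 10], life-expectancy tolerance 0.05 y at a
fixed seed and 20,000-patient calibration cohort) so that the no-PR
cohort's mean undiscounted life expectancy matches a chosen target — 8.85 y
for the published base case. A single multiplier preserves the published
sex/stage gradient while matching overall survival.

## Randomness, common random numbers, and the PSA

All streams are named substreams of one master seed (`substream_seed()`):
cohort generation, year-1 event uniforms, and post-year-1 survival uniforms
are independent, and none depends on the strategy, so the PR and no-PR arms
of a comparison consume identical uniforms (common random numbers). Under
null effects the two arms are then *identical* except for the PR program
cost — a sharp identity the tests exploit — and incremental contrasts have
much lower Monte-Carlo variance. CRN can be broken simply by running the
arms with different seeds.

The PSA (`run_psa()`) draws parameters in an outer loop and runs a paired
inner microsimulation per draw. Two design choices matter:

- **Scope and the meaning of the printed intervals.** The default scope
  samples every parameter with a stated distribution *except* the cohort
  descriptors (sex, GOLD shares, travel distance, session count). For the
  narrow hazard-ratio/utility-increment-only reading, pass
  `default_psa_scope(mode = "narrow")`. The printed 95% intervals for
  per-person-year utilization and per-accrual costs (e.g. hospital days
  2.3–45.3, ED $228–$2725) describe patient-level heterogeneity, not
  uncertainty in the mean — treating them as the latter would make
  strategy-level prediction intervals an order of magnitude wider than the
  published ones. These entries are therefore tagged `psa = "mean"`: the
  outer loop draws the *sampling distribution of the mean* of `n_eff`
  observations (Gamma(shape × n_eff, scale / n_eff); `n_eff` defaults to
  2704, the propensity-matched source-cohort size implied by
  beta(1732, 972)), and the inner patient-level draws use the full gamma
  rescaled to the drawn mean.
- **Inner seeding.** The same inner substream is reused across outer draws,
  so between-draw variation isolates parameter uncertainty, and an empty
  scope yields exactly zero between-draw variance. Prediction intervals are
  2.5th/97.5th percentiles of per-draw incremental means; the CEAC reports,
  per willingness-to-pay, the share of draws with positive net monetary
  benefit for PR.

## Numerical choices

- Gamma/beta fitting: 1-D `optimize()` on the log-shape/log-concentration
  over [1e-4, 1e6]/[2, 1e8], tolerance 1e-10; one-sided gamma fits use
  `uniroot()` on the upper shape branch (tolerance 1e-12).
- Calibration bisection: at most 60 iterations, stops at half the 0.05-y
  tolerance or a multiplier interval below 1e-6; monotonicity of life
  expectancy in the multiplier guarantees convergence.
- Threshold search (`threshold_cost_per_session()`): bisection to $1 on
  [$0, $10,000] per session. Each evaluation re-runs the paired comparison
  at the same seed, so the objective is deterministic and linear in the
  session cost; the root criterion is net monetary benefit = 0, which
  reduces to incremental cost = 0 for the cost-saving threshold.
- Truncated distributions sample by inverse-CDF restriction, so truncation
  never changes the number of uniforms consumed.
- Degenerate inputs: zero-width intervals collapse to point masses;
  `n = 0` cohorts are valid and empty; certain-death mortality models give
  survivors exactly one post-year-1 accounting year of zero accrual.

## Problem sizes

Package defaults and the bundled analysis script use cohorts of
10,000–50,000 patients for strategy-level means, 100,000 for
distribution-recovery checks, 20,000 for calibration, and a 200 × 2,000
PSA; the full-scale published design (1000 draws × 10,000 patients) is a
parameter choice away (`run_psa(1000, 10000, ...)`) and scales linearly in
both dimensions.

## Known limitations and non-reproducible published quantities

- The published SNF cost (no PR $2664) is ~2.7× what 2.97 days at any
  daily cost within the stated uniform(173, 500) can produce; the SNF
  costing formula is not recoverable, so SNF components (and through them
  the exact printed savings figures) are reproduced only approximately.
- The composition of the published $1749 PR program cost is unresolved
  (mean sessions × $111.32 ≈ $1002 plus an unexplained remainder); the
  travel cost-per-mile is likewise under-determined, so the default is a
  conservative fuel-only $0.116/mile (=$2.32/gal ÷ 20 mi/gal), with both
  the fuel price and fleet economy configurable.
- Published lifetime totals and the $171/$884/$1597 per-session thresholds
  inherit these gaps; the package asserts their structural properties
  (threshold ordering, dominance, calibration) rather than their printed
  values.
- The published first-year no-PR mortality (13.1%) differs from its own
  stated input (beta mean 14.1%); the stated input is implemented.
- No dose–response of PR sessions on outcomes, no within-year event timing,
  no disease progression, no productivity or caregiver costs — all
  exclusions shared with the source model.
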