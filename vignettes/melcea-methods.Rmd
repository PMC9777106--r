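---
title: "Methods: multistate cost-effectiveness analysis of melanoma treatment sequences"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multistate cost-effectiveness analysis of melanoma treatment sequences}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The model

`melcea` evaluates sequential advanced-melanoma treatment strategies with a
three-state multistate model: *first line of treatment* (L1), *subsequent
lines* (L2+), *death*. Every patient starts in L1; exits from L1 are a
competing-risk pair (progression to a second line vs death), and the L2+
sojourn is *clock-reset* (semi-Markov): its distribution depends on time
since L2 entry, not on calendar time. This matches how line-of-therapy data
are recorded — a patient's prognosis after switching lines is driven by how
long they have been on the new line — and it is the assumption the synthetic
generator, the estimator and the occupancy integrator all share. All times
are in months; years are months/12.

The estimation chain per strategy is:

1. **Weighting.** Treatment allocation in routine care depends on prognosis,
   so each patient is weighted by the inverse of the estimated probability
   of the strategy actually received (IPTW, ATE estimand: every arm is
   reweighted to the pooled population). Propensities for the K strategies
   come from K one-vs-rest gradient-boosted logistic tree ensembles with
   per-patient renormalization of the predicted probabilities.
2. **Transition curves.** Weighted Kaplan–Meier estimators for the all-cause
   L1 exit and for the L2+ sojourn; a weighted Aalen–Johansen estimator
   splits L1 exits into their two causes per monthly cycle.
3. **Extrapolation.** Each KM curve is extended to the analysis horizon by a
   parametric tail fitted by weighted maximum likelihood and selected by
   minimum AIC among exponential, Weibull, lognormal, log-logistic and
   Gompertz; the tail is rescaled to pass through the KM value at the
   attachment point, so the spliced curve is continuous.
4. **Occupancy.** Discrete-time product integration on the monthly grid:
   L1 occupancy is the extrapolated all-cause exit survival; per-cycle exits
   split by the cause-specific share; each L2-entry cohort is tracked with
   the clock-reset sojourn curve; death absorbs the remainder, so
   P_L1 + P_L2 + P_dead = 1 holds to machine precision by construction.
5. **Economics.** Discounted cost and QALY accumulation over cycles with
   per-(strategy, line) monthly costs and utilities, a one-off
   palliative-care cost in the cycle of death, and discount factor
   (1 + r)^(−t/12).
6. **Decision analysis.** Strict-dominance efficiency frontier, sequential
   ICERs, stratified non-parametric bootstrap with percentile intervals, and
   cost-effectiveness acceptability curves from net monetary benefit.

# Parameters that matter

| Parameter | Default | Units | Why |
|---|---|---|---|
| `horizon_months` | 120 | months | 10-year reference horizon; 60 and 180 in sensitivity scenarios |
| `discount_rate` | 0.04 | /year | French reference-case rate; 0 in sensitivity scenarios |
| `replicates` | 1000 | — | bootstrap replicates for percentile CIs |
| `max_trees` | 600 | trees | upper bound for the boosted propensity model |
| `shrinkage` | 0.01 | — | slow learning rate; see the stopping rule below |
| `interaction_depth` | 2 | — | shallow trees capture pairwise prognostic interactions |
| `truncation_quantile` | none | — | optional weight cap; logged whenever applied |
| attachment fraction | 0.10 | — | extrapolation attaches at the last event time with ≥ 10% of the initial weighted risk set |

# The propensity stopping rule

The boosting iteration count is not chosen by predictive loss. Candidate
counts on a grid (every 100 trees, plus an intercept-only 0-tree model whose
probabilities are the empirical arm shares) are scored by the mean absolute
standardized mean difference across all expanded covariates and
strategy-vs-pooled comparisons, computed under the weights each candidate
implies, and the minimizer is kept. Including the 0-tree candidate lets the
criterion refuse to boost when the arms are already balanced. SMDs use the
difference in weighted means divided by the *unweighted full-sample* SD
(population form, so a binary covariate's denominator is √(p(1−p)) of the
full-sample proportion): a stable denominator makes the metric comparable
across iterations. The learning rate of 0.01 follows standard practice for
balance-targeted boosting; faster rates let the ensemble chase sample noise,
which shows up as propensities spread far from the truth under null
confounding even while measured balance keeps improving. Categorical
covariates are expanded to indicator columns; missing covariate values are
rejected outright (imputation is out of scope).

# Numerical choices

- **Half-cycle correction is the default.** Cycle sums use the trapezoidal
  average of the occupancy endpoints with discounting at the cycle midpoint,
  and the L2 convolution credits entrant cohorts at half-cycle sojourn
  offsets. Left-step sums on a monthly grid of a smooth survival curve carry
  an O(cycle) bias — about +5% on the restricted mean of an exponential with
  rate 0.1/month — while the trapezoidal scheme is O(cycle²) and reproduces
  closed-form restricted means to well under 1% at monthly cycles (the test
  suite checks this against the analytic exponential solution and a 100k
  patient microsimulation). `half_cycle = FALSE` restores plain left sums,
  which are exact when the integrand really is a right-continuous step
  function.
- **Competing risks.** Cause-specific exits from L1 are split by
  Aalen–Johansen cumulative-incidence increments per cycle, not by
  independent cause-specific KMs, to avoid the classical upward bias and to
  keep occupancy conservation exact; cycles without observed exits (and the
  whole extrapolated region) fall back to the overall cumulative split.
- **Tail selection.** Minimum AIC with ties broken in the family order
  exponential, Weibull, lognormal, log-logistic, Gompertz (simplest first).
  If no family converges, an exponential moment estimator (weighted events /
  weighted exposure) is used with a warning. Fitting requires at least five
  weighted events; all-censored input is an error.
- **ICER reporting.** Ratios are rounded half-away-from-zero to integer
  EUR/QALY, isolated in `round_half_away()`. Worked-example reproduction
  feeds printed-precision inputs (one-decimal QALYs, integer EUR), because
  published incremental ratios are computed from printed deltas; pipeline
  outputs are used at full precision. A zero QALY delta is reported as a tie
  rather than a ratio.
- **Discounting.** Monthly compounding, (1 + r)^(−t/12); whether published
  analyses compounded annually or continuously is typically unstated, and at
  4%/year the conventions differ by under 0.1% over 10 years.
- **Degenerate inputs.** Zero transition rates are legal (the transition
  never fires; an all-zero configuration yields a cohort fully censored at
  the horizon); negative rates, propensities of exactly zero, single-arm
  propensity fits and empty KM inputs are errors.

# Decision-analysis conventions

- **Extended dominance is OFF by default.** With strict dominance only, a
  cost-ordered frontier may legitimately contain non-increasing sequential
  ICERs; the published wild-type frontier retains a strategy whose upstream
  ICER exceeds the downstream one, so reproducing it requires the strict
  rule. `extended_dominance = TRUE` applies the standard iterative removal,
  after which reported ICERs strictly increase (both behaviors are tested).
- **Bootstrap.** Resampling is stratified by strategy to preserve arm sizes,
  and the propensity model is refitted inside every replicate, so the CIs
  reflect the weighting step's own sampling variability. Replicate seeds are
  drawn from one stream: doubling the replicate count reproduces the first
  half. Failed replicates are skipped and logged; more than 10% failures
  aborts.
- **CEAC.** At each willingness-to-pay λ the probability that a strategy
  maximizes λ·QALY − cost across replicates; within-replicate ties are split
  equally, so probabilities sum to one exactly.

# What the synthetic generator emulates — and what it does not

`simulate_cohort()` reproduces the statistical *structure* the pipeline
assumes: ten prognostic baseline covariates at realistic prevalences
(binary and categorical, including "unknown" levels), multinomial-logit
treatment assignment confounded by prognosis with the exact true
propensities returned for oracle tests, exponential (optionally Weibull,
optionally covariate-dependent proportional-hazards) transition times with
clock reset at L2 entry, uniform accrual over 66 months with an
administrative cut at month 66 plus exponential drop-out, truncated-normal
monthly cost draws floored at zero, and utility observations at line entry,
every 3 months and at line change, truncated to the French EQ-5D index
range [−0.53, 1].

Default sojourn rates are calibrated *loosely* to published mean 10-year
state-occupancy times per sequence (exit rate = 1/mean L1 months; share
entering L2 set to 0.60 / 0.45 for the mutated / wild-type populations from
observed second-line frequencies), and cost/utility means to the published
per-line tables. Per-sequence transition-time *distributions* were never
published, so the generator is a structural stand-in, not a re-creation of
the source cohort: passing tests demonstrate that the estimation machinery
is correct under the stated model, not that any real-data estimate is
reproduced. Real cohorts additionally carry informative censoring,
time-varying costs, utility trajectories within lines (a longitudinal
repeated-measures model is out of scope — the package consumes utility
indices directly) and more than one distinct subsequent line, none of which
the generator produces. Utility SDs are not published per line; the default
of 0.2 is a typical EQ-5D-3L dispersion.

All randomness flows from one master seed expanded into independent
per-stage streams (covariates, assignment, transitions, economics,
bootstrap, microsimulation — in that order), so regenerating one stage never
perturbs another.

# Problem sizes

The shipped tests run the generator at 10,000–20,000 patients for balance
and null-effect checks, 100,000 draws for the microsimulation oracle, and
scale the bootstrap demonstrations to 200 replicates with a 100-repetition
coverage experiment; these sizes give Monte-Carlo error comfortably inside
the asserted tolerances while keeping the default suite fast.

# Known limitations

- Two aggregated treatment lines only; micro-costing categories are
  collapsed into one monthly total per line.
- Costs and utilities are stationary within a line over the whole horizon.
- Extrapolation rests on the usual single-arm parametric assumptions; with
  immature follow-up the tail family choice, not the data, drives much of
  the 10-year mean (the sensitivity scenarios vary horizon and discounting,
  not the tail family).
- IPTW corrects measured confounding only.
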