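---
title: "Methods: the PD-first versus HD-first Markov cost-utility model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the PD-first versus HD-first Markov cost-utility model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette is the package's account of its science: the model and its
assumptions, the estimation procedures around it, the numerical choices made
where the design was genuinely open, and the limits of what the shipped
synthetic data can demonstrate.

## The decision problem

Patients with end-stage kidney disease (ESKD) who need dialysis can start on
peritoneal dialysis (PD) or hemodialysis (HD). Thailand's universal-coverage
"PD-first" policy makes this an explicit policy comparison: per
quality-adjusted life-year (QALY) gained, is starting patients on HD worth
its extra lifetime cost? The package answers with a cost-utility analysis:
lifetime discounted costs, life-years (LY) and QALYs per strategy, their
incremental cost-effectiveness ratio (ICER), one-way and probabilistic
sensitivity analyses, and a cost-effectiveness acceptability curve (CEAC)
against a willingness-to-pay (WTP) threshold of 4,766 USD/QALY.

## Model structure

A five-state Markov cohort model with annual cycles:

* `PD`, `HD` — on the modality, no chronic complications;
* `PD_CC`, `HD_CC` — on the modality with chronic complications
  (cardiovascular disease, stroke, CKD-related mineral and bone disorders);
  there is no reverse transition to the complication-free state;
* `DEATH` — absorbing.

A cohort enters fully in the state of its initial modality and is propagated
until the living mass falls below `1e-8` or the cohort reaches the age cap
(100 years); both are configurable. Acute complications (peritonitis,
vascular-access infection) are transient within-cycle events: they carry an
expected cost add-on per cycle (`p_acute * acute add-on cost`) but no state
change and no utility decrement, because the parameter set prices acute
events but provides utilities only by chronic status.

Transition parameters are indexed by the *initial-modality stratum*: a
PD-first patient who switches to HD keeps the PD-first stratum's parameters
(including the "HD to HD with chronic complications" probability listed in
that stratum), mirroring how the source estimates are organised.

### Within-cycle composition

The published model gives no ordering of competing events, so a choice was
needed. Death is resolved first (from the mortality model, state- and
age-dependent), then the modality-switch and chronic-complication
probabilities apply to the survivors, with the remainder staying put. If
competing probabilities sum above one they are renormalised proportionally
with a warning — a signal of implausible inputs, not an error. Chronic
states may also switch modality (`PD_CC -> HD_CC`), using the stratum's
switch probability; a flag (`switch_from_chronic`) disables this.

Cycle length is one year with **no half-cycle correction** by default; the
reference implementation used a commercial tool's defaults and does not say,
so the package default is plain beginning-of-cycle accrual, with
`half_cycle = TRUE` available. Set-up cost is charged at entry and again on
each expected modality switch (vascular access and PD catheters are both
real one-time costs); `setup_on_switch = FALSE` disables the second charge.

### Accrual and discounting

Per cycle `t` each living state's start-of-cycle occupancy contributes
discounted LY, QALYs (occupancy times the state utility) and cost (annual
state cost plus expected acute add-on), with `d(t) = 1/(1+r)^t` and r = 3%
per year. The *government* perspective counts direct medical costs only; the
*societal* perspective adds direct non-medical (travel, food, caregiver)
and indirect (productivity-loss) costs. All costs are 2021 USD at
33.57 THB/USD.

## Parameters and their uncertainty distributions

The canonical parameter file (`inst/extdata/table1.yaml`) holds each
estimate as mean, 95% interval and a distribution family for probabilistic
sensitivity analysis: beta for probabilities and utilities, gamma for
non-medical/indirect costs, exponential for annual medical costs, uniform
(±10%) for set-up costs.

The source material never states how interval estimates were converted to
distribution parameters, so the package uses a symmetric
normal-approximation convention: target sd = (high − low)/(2×1.96), then
method-of-moments inversion with the mean matched exactly. Consequences
worth knowing:

* an exponential distribution has one parameter, so it is anchored at the
  point estimate as its mean and the printed interval is recorded but not
  matched;
* gamma rows with a zero lower bound (indirect costs) keep the same sd
  convention; a gamma cannot draw exactly zero, accepted as an
  approximation;
* beta inversion rejects intervals whose implied variance is infeasible
  (`var >= mean(1-mean)`).

PSA draws are mutually independent (no correlation structure is given for
the source estimates). A draw that violates a structural invariant — e.g. a
chronic-state utility sampled above its complication-free counterpart — is
resampled and counted. Sampling start age in the PSA is supported in
principle by the distribution machinery but is off by default: the source
says age was sampled from a gamma distribution but gives no parameters, so
the package treats age as fixed per scenario.

## Mortality

Survival follows a Weibull accelerated-failure-time (AFT) model,
`S(t|x) = exp(-(t e^{-x'b} / scale)^shape)`, with a proportional-hazards
multiplier `chronic_hr >= 1` on the cumulative hazard in chronic states.
Annual death probabilities are `1 - S(t+1|x)/S(t|x)`; chaining them exactly
reproduces `S`. Age enters through the linear predictor as a fixed
covariable of the start age — the cohort does not age through the
coefficient; duration-dependence is carried by the Weibull shape. This is a
documented simplification.

Two paths provide a mortality model:

1. **Fitting** (`fit_weibull()`): maximum-likelihood AFT regression via
   `survival::survreg()` for users with patient-level data.
2. **Calibration** (`calibrate_mortality()`): the reference analysis never
   printed its fitted Weibull coefficients, so downstream reproduction
   recovers a minimal model per stratum — shape, scale, a cubic age
   polynomial on the AFT scale (age, age²/100, age³/10⁴) and the chronic
   hazard ratio — by least squares against the published discounted
   life-year targets at start ages 20–60. Those targets are treated as
   discounted at 3% (consistent with the stated discounting of both costs
   and outcomes); `discount = FALSE` switches to undiscounted calibration.

Calibration numerics: a deterministic five-point Nelder–Mead multi-start
with a final polish; the chronic hazard ratio is constrained to (1, 5)
through a logistic transform. The bound matters: unconstrained fits can
push the ratio to implausible values (>50) that empty the chronic states —
buying a slightly better life-year fit at the price of a distorted state
mix and implausible epidemiology. The quadratic/cubic age terms give the
age–life-year curve enough curvature to meet the 0.1-LY RMS contract
without touching the state composition. The shipped fixture
(`inst/extdata/calibrated_mortality.json`) is exactly the output of
`calibrate_mortality_all(default_params())` and achieves RMS ≈ 0.03 LY
(PD-first) and ≈ 0.05 LY (HD-first). All reproduction-style results in this
package are conditional on this calibrated fixture and are labelled as
such; they are not the original fitted model.

## Estimation procedures

**Direct medical costs** follow a six-step aggregation of visit-level
billing records: re-categorise 189 raw labels into eight groups; window
each patient's visits into 30-day observations; pool patients; inflate each
observation to 2021 THB with a user-supplied index series; classify
observations into eight (treatment × complication) groups; summarise and
convert to USD. The windowing anchor is unstated in the source; the package
anchors non-overlapping 30-day windows at each patient's first visit, with
calendar-month windowing as an option. Money is conserved: total USD out
equals total inflated THB in divided by the fx rate.

**Non-medical and indirect unit costs** are summarised as median and IQR
per visit; totals multiply the median by follow-up visits or hospital days.

**EQ-5D utilities**: responses on the five dimensions are scored with an
additive tariff (constant minus per-dimension decrements; full health
scores 1). The official Thai value set is licensed and is *not*
redistributed: the tariff is a pluggable CSV, and a clearly synthetic "toy"
tariff ships for tests. Treatment-group utilities are estimated by IPWRA:
a logit propensity model of assignment, inverse-probability-weighted linear
outcome models per treatment, and potential-outcome means averaged over the
full sample, overall and by chronic status. Propensities are truncated at
[0.01, 0.99] with a warning (the source reports no overlap handling);
perfect separation is an error. Standard errors use the weighted outcome
model's HC1-robust covariance at the mean covariable profile and do not
propagate propensity-estimation uncertainty — slightly anti-conservative,
acceptable for the recovery checks it supports. The "complications"
adjuster in the outcome model is the chronic indicator only; whether acute
events belonged there is ambiguous in the source.

## Synthetic data: what it does and does not show

`generator_spec()`/`generate_cohort()` produce a patient-level cohort with
the statistical structure the estimation stages assume: treatment
assignment confounded with age, diabetes and cardiovascular disease through
a logit model; Weibull event times with AFT covariable effects and
administrative censoring over a nine-year window; gamma 30-day billing
costs split across raw labels; EQ-5D profiles whose toy-tariff scores hit
the true cell means in expectation (per-dimension level probabilities are
solved from the target decrement). True utilities, switch rates and acute
rates default to the canonical parameter means; covariable marginals
(age 55 ± 12, 40% diabetes, 70% hypertension, …) are illustrative package
constants, since no baseline table was available to copy.

The confounding strength (assignment-age log-odds 0.05/year; utility-age
slope −0.004/year) was set by a power argument: it makes the naive group
means biased by several standard errors at n = 10,000 so the
"IPWRA corrects, naive does not" contrast is demonstrable, while keeping
propensities far from the truncation bounds.

Passing recovery tests on this cohort shows the estimators are implemented
correctly under their own assumptions — correctly specified propensity and
outcome models, non-informative censoring, independent visits. It does not
show robustness to the misspecification, informative censoring, or billing
idiosyncrasies of real hospital data; the generator makes no attempt to
mimic 189 real billing categories (12 representative labels stand in).

## Sensitivity analyses

* **Tornado** (`tornado()`): each parameter in turn to its interval bounds
  (±10% for set-up costs — the source does not state its ranges), others at
  base, at the published analysis's median initiation age of 55.7 years,
  societal perspective; entries ranked by ICER span. Non-monotone responses
  are possible and entries with an undefined ICER at a bound are flagged
  rather than ranked.
* **PSA** (`run_psa()`): 5,000 iterations by default, seeded and
  reproducible; results as per-draw (cost, QALY) pairs, an ICE plane plot,
  and bootstrap Monte-Carlo standard errors of the mean increments.
* **CEAC** (`ceac()`): preference by net monetary benefit
  `wtp*QALY − cost` per draw; ties split equally; WTP grid 0–60,000
  USD/QALY in steps of 100 by default. `crossover_wtp()` linearly
  interpolates the 0.5 crossing; dominance everywhere yields a signalled
  `NA`.

## Problem sizes used in the shipped checks

The test-suite and acceptance-script sizes are the package's own choices,
balancing Monte-Carlo resolution against desk-scale runtimes: 10⁶ draws for
distribution-inversion spot checks, a 10⁵-patient microsimulation as the
cohort-engine oracle, the full n = 10,000 synthetic cohort for estimator
recovery, and the full 5,000-iteration PSA.

## Known limitations

* The calibrated mortality fixture reproduces published *life-years*; QALY
  and cost agreement (observed within about ±6% on the government
  perspective) is a consequence, not a constraint, because the original
  Weibull fit is unavailable. Societal-perspective absolute costs inherit
  any difference in non-medical cost accrual conventions.
* One switch probability per stratum covers both directions of switching
  after the first switch; patients who switch twice are rare but possible
  in the model.
* No competing risks, no tunnel states for acute events, no kidney
  transplantation, automated PD or hemodiafiltration.
* Discounted results depend on the beginning-of-cycle accrual convention;
  enabling `half_cycle` shifts LY by roughly half a cycle's occupancy.
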