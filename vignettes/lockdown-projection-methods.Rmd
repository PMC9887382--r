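---
title: "Forecasting interrupted anti-VEGF demand and projecting untreated visual acuity"
author: "amdforecast"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Forecasting interrupted anti-VEGF demand and projecting untreated visual acuity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(amdforecast)
```

# The problem

Anti-VEGF therapy is the standard of care for neovascular age-related
macular degeneration (nAMD), and delaying its initiation costs vision that
is largely not recovered. When a service interruption (here, the first UK
national lockdown, ISO weeks 12–31 of 2020) prevents newly presenting
patients from starting treatment, planners need an estimate of (a) how
many patients are affected and (b) how much acuity they stand to lose
while untreated. Because withholding anti-VEGF is no longer ethical, the
untreated counterfactual must come from historical trial data: we use a
sham-control arm — participants who received mock injections and no active
drug — as the source of untreated visual-acuity (VA) trajectories.

This vignette documents the model at each stage, the tunable parameters
and their defaults, the numerical conventions, and what the synthetic-data
generators do and do not emulate.

# Visual-acuity scales and record normalisation

All acuities are handled in approximate ETDRS letters (0–100, higher is
better, 85 ≈ normal). Snellen fractions are converted with

$$\text{letters} = 85 + 50 \log_{10}(\text{numerator}/\text{denominator}),$$

rounded half-up and clamped to $[0, 100]$. The source publications state
three Snellen/letter equivalences (6/12 ↔ 70, 6/96 ↔ 25, 3/60 ↔ 20)
without printing a formula; this standard conversion reproduces all three,
which is why it was adopted. The rounding convention (half-up, via
`round_half_up()`) is likewise an assumption: the equivalences do not pin
it down, but half-up matches how the printed values behave and is applied
uniformly to letters, counts and percentages.

Ages arrive only as six deidentified bands (`<65` … `85+`). Wherever a
model needs a number, the band midpoint is used, with 60 and 88 years for
the two open bands — a deliberate, crude imputation that any user with
numeric ages should replace. The study eye is the first eye diagnosed,
right eye on ties. Summaries report sample (n−1) standard deviations, with
the convention that a single observation has sd 0 so tables stay numeric,
and the two centres are compared with a Welch (unequal-variance) t-test
computable from summary statistics alone, so it can also be evaluated on
published tables.

# Forecasting weekly initiations

Each centre's weekly count series $y_t$ (2018-W01 through 2020-W11, 115
contiguous ISO weeks) is treated as additive: trend + seasonal + random.
`decompose_additive()` implements the classical decomposition — centred
moving average of window $m$, per-period averages of the detrended series
re-centred to sum to zero — and is used both as a diagnostic and to
initialise smoothing.

`fit_holt_winters()` implements additive Holt–Winters recursions with
level $\ell$, trend $b$ and $m$ seasonal indices:

$$\ell_t = \alpha (y_t - s_{t-m}) + (1-\alpha)(\ell_{t-1} + b_{t-1}),\qquad
  b_t = \beta (\ell_t - \ell_{t-1}) + (1-\beta) b_{t-1},\qquad
  s_t = \gamma (y_t - \ell_t) + (1-\gamma) s_{t-m}.$$

Design choices the method description leaves open, and how they were
resolved:

* **Seasonal period** $m = 52$ weeks: one annual cycle of a weekly series.
  Week 53 of 2020 lies beyond the forecast horizon and needs no special
  handling.
* **Initialisation**: $\ell_0, b_0$ from a least-squares line through the
  trend component of the first two cycles' decomposition; initial seasonal
  indices from the same decomposition (they sum to zero by construction).
  On any noiseless trend-plus-seasonal series this initialisation is
  exact, so one-step residuals vanish for *any* smoothing parameters — the
  property the test suite pins at 1e-6.
* **Parameter selection**: when not supplied, $(\alpha,\beta,\gamma)$
  minimise the in-sample one-step squared error over $[0,1]^3$, seeded
  from a coarse grid (3×3×3) and polished with L-BFGS-B. A grid seed
  guards against the flat, multimodal SSE surfaces that short noisy count
  series produce.
* **Prediction intervals**: Gaussian, $\hat y_{t+h} \pm 1.96\,
  \hat\sigma\sqrt{h}$ with $\hat\sigma$ the one-step residual RMS — the
  usual exponential-smoothing approximation, chosen because the original
  figures show 95% bands without a formula. Points and lower bounds are
  truncated at zero (counts).
* **Window total**: the rounded sum of *unrounded* weekly points, so
  per-week rounding cannot accumulate.

Each centre is fitted and forecast independently; all available
pre-interruption weeks are used for fitting, since the sources do not say
whether the weeks of early 2020 were included and there is no reason to
discard them.

# Sampling the hypothetical cohort

The forecasted number of profiles per centre is drawn uniformly from the
historical pool of patients whose treatment began in the same calendar
window (ISO weeks 12–31) of 2018 or 2019, pooled jointly across the two
years. Sampling is without replacement whenever the forecast does not
exceed the pool, with replacement (and a logged notice) otherwise.
Sampled profiles keep every covariate of their source record and receive
a fresh id suffixed with the draw index, so duplicate draws remain
distinguishable downstream.

# Eligibility, propensity and matching

Trial-eligibility screening precedes matching: profiles with baseline VA
outside $[25, 70]$ letters are excluded a priori and routed to the
model-based projection. The trial's own acuity bounds are not printed
anywhere we could find; 25 and 70 letters are the two clinically meaningful
thresholds the analysis already uses (the treatment floor and the
good-vision cutoff), and they reproduce the observed pattern that most
non-matched patients at the larger centre had VA ≥ 70. The window is a
parameter (`screen_eligibility(va_min, va_max)`), not a constant.

`fit_propensity()` fits a maximum-likelihood logistic regression of
cohort-vs-sham membership on age-band midpoint, sex (female = 1) and
baseline VA — exactly the three covariates named by the source — and
exposes per-subject scores on the probability and logit scales.
(Quasi-)perfect separation and singular designs raise errors rather than
producing degenerate matches.

`match_within_calliper()` performs greedy best-first 1:1 matching without
replacement: all cross-group pairs within the calliper are admitted in
ascending $|\Delta \text{logit}|$, ties broken lexicographically by
(profile id, participant id) so the result is deterministic and invariant
to input order. The calliper is $0.1 \times$ SD of the logit propensity
over *all* fitted subjects (the reference population is unstated in the
source; pooling is the common default). Best-first greedy was chosen over
optimal matching because the source says only "matched", greedy is the
standard calliper algorithm, and an exhaustive best-first oracle in the
test suite pins its behaviour exactly on small instances. A description
elsewhere in the source of patients "matched exactly" on age, sex and VA
is read as shorthand for this calliper procedure on those covariates.

# Trajectory projection

Projections are evaluated at months $\{0, 3, 6, 12\}$, the timepoints the
outcome tables report.

**Matched patients** inherit their partner's *change from baseline*:
$\text{VA}(t) = \text{clamp}(\text{VA}_0 + (\text{partner VA}(t) -
\text{partner VA}_0),\ 0,\ 100)$. Carrying the change rather than the
partner's absolute VA preserves the cohort's own baseline distribution,
which is what the pooled baseline bars of the original outcome figure
show; this was a genuinely open choice and is flagged as such. Missing
partner months are linearly interpolated between adjacent visits, and
trailing gaps carry the last observation forward. By linearity, the
matched cohort's mean projected change equals its partners' mean change
exactly (before clamping) — a property the tests assert.

**Unmatched and ineligible patients** are projected with one ordinary
least-squares model per horizon month — VA(t) on age midpoint, sex and
baseline VA, fitted on sham participants only. One model per month was
preferred over a single model with time as a covariate because "simple
linear model" is ambiguous and per-month fits make no linearity-in-time
assumption. Predictions are clamped to $[0, 100]$; a profile whose
baseline VA lies outside the training range is still projected but logged
as an extrapolation. Clamping can only shrink the magnitude of a
projected change, never inflate it.

# Outcome tables

`apply_locf()` completes every trajectory on the full month grid by
carrying the last observation forward, which keeps the denominator
constant across months — the convention the original outcome figure
states. `summarize_outcomes()` then reports, per month: n, mean and
sample SD of VA, and the counts/percentages for the three thresholds with
their printed boundary conventions — **≥ 70** inclusive, **< 25** strict,
**≤ 20** inclusive. Percentages are reported to one decimal place.
`pool_cohorts()` recombines matched and modelled subgroups: counts add,
means recombine size-weighted, and SDs recombine with the pooled-variance
formula including the between-group mean-shift term under the (n−1)
convention.

# The synthetic-data generators

The generators exist so the pipeline runs and is testable without the
private hospital and trial records. They emulate:

* **Weekly counts**: Poisson draws around
  $\max(0,\ \text{level} + \text{trend}\cdot t +
  \text{amplitude}\cdot\sin(2\pi(\text{week}+\text{phase})/52))$. Default
  levels are 16.25 and 2.55 counts/week — the two centres' published
  20-week totals (325 and 51) divided by 20, which also agree with their
  cohort sizes over the 115-week history. The sinusoidal annual cycle is a
  modelling choice (the sources show seasonality but do not parameterise
  it); amplitudes are small relative to level, and the phase (4.5 weeks,
  peak in late winter) makes the sinusoid integrate to approximately zero
  over the forecast window so the calibration of the totals is not
  distorted by the seasonal term.
* **Patient profiles**: independent draws per covariate from the published
  per-centre margins (sex, age band, ethnicity, smoking), baseline VA from
  a truncated normal (MEH 55.9 ± 16.3, UHB 51.7 ± 20.0, truncated to
  $[0, 95]$) rounded to integer letters, and index weeks uniform over the
  sampling window. Covariates are independent by design — the sources give
  only margins — so any real age–acuity correlation is *not* emulated.
* **Sham cohort**: 238 participants with baseline VA 53.61 ± 14.06;
  each gets an individual slope drawn from
  $\mathcal N(\mu_\Delta/12,\ \sigma_\Delta/12)$ letters/month with
  $\mu_\Delta = -9.3$ (the published matched-cohort 12-month decline,
  52.9 → 43.6) and $\sigma_\Delta = 12$, visit noise sd 2.5 letters,
  visits at months 0, 3, 6, 12, all values clamped to $[0, 100]$ and the
  month-0 visit equal to baseline by construction.

Passing tests on these generators therefore demonstrate that the
*machinery* is correct — decomposition and smoothing recover known
closed forms, matching equals an exhaustive oracle, the regression models
recover generating coefficients, and the end-to-end pipeline recovers the
generator's mean decline within ±1.5 letters over 20 seeded runs at
n = 300. They do not demonstrate calibration against real EHR data, which
exhibit correlated covariates, non-sinusoidal seasonality, holiday
effects and measurement artefacts that the emulator deliberately omits.

# Numerical conventions and degenerate inputs

* Rounding: half-up everywhere a value is reported (letters, percentages
  to one decimal).
* Sample (n−1) SD; a single observation reports sd 0.
* Zero counts, empty pools, series shorter than two seasonal cycles,
  missing month-0 visits, partners with only a baseline visit, singular
  or separated designs: all raise immediate, named errors rather than
  propagating NAs.
* Seeds: every stochastic stage takes an explicit seed;
  `run_pipeline()` derives per-stage seeds deterministically from one
  top-level seed (`stage_seed()`), so stages are independently
  reproducible and a fixed seed fixes every stage output byte-for-byte.
* Matching determinism: best-first admission with lexicographic
  tie-breaks; a zero calliper admits only exact logit ties.

# Problem sizes used in the shipped runs

The packaged tests and drivers run at the study's own scale: 115-week
series per centre, historical cohorts of 1 929 and 267 profiles, a
238-participant sham arm, and forecast cohorts of a few hundred. The
end-to-end recovery check uses 20 seeded runs at n = 300, and the matching
oracle 200 random instances of up to 12 subjects per side — sizes at
which the exhaustive oracle is exact and fast.

# Known limitations

* The untreated trajectories come from a two-decade-old trial population
  with strict inclusion criteria; real-world untreated decline (with
  comorbid cataract, diabetic retinopathy, etc.) is plausibly worse, so
  projections are, if anything, conservative.
* Band-midpoint age is a coarse surrogate inside both the propensity and
  projection models.
* The eligibility window $[25, 70]$ is an inference, not a published
  bound, and materially drives the matched/unmatched split.
* Holt–Winters totals at very low weekly counts (the smaller centre) have
  wide sampling variability; totals there should be read with their
  intervals, not as point values.
* No attempt is made to model pandemic-era presentation behaviour: the
  counterfactual is strictly "the historical patient flow, untreated".
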