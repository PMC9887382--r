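# amdforecast

Neovascular age-related macular degeneration (nAMD) causes rapid,
irreversible central-vision loss unless anti-VEGF injections are started
promptly. When ophthalmic services shut down — as during the first UK
COVID-19 lockdown (16 March – 31 July 2020) — newly presenting patients go
untreated, and the clinical question is how much vision that bolus of
patients stands to lose. `amdforecast` implements that analysis as a
reusable pipeline for service planners and clinical researchers:

1. **Forecast demand.** Weekly counts of treatment-naïve nAMD patients
   initiating anti-VEGF per centre are modelled with an additive
   decomposition (trend + seasonal + random) and additive Holt–Winters
   exponential smoothing
   (ℓ_t = α(y_t − s_{t−m}) + (1−α)(ℓ_{t−1} + b_{t−1}), etc., period
   m = 52 weeks). The h-step forecast ℓ + h·b + s, truncated at zero, is
   summed over the 20-week interruption window (ISO weeks 12–31 of 2020)
   to give the number of patients whose treatment start is missed.
2. **Sample a hypothetical cohort.** That many patient profiles are drawn
   uniformly from the historical pool who presented in the same calendar
   window of the two preceding years.
3. **Match to an untreated control arm.** Profiles within the trial
   eligibility window (baseline VA 25–70 ETDRS letters) enter a logistic
   propensity model e(x) on age, sex and baseline visual acuity, and are
   matched 1:1, best-first, to sham-control trial participants within a
   calliper of 0.1 × SD(logit e).
4. **Project untreated trajectories.** Matched patients inherit their
   partner's change-from-baseline at months 3, 6 and 12; unmatched and
   ineligible patients are projected with per-month OLS models of VA on
   age, sex and baseline VA trained on the sham arm.
5. **Summarise outcomes.** With last observation carried forward for
   constant denominators: mean ± SD VA per month and the proportions of
   eyes with VA ≥ 70 letters (good vision, UK driving standard), < 25
   (below the anti-VEGF treatment floor) and ≤ 20 (severe sight
   impairment registration threshold).

The hospital EHR data and the trial sham arm behind the original analysis
are not publicly available, so the package ships a synthetic-data module
(`gen_weekly_counts()`, `gen_patient_profiles()`, `gen_sham_cohort()`)
whose defaults are calibrated to the published baseline tables; every
stage runs end to end on those synthetic stand-ins.

## Worked example

A single-centre run on synthetic data:

```r
library(amdforecast)
sc <- default_scenario()

weekly <- gen_weekly_counts(sc, "MEH", seed = 100)
fit <- fit_holt_winters(weekly, m = 52)
fc <- forecast_weeks(fit, iso_week_seq(c(2020L, 12L), c(2020L, 31L)))
print(fit); print(fc)
#> Additive Holt-Winters state (m = 52, n = 115)
#>   alpha 0.000  beta 0.000  gamma 0.239
#>   level 16.387  trend 0.0123  one-step sd 4.084
#> Holt-Winters forecast: 20 weeks, total 324 patients

pool <- build_pool(gen_patient_profiles(sc, "MEH", seed = 102), "MEH")
cohort <- sample_profiles(pool, fc$total, seed = 103)
sham <- gen_sham_cohort(sc, seed = 104)
scr <- screen_eligibility(cohort, 25, 70)
ms <- match_within_calliper(fit_propensity(scr$eligible, sham$cohort))
print(ms)
#> Calliper match set: 193 pairs, 54 unmatched (calliper 0.0362 = 0.10 x sd(logit) 0.3623)

vm <- fit_va_model(sham$cohort, sham$visits)
traj <- apply_locf(project_cohort(cohort, ms, sham$visits, vm))
summarize_outcomes(traj, "MEH")
#>  centre month   n mean_va sd_va n_ge70 pct_ge70 n_lt25 pct_lt25 n_le20 pct_le20
#>     MEH     0 324   55.04 16.91     69     21.3     14      4.3      8      2.5
#>     MEH     3 324   53.19 16.88     57     17.6     19      5.9     12      3.7
#>     MEH     6 324   50.89 17.40     43     13.3     23      7.1     16      4.9
#>     MEH    12 324   46.84 18.46     30      9.3     43     13.3     30      9.3
```

Reading the table: 324 patients are forecast to miss treatment initiation
at this centre over the 20-week window; left untreated, their mean acuity
is projected to fall from 55.0 to 46.8 letters by month 12, the share
keeping good vision (≥ 70 letters) drops from 21.3% to 9.3%, and the share
falling below the 25-letter treatment-eligibility floor rises from 4.3% to
13.3%.

`run_pipeline(out_dir, seed)` runs both centres end to end and writes
every stage output plus a JSON manifest. The same stages are available as
narrative drivers under `analysis/` (`01_simulate.R` … `06_outcomes.R`),
each writing its tables under `results/`.

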