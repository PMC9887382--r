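#!/usr/bin/env Rscript
# Stage 3 — build the hypothetical interruption cohort.
#
# For each centre, the forecasted number of patient profiles is drawn
# uniformly at random from the historical pool of patients who initiated
# treatment in the same calendar window (ISO weeks 12-31) of 2018/2019.

library(amdforecast)

seed <- 17
profiles <- read_stage_csv("results/data/profiles.csv", "profiles")
totals <- utils::read.csv("results/forecast_totals.csv")
sc <- default_scenario()

cohort <- do.call(rbind, lapply(totals$centre, function(cc) {
  pool <- build_pool(profiles, cc, weeks = sc$window$weeks,
                     years = sc$window$years)
  sample_profiles(pool, totals$total[totals$centre == cc],
                  seed = stage_seed(seed, paste0("sample:", cc)))
}))
write_stage_csv(cohort, "results/hypothetical_cohort.csv",
                "hypothetical_cohort")
cat(sprintf("hypothetical cohort: %d profiles\n", nrow(cohort)))
print(summarize_baseline(cohort))
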