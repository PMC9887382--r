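#!/usr/bin/env Rscript
# Stage 6 — cohort outcome tables.
#
# Matched and modelled trajectories are summarised separately and pooled
# per centre: mean (sd) VA per month and the proportions of eyes with
# VA >= 70 letters (good vision), < 25 (below the treatment floor) and
# <= 20 (severe sight impairment threshold).

library(amdforecast)

traj <- read_stage_csv("results/trajectories.csv", "trajectories")
centre_of <- function(ids) substr(ids, 1, 3)

pooled <- list(); matched_only <- list()
for (cc in unique(centre_of(traj$profile_id))) {
  sub <- traj[centre_of(traj$profile_id) == cc, ]
  m <- summarize_outcomes(sub[sub$source == "matched", ], cc)
  u <- if (any(sub$source == "modelled")) {
    summarize_outcomes(sub[sub$source == "modelled", ], cc)
  } else NULL
  matched_only[[cc]] <- m
  pooled[[cc]] <- pool_cohorts(m, u, centre = cc)
}

outcomes <- do.call(rbind, pooled)
write_stage_csv(outcomes, "results/outcomes.csv", "outcomes")
write_stage_csv(do.call(rbind, matched_only), "results/outcomes_matched.csv",
                "outcomes")

for (cc in names(pooled)) {
  oc <- pooled[[cc]]
  cat(sprintf("[%s] n = %d; mean VA %.1f -> %.1f letters by month 12\n",
              cc, oc$n[1], oc$mean_va[oc$month == 0],
              oc$mean_va[oc$month == 12]))
  cat(sprintf("[%s] VA >= 70: %.1f%% -> %.1f%%; VA < 25: %.1f%% -> %.1f%%; VA <= 20: %.1f%% -> %.1f%%\n",
              cc, oc$pct_ge70[oc$month == 0], oc$pct_ge70[oc$month == 12],
              oc$pct_lt25[oc$month == 0], oc$pct_lt25[oc$month == 12],
              oc$pct_le20[oc$month == 0], oc$pct_le20[oc$month == 12]))
}
print(outcomes)
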