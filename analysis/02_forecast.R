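#!/usr/bin/env Rscript
# Stage 2 — forecast weekly anti-VEGF initiations over the interruption
# window (ISO weeks 12-31 of 2020) for each centre independently.
#
# The pre-interruption series (2018-W01 .. 2020-W11) is fitted with
# additive Holt-Winters smoothing (annual period m = 52); the 20-week
# horizon gets point forecasts with Gaussian 95% intervals, and the
# centre total is the rounded sum of the unrounded weekly points.

library(amdforecast)

weekly <- read_stage_csv("results/data/weekly_counts.csv", "weekly_counts")
sc <- default_scenario()
horizon <- iso_week_seq(sc$horizon$start, sc$horizon$end)

fc_all <- list(); totals <- list()
for (cc in unique(weekly$centre)) {
  ser <- weekly[weekly$centre == cc, ]
  fit <- fit_holt_winters(ser, m = 52)
  print(fit)
  fc <- forecast_weeks(fit, horizon)
  cat(sprintf("[%s] forecast total over %d weeks: %d patients\n",
              cc, nrow(horizon), fc$total))
  fc_all[[cc]] <- cbind(centre = cc, fc$weeks)
  totals[[cc]] <- data.frame(centre = cc, total = fc$total)
}

write_stage_csv(do.call(rbind, fc_all), "results/forecast.csv", "forecast")
utils::write.csv(do.call(rbind, totals), "results/forecast_totals.csv",
                 row.names = FALSE)
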