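Package: amdforecast
Title: Forecasting Anti-VEGF Demand and Untreated Visual-Acuity Outcomes in
    Neovascular AMD During Service Interruption
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: An analysis pipeline estimating the immediate impact of an
    interruption to neovascular age-related macular degeneration (nAMD)
    services on treatment-naive patients. Weekly counts of anti-VEGF
    treatment initiations are decomposed into trend, seasonal and random
    components and forecast over the interruption window with additive
    Holt-Winters exponential smoothing; a hypothetical patient cohort is
    sampled from the same calendar window of preceding years; patients are
    matched to an untreated trial sham-control arm by propensity-score
    calliper matching on age, sex and visual acuity; and 12-month untreated
    visual-acuity trajectories are projected for matched (change-score
    carry-over) and unmatched (per-month linear model) patients, summarised
    as mean acuity and 70/25/20-letter threshold proportions under
    last-observation-carried-forward. A synthetic-data module generates
    weekly series, patient profiles and a longitudinal sham cohort with the
    statistical structure the analysis assumes, so the full pipeline runs
    without access to the original hospital or trial records.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
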