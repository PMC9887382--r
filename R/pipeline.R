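# End-to-end pipeline: simulate (or ingest) -> forecast -> sample ->
# screen/match -> project -> summarise, with one top-level seed deriving a
# deterministic per-stage seed so every stage is independently reproducible.

#' Derive a per-stage seed from the top-level seed
#'
#' Deterministic and stable across runs: a small hash of the stage name
#' mixed with the top-level seed, kept below 2^31.
#'
#' @param seed top-level integer seed.
#' @param stage stage name, e.g. `"simulate:MEH"`.
#' @return integer seed.
#' @export
stage_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 7919 + h) %% 2147483647)
}

#' Run the full lockdown-impact pipeline on synthetic inputs
#'
#' Executes, per centre: synthetic-data generation, Holt-Winters fit on the
#' pre-interruption weekly series and forecast over the interruption window,
#' sampling of the forecasted number of hypothetical profiles from the
#' same-calendar-window historical pool, eligibility screening and
#' propensity calliper matching against the sham cohort, trajectory
#' projection, and outcome summaries (matched, modelled and pooled).
#' All stage outputs are written to `out_dir` as CSV; a JSON manifest
#' records the seed, configuration and per-file row counts.
#'
#' @param out_dir output directory (created if needed).
#' @param seed top-level integer seed.
#' @param scenario scenario list (default [default_scenario()]).
#' @return the manifest, invisibly (also written as `manifest.json`).
#' @export
run_pipeline <- function(out_dir, seed = 17, scenario = default_scenario()) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  centres <- names(scenario$centres)
  files <- list()
  put <- function(df, name, schema) {
    path <- file.path(out_dir, name)
    write_stage_csv(df, path, schema)
    files[[name]] <<- list(path = name, rows = nrow(df))
    df
  }

  # --- simulate -------------------------------------------------------
  weekly <- do.call(rbind, lapply(centres, function(cc) {
    gen_weekly_counts(scenario, cc, seed = stage_seed(seed, paste0("weekly:", cc)))
  }))
  put(weekly, "weekly_counts.csv", "weekly_counts")
  profiles <- do.call(rbind, lapply(centres, function(cc) {
    gen_patient_profiles(scenario, cc,
                         seed = stage_seed(seed, paste0("profiles:", cc)))
  }))
  put(profiles, "profiles.csv", "profiles")
  sham <- gen_sham_cohort(scenario, seed = stage_seed(seed, "sham"))
  put(sham$cohort, "sham_cohort.csv", "sham_cohort")
  put(sham$visits, "sham_visits.csv", "sham_visits")

  # baseline summary of the historical cohort
  write_baseline_summary(summarize_baseline(profiles),
                         file.path(out_dir, "baseline_summary.csv"))
  files[["baseline_summary.csv"]] <- list(path = "baseline_summary.csv",
                                          rows = NA)

  # shared sham-trained projection model
  va_model <- fit_va_model(sham$cohort, sham$visits)
  horizon <- iso_week_seq(scenario$horizon$start, scenario$horizon$end)

  fc_rows <- list(); totals <- list(); match_rows <- list()
  unmatched_rows <- list(); traj_rows <- list(); outcome_rows <- list()
  matched_outcome_rows <- list()

  for (cc in centres) {
    # --- forecast -----------------------------------------------------
    ser <- weekly[weekly$centre == cc, , drop = FALSE]
    hw <- fit_holt_winters(ser, m = 52)
    fc <- forecast_weeks(hw, horizon)
    fc_rows[[cc]] <- cbind(centre = cc, fc$weeks)
    totals[[cc]] <- data.frame(centre = cc, total = fc$total)
    message(sprintf("[%s] forecast total over %d weeks: %d",
                    cc, nrow(horizon), fc$total))

    # --- sample -------------------------------------------------------
    pool <- build_pool(profiles, cc, weeks = scenario$window$weeks,
                       years = scenario$window$years)
    cohort <- sample_profiles(pool, fc$total,
                              seed = stage_seed(seed, paste0("sample:", cc)))

    # --- screen + match ----------------------------------------------
    scr <- screen_eligibility(cohort, scenario$eligibility[1],
                              scenario$eligibility[2])
    prop <- fit_propensity(scr$eligible, sham$cohort)
    ms <- match_within_calliper(prop, scenario$calliper_mult)
    message(sprintf(
      "[%s] eligibility window [%g, %g]: %d eligible, %d ineligible; calliper %.4f; %d matched",
      cc, scenario$eligibility[1], scenario$eligibility[2],
      nrow(scr$eligible), nrow(scr$ineligible), ms$calliper, nrow(ms$pairs)))
    match_rows[[cc]] <- ms$pairs
    unmatched_rows[[cc]] <- rbind(
      ms$unmatched,
      data.frame(profile_id = as.character(scr$ineligible$patient_id),
                 reason = scr$ineligible$reason,
                 stringsAsFactors = FALSE))

    # --- project ------------------------------------------------------
    traj <- project_cohort(cohort, ms, sham$visits, va_model)
    traj <- apply_locf(traj)
    traj_rows[[cc]] <- traj

    # --- summarise ----------------------------------------------------
    matched_sum <- summarize_outcomes(
      traj[traj$source == "matched", , drop = FALSE], cc)
    modelled <- traj[traj$source == "modelled", , drop = FALSE]
    modelled_sum <- if (nrow(modelled) > 0) {
      summarize_outcomes(modelled, cc)
    } else NULL
    matched_outcome_rows[[cc]] <- matched_sum
    outcome_rows[[cc]] <- pool_cohorts(matched_sum, modelled_sum, centre = cc)
  }

  put(do.call(rbind, fc_rows), "forecast.csv", "forecast")
  ft <- do.call(rbind, totals)
  utils::write.csv(ft, file.path(out_dir, "forecast_totals.csv"),
                   row.names = FALSE)
  files[["forecast_totals.csv"]] <- list(path = "forecast_totals.csv",
                                         rows = nrow(ft))
  put(do.call(rbind, match_rows), "matches.csv", "matches")
  put(do.call(rbind, unmatched_rows), "unmatched.csv", "unmatched")
  put(do.call(rbind, traj_rows), "trajectories.csv", "trajectories")
  put(do.call(rbind, outcome_rows), "outcomes.csv", "outcomes")
  put(do.call(rbind, matched_outcome_rows), "outcomes_matched.csv", "outcomes")

  manifest <- list(
    pipeline_version = as.character(utils::packageVersion("amdforecast")),
    seed = seed,
    eligibility = scenario$eligibility,
    calliper_mult = scenario$calliper_mult,
    files = files,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}
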