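# Synthetic study inputs. The real analysis consumed hospital EHR data from
# two centres and an external trial sham arm, none of which are public.
# These generators emulate their statistical structure — a weekly count
# series with trend, annual seasonality and Poisson noise; patient profiles
# drawn from published baseline margins; and a longitudinal sham cohort with
# a mean 12-month decline — so the full pipeline runs and is testable
# without any download. All outputs are synthetic stand-ins, not data.

#' Default synthetic scenario
#'
#' Per-centre weekly-count parameters (counts/week), profile margins and
#' visual-acuity distributions, and sham-cohort parameters, calibrated to
#' the published baseline tables of the two-centre cohort and the trial
#' sham arm: centre MEH averages 16.25 initiations/week (325 over the
#' 20-week interruption window), UHB 2.55 (51 over the window); baseline VA
#' is 55.9 (16.3) letters at MEH, 51.7 (20.0) at UHB and 53.61 (14.06) in
#' the 238-participant sham arm, whose mean untreated 12-month change is
#' -9.3 letters (between-subject sd 12). The seasonal phase puts the annual
#' peak in late winter so the sinusoid integrates to roughly zero over the
#' interruption window.
#'
#' @return nested list understood by the `gen_*` generators and
#'   [run_pipeline()].
#' @export
default_scenario <- function() {
  list(
    centres = list(
      MEH = list(
        n_history = 1929,
        weekly = list(level = 16.25, trend = 0, amplitude = 2.5, phase = 4.5),
        profile = list(
          p_female = 0.605,
          age_probs = c(`<65` = 0.065, `65-69` = 0.072, `70-74` = 0.140,
                        `75-79` = 0.191, `80-84` = 0.232, `85+` = 0.300),
          eth_probs = c(white = 0.469, not_white = 0.490, not_reported = 0.041),
          p_smoker = 0.073,
          va_mean = 55.9, va_sd = 16.3, va_range = c(0, 95))
      ),
      UHB = list(
        n_history = 267,
        weekly = list(level = 2.55, trend = 0, amplitude = 0.6, phase = 4.5),
        profile = list(
          p_female = 0.685,
          age_probs = c(`<65` = 0.030, `65-69` = 0.056, `70-74` = 0.154,
                        `75-79` = 0.142, `80-84` = 0.255, `85+` = 0.363),
          eth_probs = c(white = 0.745, not_white = 0.052, not_reported = 0.203),
          p_smoker = 0.034,
          va_mean = 51.7, va_sd = 20.0, va_range = c(0, 95))
      )
    ),
    sham = list(
      n = 238,
      p_female = 0.668,
      age_probs = c(`<65` = 0.046, `65-69` = 0.071, `70-74` = 0.210,
                    `75-79` = 0.286, `80-84` = 0.269, `85+` = 0.118),
      eth_probs = c(white = 0.971, not_white = 0.029),
      p_smoker = 0.546,
      va_mean = 53.61, va_sd = 14.06, va_range = c(0, 95),
      mean_change_12m = -9.3, slope_sd_12m = 12,
      visit_months = c(0, 3, 6, 12), visit_noise_sd = 2.5
    ),
    window = list(weeks = 12:31, years = c(2018L, 2019L)),
    history = list(start = c(2018L, 1L), end = c(2020L, 11L)),
    horizon = list(start = c(2020L, 12L), end = c(2020L, 31L)),
    eligibility = c(25, 70),
    calliper_mult = 0.1
  )
}

.check_margin <- function(p, what) {
  if (any(p < 0) || any(p > 1) || abs(sum(p) - 1) > 1e-6) {
    stop(sprintf("%s probabilities must lie in [0,1] and sum to 1", what),
         call. = FALSE)
  }
  p
}

#' Generate a synthetic weekly initiation series for one centre
#'
#' Weekly counts are Poisson with mean
#' `max(0, level + trend * t + amplitude * sin(2*pi*(week + phase)/52))`,
#' where `week` is the ISO week-of-year (so the seasonal cycle stays
#' aligned across years) and `t` indexes weeks from the series start.
#'
#' @param scenario a scenario list (see [default_scenario()]).
#' @param centre centre name (a key of `scenario$centres`).
#' @param seed optional integer seed.
#' @param deterministic if `TRUE`, return the rounded Poisson means
#'   instead of draws (noise off).
#' @return weekly series data.frame (`centre`, `iso_year`, `iso_week`,
#'   `count`) spanning the scenario history.
#' @export
gen_weekly_counts <- function(scenario, centre, seed = NULL,
                              deterministic = FALSE) {
  par <- scenario$centres[[centre]]$weekly
  stopifnot(!is.null(par))
  wk <- iso_week_seq(scenario$history$start, scenario$history$end)
  t <- seq_len(nrow(wk))
  mu <- pmax(0, par$level + par$trend * t +
               par$amplitude * sin(2 * pi * (wk$iso_week + par$phase) / 52))
  if (all(mu == 0)) {
    warning("weekly-count parameters imply an all-zero mean series")
  }
  if (deterministic) {
    count <- as.integer(round_half_up(mu))
  } else {
    if (!is.null(seed)) set.seed(seed)
    count <- stats::rpois(length(mu), mu)
  }
  data.frame(centre = centre, iso_year = wk$iso_year,
             iso_week = wk$iso_week, count = count,
             stringsAsFactors = FALSE)
}

# truncated-normal integer VA draws by rejection
.rva <- function(n, mean, sd, range) {
  out <- numeric(0)
  while (length(out) < n) {
    x <- stats::rnorm(2 * (n - length(out)) + 10, mean, sd)
    out <- c(out, x[x >= range[1] & x <= range[2]])
  }
  as.integer(round_half_up(out[seq_len(n)]))
}

#' Generate synthetic patient profiles for one centre
#'
#' Covariates are independent draws from the configured margins; baseline
#' VA is a truncated normal rounded to integer letters; index weeks are
#' uniform over the configured sampling window (weeks x years).
#'
#' @param scenario scenario list.
#' @param centre centre name.
#' @param n number of profiles (default the centre's `n_history`).
#' @param seed optional integer seed.
#' @return profiles data.frame with the standard columns.
#' @export
gen_patient_profiles <- function(scenario, centre,
                                 n = scenario$centres[[centre]]$n_history,
                                 seed = NULL) {
  stopifnot(n >= 1)
  par <- scenario$centres[[centre]]$profile
  stopifnot(!is.null(par))
  .check_margin(par$age_probs, "age-band")
  .check_margin(par$eth_probs, "ethnicity")
  .check_margin(c(par$p_female, 1 - par$p_female), "sex")
  if (!is.null(seed)) set.seed(seed)
  weeks <- scenario$window$weeks
  years <- scenario$window$years
  data.frame(
    patient_id = sprintf("%s-%05d", centre, seq_len(n)),
    centre = centre,
    sex = sample(c("female", "male"), n, replace = TRUE,
                 prob = c(par$p_female, 1 - par$p_female)),
    age_band = sample(names(par$age_probs), n, replace = TRUE,
                      prob = par$age_probs),
    ethnicity = sample(names(par$eth_probs), n, replace = TRUE,
                       prob = par$eth_probs),
    smoker = sample(c("yes", "no_or_unknown"), n, replace = TRUE,
                    prob = c(par$p_smoker, 1 - par$p_smoker)),
    index_year = sample(years, n, replace = TRUE),
    index_week = sample(weeks, n, replace = TRUE),
    study_eye = sample(c("right", "left"), n, replace = TRUE),
    baseline_va = .rva(n, par$va_mean, par$va_sd, par$va_range),
    stringsAsFactors = FALSE)
}

#' Generate a synthetic sham-control cohort with longitudinal VA
#'
#' Each participant gets a baseline VA from a truncated normal and an
#' individual monthly slope `~ Normal(mean_change_12m/12, slope_sd_12m/12)`
#' letters/month. Visit VA at month m is
#' `clamp(round(baseline + slope * m + noise), 0, 100)`; the month-0 visit
#' equals the baseline exactly.
#'
#' @param scenario scenario list.
#' @param seed optional integer seed.
#' @return list with `cohort` (participant covariates) and `visits`
#'   (`participant_id`, `month`, `va`) data.frames.
#' @export
gen_sham_cohort <- function(scenario, seed = NULL) {
  par <- scenario$sham
  .check_margin(par$age_probs, "age-band")
  .check_margin(par$eth_probs, "ethnicity")
  if (!0 %in% par$visit_months || !12 %in% par$visit_months) {
    stop("sham visit months must include 0 and 12", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  n <- par$n
  cohort <- data.frame(
    participant_id = sprintf("SHAM-%04d", seq_len(n)),
    sex = sample(c("female", "male"), n, replace = TRUE,
                 prob = c(par$p_female, 1 - par$p_female)),
    age_band = sample(names(par$age_probs), n, replace = TRUE,
                      prob = par$age_probs),
    ethnicity = sample(names(par$eth_probs), n, replace = TRUE,
                       prob = par$eth_probs),
    smoker = sample(c("yes", "no_or_unknown"), n, replace = TRUE,
                    prob = c(par$p_smoker, 1 - par$p_smoker)),
    baseline_va = .rva(n, par$va_mean, par$va_sd, par$va_range),
    stringsAsFactors = FALSE)
  slope <- stats::rnorm(n, par$mean_change_12m / 12, par$slope_sd_12m / 12)
  months <- sort(par$visit_months)
  visits <- do.call(rbind, lapply(seq_len(n), function(i) {
    va <- vapply(months, function(m) {
      if (m == 0) return(as.numeric(cohort$baseline_va[i]))
      raw <- cohort$baseline_va[i] + slope[i] * m +
        stats::rnorm(1, 0, par$visit_noise_sd)
      clamp(round_half_up(raw), 0, 100)
    }, numeric(1))
    data.frame(participant_id = cohort$participant_id[i],
               month = as.integer(months), va = as.integer(va),
               stringsAsFactors = FALSE)
  }))
  rownames(visits) <- NULL
  list(cohort = cohort, visits = visits)
}
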