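# Untreated visual-acuity projection over 12 months: matched patients
# inherit their sham partner's change-from-baseline profile; unmatched
# patients are projected with per-month linear models fitted on the sham
# cohort.

#' Months at which trajectories are evaluated
#' @export
TRAJECTORY_MONTHS <- c(0, 3, 6, 12)

# VA of one participant at an arbitrary month: exact visit value, linear
# interpolation between adjacent visits, last observation carried forward
# beyond the final visit
visit_va_at <- function(visits, month) {
  v <- visits[order(visits$month), , drop = FALSE]
  vapply(month, function(m) {
    if (m %in% v$month) return(v$va[match(m, v$month)])
    if (m > max(v$month)) return(v$va[nrow(v)])  # trailing gap: LOCF
    if (m < min(v$month)) {
      stop(sprintf("month %g precedes the first visit", m), call. = FALSE)
    }
    stats::approx(v$month, v$va, xout = m)$y
  }, numeric(1))
}

#' Project a matched patient by carrying the partner's VA change
#'
#' The patient's VA at month t is their own baseline plus the matched sham
#' partner's change from baseline at t, clamped to `[0, 100]`. Carrying the
#' change (not the partner's absolute VA) preserves the cohort's baseline
#' distribution. Missing partner months are linearly interpolated between
#' adjacent visits; trailing gaps carry the last observation forward.
#'
#' @param profile one-row data.frame with `patient_id` and `baseline_va`.
#' @param partner_visits data.frame of the partner's visits
#'   (`participant_id`, `month`, `va`), month 0 present.
#' @param months evaluation months (default `c(0, 3, 6, 12)`).
#' @return data.frame with columns `profile_id`, `source` (`"matched"`),
#'   `partner_id`, `month`, `va`.
#' @export
carry_matched_trajectory <- function(profile, partner_visits,
                                     months = TRAJECTORY_MONTHS) {
  stopifnot(nrow(profile) == 1)
  if (nrow(partner_visits) < 2) {
    stop(sprintf("partner %s has only a baseline visit: no trajectory information",
                 partner_visits$participant_id[1]), call. = FALSE)
  }
  if (!0 %in% partner_visits$month) {
    stop("partner visits must include month 0", call. = FALSE)
  }
  base_p <- partner_visits$va[partner_visits$month == 0]
  change <- visit_va_at(partner_visits, months) - base_p
  data.frame(profile_id = as.character(profile$patient_id),
             source = "matched",
             partner_id = as.character(partner_visits$participant_id[1]),
             month = months,
             va = clamp(profile$baseline_va + change, 0, 100),
             stringsAsFactors = FALSE)
}

#' Fit per-month linear VA models on the sham cohort
#'
#' For each horizon month an ordinary least-squares regression of observed
#' VA at that month on age (band midpoint), sex (female = 1) and baseline
#' VA, fitted on sham participants only. One model per month makes no
#' linearity-in-time assumption.
#'
#' @param sham_cohort data.frame of participants (`participant_id`, `sex`,
#'   `age_band`, `baseline_va`).
#' @param sham_visits data.frame of visits (`participant_id`, `month`, `va`).
#' @param months horizon months to model (default 3, 6, 12).
#' @param min_n minimum participants required per month (default 10).
#' @return object of class `va_model`: per-month coefficients, residual sd
#'   and the baseline-VA training range.
#' @export
fit_va_model <- function(sham_cohort, sham_visits,
                         months = c(3, 6, 12), min_n = 10) {
  by_id <- split(sham_visits, sham_visits$participant_id)
  usable <- names(by_id)[vapply(by_id, nrow, integer(1)) >= 2]
  coh <- sham_cohort[sham_cohort$participant_id %in% usable, , drop = FALSE]
  if (nrow(coh) < min_n) {
    stop(sprintf("need at least %d sham participants with follow-up visits, got %d",
                 min_n, nrow(coh)), call. = FALSE)
  }
  X <- .match_design(coh)
  fits <- lapply(months, function(m) {
    y <- vapply(as.character(coh$participant_id), function(id) {
      visit_va_at(by_id[[id]], m)
    }, numeric(1))
    d <- cbind(X, va = y)
    fit <- stats::lm(va ~ age_mid + sex_female + baseline_va, data = d)
    if (any(is.na(stats::coef(fit)))) {
      stop(sprintf("singular design in the month-%d VA model", m),
           call. = FALSE)
    }
    list(month = m, coefficients = stats::coef(fit),
         sigma = suppressWarnings(summary(fit)$sigma), fit = fit)
  })
  names(fits) <- paste0("month", months)
  structure(list(models = fits, months = months,
                 n = nrow(coh),
                 va_range = range(coh$baseline_va)),
            class = "va_model")
}

#' @export
print.va_model <- function(x, ...) {
  cat(sprintf("Per-month VA models (OLS on %d sham participants, baseline VA %g-%g)\n",
              x$n, x$va_range[1], x$va_range[2]))
  for (m in x$models) {
    cat(sprintf("  month %2d: ", m$month))
    print(round(m$coefficients, 3))
  }
  invisible(x)
}

#' Project an unmatched patient with the sham-trained linear models
#'
#' Month 0 is the patient's own baseline; each horizon month is the fitted
#' model's prediction from age, sex and baseline VA, clamped to `[0, 100]`.
#' Patients whose baseline VA lies outside the model's training range are
#' flagged as extrapolations via a message.
#'
#' @param profile one-row data.frame (`patient_id`, `sex`, `age_band`,
#'   `baseline_va`).
#' @param model a `va_model` from [fit_va_model()].
#' @param months evaluation months (default `c(0, 3, 6, 12)`); months other
#'   than 0 must have a fitted model.
#' @return data.frame with columns `profile_id`, `source` (`"modelled"`),
#'   `partner_id` (`NA`), `month`, `va`.
#' @export
predict_unmatched <- function(profile, model, months = TRAJECTORY_MONTHS) {
  stopifnot(inherits(model, "va_model"), nrow(profile) == 1)
  if (profile$baseline_va < model$va_range[1] ||
      profile$baseline_va > model$va_range[2]) {
    message(sprintf(
      "extrapolation: %s baseline VA %g outside model training range [%g, %g]",
      profile$patient_id, profile$baseline_va,
      model$va_range[1], model$va_range[2]))
  }
  x <- .match_design(profile)
  va <- vapply(months, function(m) {
    if (m == 0) return(as.numeric(profile$baseline_va))
    key <- paste0("month", m)
    if (!key %in% names(model$models)) {
      stop(sprintf("no fitted model for month %d", m), call. = FALSE)
    }
    cf <- model$models[[key]]$coefficients
    unname(cf[1] + cf["age_mid"] * x$age_mid +
             cf["sex_female"] * x$sex_female +
             cf["baseline_va"] * x$baseline_va)
  }, numeric(1))
  data.frame(profile_id = as.character(profile$patient_id),
             source = "modelled", partner_id = NA_character_,
             month = months, va = clamp(va, 0, 100),
             stringsAsFactors = FALSE)
}

#' Project a full cohort given a match set
#'
#' Matched profiles are carried over their partner's change profile;
#' unmatched and ineligible profiles are projected with the sham-trained
#' linear models.
#'
#' @param cohort data.frame of all hypothetical profiles.
#' @param match_set a `match_set` from [match_within_calliper()].
#' @param sham_visits sham visit table (for the matched partners).
#' @param model a `va_model` (for the unmatched).
#' @param months evaluation months.
#' @return data.frame of trajectories (one row per profile per month).
#' @export
project_cohort <- function(cohort, match_set, sham_visits, model,
                           months = TRAJECTORY_MONTHS) {
  visits_by_id <- split(sham_visits, sham_visits$participant_id)
  rows <- lapply(seq_len(nrow(cohort)), function(i) {
    prof <- cohort[i, , drop = FALSE]
    j <- match(as.character(prof$patient_id), match_set$pairs$profile_id)
    if (!is.na(j)) {
      partner <- match_set$pairs$participant_id[j]
      carry_matched_trajectory(prof, visits_by_id[[partner]], months)
    } else {
      suppressMessages(predict_unmatched(prof, model, months))
    }
  })
  do.call(rbind, rows)
}
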