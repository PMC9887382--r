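# Trial-eligibility screening, propensity scoring and calliper matching of
# the hypothetical cohort to sham-control trial participants.

#' Screen profiles against the trial visual-acuity eligibility window
#'
#' Profiles with baseline VA inside `[va_min, va_max]` (inclusive) are
#' eligible; the rest are flagged with the violated bound. The default
#' window of 25-70 letters combines the treatment floor (below 25 letters
#' an eye is not treated) with the good-vision ceiling (above 70 letters,
#' Snellen 6/12).
#'
#' @param profiles data.frame with `patient_id` and `baseline_va`.
#' @param va_min,va_max eligibility bounds in ETDRS letters, `va_min < va_max`.
#' @return list with data.frames `eligible` and `ineligible`; the latter
#'   has a `reason` column naming the violated bound.
#' @export
screen_eligibility <- function(profiles, va_min = 25, va_max = 70) {
  stopifnot(va_min < va_max)
  low <- profiles$baseline_va < va_min
  high <- profiles$baseline_va > va_max
  inel <- profiles[low | high, , drop = FALSE]
  if (nrow(inel) > 0) {
    inel$reason <- ifelse(inel$baseline_va < va_min,
                          sprintf("baseline_va<%g", va_min),
                          sprintf("baseline_va>%g", va_max))
  } else {
    inel$reason <- character(0)
  }
  list(eligible = profiles[!(low | high), , drop = FALSE],
       ineligible = inel)
}

# shared design matrix: age-band midpoint (years), female indicator,
# baseline VA (letters)
.match_design <- function(df) {
  data.frame(age_mid = age_band_midpoint(df$age_band),
             sex_female = as.numeric(df$sex == "female"),
             baseline_va = as.numeric(df$baseline_va))
}

#' Fit the propensity model for cohort-vs-sham membership
#'
#' Maximum-likelihood logistic regression of group membership (hypothetical
#' cohort = 1, sham participant = 0) on age (band midpoint, years), sex
#' (female = 1) and baseline VA (letters). Returns per-subject propensity
#' scores on both the probability and the logit (linear-predictor) scale.
#'
#' @param cohort data.frame of hypothetical profiles (`patient_id`, `sex`,
#'   `age_band`, `baseline_va`).
#' @param sham data.frame of sham participants (`participant_id`, `sex`,
#'   `age_band`, `baseline_va`).
#' @return object of class `propensity_model`: list with `coefficients`,
#'   `scores` (id, group, propensity, logit) and the underlying `glm` fit.
#' @export
fit_propensity <- function(cohort, sham) {
  if (nrow(cohort) == 0 || nrow(sham) == 0) {
    stop("both the cohort and the sham group must be non-empty", call. = FALSE)
  }
  X <- rbind(.match_design(cohort), .match_design(sham))
  if (any(!stats::complete.cases(X))) {
    stop("matching covariates contain missing values", call. = FALSE)
  }
  X$group <- rep(c(1, 0), c(nrow(cohort), nrow(sham)))
  fit <- stats::glm(group ~ age_mid + sex_female + baseline_va,
                    data = X, family = stats::binomial())
  if (any(is.na(stats::coef(fit)))) {
    stop("singular design in the propensity model", call. = FALSE)
  }
  eta <- as.numeric(stats::predict(fit, type = "link"))
  p <- stats::plogis(eta)
  if (any(p < 1e-10 | p > 1 - 1e-10)) {
    stop(paste("(quasi-)perfect separation in the propensity model;",
               "review covariate overlap before matching"), call. = FALSE)
  }
  structure(list(
    coefficients = stats::coef(fit),
    scores = data.frame(
      id = c(as.character(cohort$patient_id),
             as.character(sham$participant_id)),
      group = X$group, propensity = p, logit = eta,
      stringsAsFactors = FALSE),
    fit = fit
  ), class = "propensity_model")
}

#' @export
print.propensity_model <- function(x, ...) {
  cat("Propensity model (logistic: cohort = 1, sham = 0)\n")
  print(round(x$coefficients, 4))
  cat(sprintf("subjects: %d cohort, %d sham; sd(logit) = %.4f\n",
              sum(x$scores$group == 1), sum(x$scores$group == 0),
              stats::sd(x$scores$logit)))
  invisible(x)
}

#' Greedy 1:1 calliper matching on the logit propensity score
#'
#' Pairs each hypothetical profile with at most one sham participant, both
#' used at most once, admitting pairs best-first (ascending absolute logit
#' difference) among all cross-group pairs within the calliper. The
#' calliper is `calliper_mult` times the SD of the logit propensity over
#' all fitted subjects (default multiplier 0.1). Ties are broken by
#' (profile id, participant id) lexicographic order, making the result
#' deterministic and independent of input ordering.
#'
#' @param model a `propensity_model` from [fit_propensity()].
#' @param calliper_mult calliper width as a multiple of sd(logit).
#' @return object of class `match_set`: list with `calliper`, `sd_logit`,
#'   `pairs` (profile_id, participant_id, delta_logit) and `unmatched`
#'   (profile_id, reason).
#' @export
match_within_calliper <- function(model, calliper_mult = 0.1) {
  stopifnot(inherits(model, "propensity_model"), calliper_mult >= 0)
  sc <- model$scores
  coh <- sc[sc$group == 1, ]
  shm <- sc[sc$group == 0, ]
  sd_logit <- stats::sd(sc$logit)
  calliper <- calliper_mult * sd_logit

  delta <- abs(outer(coh$logit, shm$logit, `-`))
  adm <- which(delta <= calliper, arr.ind = TRUE)
  pairs <- data.frame(profile_id = coh$id[adm[, 1]],
                      participant_id = shm$id[adm[, 2]],
                      delta_logit = delta[adm],
                      stringsAsFactors = FALSE)
  pairs <- pairs[order(pairs$delta_logit, pairs$profile_id,
                       pairs$participant_id), , drop = FALSE]

  used_p <- character(0); used_s <- character(0)
  keep <- logical(nrow(pairs))
  for (i in seq_len(nrow(pairs))) {
    if (!(pairs$profile_id[i] %in% used_p) &&
        !(pairs$participant_id[i] %in% used_s)) {
      keep[i] <- TRUE
      used_p <- c(used_p, pairs$profile_id[i])
      used_s <- c(used_s, pairs$participant_id[i])
    }
  }
  matched <- pairs[keep, , drop = FALSE]
  rownames(matched) <- NULL
  un <- setdiff(coh$id, matched$profile_id)
  if (nrow(matched) == 0) {
    message("no pairs within the calliper; all profiles unmatched")
  }
  structure(list(
    calliper = calliper, sd_logit = sd_logit,
    calliper_mult = calliper_mult,
    pairs = matched,
    unmatched = data.frame(profile_id = un,
                           reason = rep("no_neighbour_in_calliper",
                                        length(un)),
                           stringsAsFactors = FALSE)
  ), class = "match_set")
}

#' @export
print.match_set <- function(x, ...) {
  cat(sprintf(
    "Calliper match set: %d pairs, %d unmatched (calliper %.4f = %.2f x sd(logit) %.4f)\n",
    nrow(x$pairs), nrow(x$unmatched), x$calliper, x$calliper_mult,
    x$sd_logit))
  invisible(x)
}

#' Standardised mean difference of a covariate between two groups
#'
#' `(mean1 - mean2) / sqrt((var1 + var2) / 2)`; the usual balance
#' diagnostic before and after matching.
#'
#' @param x1,x2 numeric covariate values in each group.
#' @return the standardised mean difference (signed).
#' @export
standardized_mean_diff <- function(x1, x2) {
  s <- sqrt((stats::var(x1) + stats::var(x2)) / 2)
  if (s == 0) return(0)
  (mean(x1) - mean(x2)) / s
}
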