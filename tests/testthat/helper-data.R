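# Builders and independent oracles shared across the suite.

# quick profile builder with sensible defaults
make_profiles <- function(n, centre = "MEH", va = 55, sex = "female",
                          age_band = "75-79", ethnicity = "white",
                          smoker = "no_or_unknown", index_year = 2018L,
                          index_week = 15L, id_prefix = "P") {
  data.frame(
    patient_id = sprintf("%s%04d", id_prefix, seq_len(n)),
    centre = rep_len(centre, n),
    sex = rep_len(sex, n),
    age_band = rep_len(age_band, n),
    ethnicity = rep_len(ethnicity, n),
    smoker = rep_len(smoker, n),
    index_year = rep_len(index_year, n),
    index_week = rep_len(index_week, n),
    study_eye = rep_len("right", n),
    baseline_va = rep_len(va, n),
    stringsAsFactors = FALSE)
}

# noiseless additive level/trend/seasonal series: the closed form the
# Holt-Winters fit must reproduce
gen_hw_series <- function(l0, b0, s, n) {
  m <- length(s)
  t <- seq_len(n)
  l0 + b0 * t + s[((t - 1) %% m) + 1]
}

# exhaustive best-first 1:1 matching oracle: enumerate every admissible
# cross pair, sort by (delta, profile id, participant id), admit greedily.
# Written independently of match_within_calliper (plain loops, no outer()).
oracle_match <- function(profile_ids, profile_logit,
                         participant_ids, participant_logit, calliper) {
  cand <- list()
  k <- 0
  for (i in seq_along(profile_ids)) {
    for (j in seq_along(participant_ids)) {
      d <- abs(profile_logit[i] - participant_logit[j])
      if (d <= calliper) {
        k <- k + 1
        cand[[k]] <- data.frame(profile_id = profile_ids[i],
                                participant_id = participant_ids[j],
                                delta_logit = d,
                                stringsAsFactors = FALSE)
      }
    }
  }
  if (k == 0) {
    return(data.frame(profile_id = character(0),
                      participant_id = character(0),
                      delta_logit = numeric(0)))
  }
  cand <- do.call(rbind, cand)
  cand <- cand[order(cand$delta_logit, cand$profile_id,
                     cand$participant_id), ]
  taken_p <- character(0); taken_s <- character(0)
  out <- list(); k <- 0
  for (i in seq_len(nrow(cand))) {
    if (!(cand$profile_id[i] %in% taken_p) &&
        !(cand$participant_id[i] %in% taken_s)) {
      k <- k + 1
      out[[k]] <- cand[i, ]
      taken_p <- c(taken_p, cand$profile_id[i])
      taken_s <- c(taken_s, cand$participant_id[i])
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# sham cohort + visits with a known per-month linear data-generating
# process va(t) = b0 + b_age * age + b_sex * female + b_va * baseline + noise
make_linear_sham <- function(n, months = c(3, 6, 12),
                             beta = c(intercept = -2.4, age = 0,
                                      sex = 0, va = 1),
                             slope_per_month = TRUE, noise_sd = 0) {
  cohort <- data.frame(
    participant_id = sprintf("S%04d", seq_len(n)),
    sex = rep(c("female", "male"), length.out = n),
    age_band = rep(AGE_BANDS, length.out = n),
    ethnicity = "white",
    smoker = "no_or_unknown",
    baseline_va = round(seq(25, 70, length.out = n)),
    stringsAsFactors = FALSE)
  age <- age_band_midpoint(cohort$age_band)
  fem <- as.numeric(cohort$sex == "female")
  visits <- do.call(rbind, lapply(seq_len(n), function(i) {
    va <- vapply(c(0, months), function(m) {
      if (m == 0) return(as.numeric(cohort$baseline_va[i]))
      mu <- beta["va"] * cohort$baseline_va[i] + beta["age"] * age[i] +
        beta["sex"] * fem[i] +
        (if (slope_per_month) beta["intercept"] * m else beta["intercept"])
      mu + if (noise_sd > 0) rnorm(1, 0, noise_sd) else 0
    }, numeric(1))
    data.frame(participant_id = cohort$participant_id[i],
               month = c(0, months), va = va, stringsAsFactors = FALSE)
  }))
  list(cohort = cohort, visits = visits)
}
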