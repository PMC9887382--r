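# Trajectory projection: change-score carry-over for matched patients and
# per-month linear models for the rest.

visits_df <- function(id, month, va) {
  data.frame(participant_id = id, month = month, va = va,
             stringsAsFactors = FALSE)
}

test_that("matched carry-over applies the partner's change to the patient's baseline", {
  prof <- make_profiles(1, va = 60)
  flat <- visits_df("S1", c(0, 3, 6, 12), rep(55, 4))
  tr <- carry_matched_trajectory(prof, flat)
  expect_equal(tr$va, rep(60, 4))   # zero change carried
  expect_equal(tr$va[tr$month == 0], prof$baseline_va)

  drop10 <- visits_df("S1", c(0, 3, 6, 12), c(55, 52, 49, 45))
  tr2 <- carry_matched_trajectory(prof, drop10)
  expect_equal(tr2$va[tr2$month == 12], 60 - 10)

  # a -30 change from a 20-letter baseline clamps at the floor
  crash <- visits_df("S1", c(0, 12), c(55, 25))
  tr3 <- carry_matched_trajectory(make_profiles(1, va = 20), crash)
  expect_equal(tr3$va[tr3$month == 12], 0)

  baseline_only <- visits_df("S1", 0, 55)
  expect_error(carry_matched_trajectory(prof, baseline_only),
               "only a baseline")
})

test_that("missing partner months interpolate; trailing gaps carry forward", {
  prof <- make_profiles(1, va = 50)
  # no month-3 or month-12 visit: 3 interpolates 0-6, 12 carries month 6
  v <- visits_df("S1", c(0, 6), c(40, 28))
  tr <- carry_matched_trajectory(prof, v)
  expect_equal(tr$va[tr$month == 3], 50 - 6)   # halfway of the 12-letter drop
  expect_equal(tr$va[tr$month == 12], 50 - 12) # LOCF beyond last visit
})

test_that("per-month OLS recovers a noiseless linear data-generating process", {
  sham <- make_linear_sham(40)  # va(t) = baseline - 2.4 * t exactly
  m <- fit_va_model(sham$cohort, sham$visits)
  for (t in c(3, 6, 12)) {
    cf <- m$models[[paste0("month", t)]]$coefficients
    expect_equal(unname(cf["(Intercept)"]), -2.4 * t, tolerance = 1e-6)
    expect_equal(unname(cf["baseline_va"]), 1, tolerance = 1e-8)
    expect_equal(unname(cf["age_mid"]), 0, tolerance = 1e-8)
    expect_equal(unname(cf["sex_female"]), 0, tolerance = 1e-8)
    expect_lt(m$models[[paste0("month", t)]]$sigma, 1e-6)
  }
  # and predictions reproduce the generator for an in-range profile
  prof <- make_profiles(1, va = 48, sex = "male", age_band = "70-74")
  pr <- predict_unmatched(prof, m)
  expect_equal(pr$va, 48 - 2.4 * c(0, 3, 6, 12), tolerance = 1e-6)
  expect_equal(pr$source, rep("modelled", 4))
})

test_that("per-month OLS recovers noisy coefficients within 3 standard errors", {
  set.seed(31)
  beta <- c(intercept = -0.8, age = -0.1, sex = 1.5, va = 0.9)
  sham <- make_linear_sham(238, beta = beta, noise_sd = 5)
  m <- fit_va_model(sham$cohort, sham$visits)
  for (t in c(3, 6, 12)) {
    fit <- m$models[[paste0("month", t)]]$fit
    est <- coef(fit)
    se <- summary(fit)$coefficients[, "Std. Error"]
    truth <- c(beta["intercept"] * t, beta["age"], beta["sex"], beta["va"])
    expect_true(all(abs(est - truth) < 3 * se))
  }
  expect_error(fit_va_model(sham$cohort[1:9, ], sham$visits), "at least 10")
})

test_that("unmatched prediction clamps and flags extrapolation", {
  sham <- make_linear_sham(30)
  m <- fit_va_model(sham$cohort, sham$visits)  # trained on VA 25-70
  expect_message(predict_unmatched(make_profiles(1, va = 80), m),
                 "extrapolation")
  # all-intercept model: every patient projected to the same values
  m0 <- m
  for (t in c(3, 6, 12)) {
    m0$models[[paste0("month", t)]]$coefficients <-
      c(`(Intercept)` = c(`3` = 50, `6` = 45, `12` = 40)[[as.character(t)]],
        age_mid = 0, sex_female = 0, baseline_va = 0)
  }
  p1 <- predict_unmatched(make_profiles(1, va = 30), m0)
  p2 <- predict_unmatched(make_profiles(1, va = 65, sex = "male"), m0)
  expect_equal(p1$va[-1], c(50, 45, 40))
  expect_equal(p2$va[-1], c(50, 45, 40))
})

test_that("cohort mean carried change equals the partners' mean change", {
  set.seed(12)
  sc <- default_scenario()
  sham <- gen_sham_cohort(sc, seed = 77)
  # mid-range baselines so the [0, 100] clamp never binds
  coh <- make_profiles(60, va = sample(45:60, 60, TRUE),
                       sex = sample(c("female", "male"), 60, TRUE),
                       age_band = sample(AGE_BANDS, 60, TRUE))
  pm <- fit_propensity(coh, sham$cohort)
  ms <- suppressMessages(match_within_calliper(pm))
  vm <- fit_va_model(sham$cohort, sham$visits)
  traj <- project_cohort(coh, ms, sham$visits, vm)
  matched <- traj[traj$source == "matched", ]
  change_cohort <- mean(matched$va[matched$month == 12] -
                          matched$va[matched$month == 0])
  by_id <- split(sham$visits, sham$visits$participant_id)
  partner_change <- vapply(unique(matched$partner_id), function(id) {
    v <- by_id[[id]]
    visit_va <- v$va[match(c(0, 12), v$month)]
    visit_va[2] - visit_va[1]
  }, numeric(1))
  expect_equal(change_cohort, mean(partner_change), tolerance = 1e-10)
})

test_that("clamping never increases the magnitude of change from baseline", {
  prof <- make_profiles(1, va = 15)
  v <- visits_df("S1", c(0, 3, 6, 12), c(55, 35, 20, 5))  # -50 by month 12
  tr <- carry_matched_trajectory(prof, v)
  raw_change <- c(0, -20, -35, -50)
  expect_true(all(abs(tr$va - 15) <= abs(raw_change)))
  expect_true(all(tr$va >= 0 & tr$va <= 100))
})
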