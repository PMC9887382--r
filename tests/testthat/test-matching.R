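# Eligibility screening, propensity model and calliper matching.

test_that("eligibility screening applies inclusive bounds and names the violated one", {
  prof <- make_profiles(4, va = c(80, 25, 70, 20))
  scr <- screen_eligibility(prof, 25, 70)
  expect_setequal(scr$eligible$baseline_va, c(25, 70))
  expect_equal(scr$ineligible$reason[scr$ineligible$baseline_va == 80],
               "baseline_va>70")
  expect_equal(scr$ineligible$reason[scr$ineligible$baseline_va == 20],
               "baseline_va<25")
  empty <- screen_eligibility(make_profiles(0))
  expect_equal(nrow(empty$eligible), 0)
  expect_equal(nrow(empty$ineligible), 0)
  expect_error(screen_eligibility(prof, 70, 25))
})

test_that("identical covariate distributions give near-constant propensity", {
  coh <- make_profiles(60, va = rep(c(40, 60, 55, 45), 15),
                       sex = rep(c("female", "male"), 30),
                       age_band = rep(c("70-74", "80-84"), each = 30))
  shm <- coh
  names(shm)[names(shm) == "patient_id"] <- "participant_id"
  shm$participant_id <- paste0("S", seq_len(60))
  pm <- fit_propensity(coh, shm)
  expect_lt(diff(range(pm$scores$propensity)), 1e-6)
  expect_lt(stats::sd(pm$scores$logit), 1e-6)
  expect_equal(mean(pm$scores$propensity), 0.5, tolerance = 1e-6)
  # logit column is exactly the log-odds of the propensity column
  expect_equal(pm$scores$logit,
               log(pm$scores$propensity / (1 - pm$scores$propensity)),
               tolerance = 1e-8)
  expect_error(fit_propensity(coh[0, ], shm), "non-empty")
})

test_that("propensity model recovers known generating coefficients", {
  set.seed(42)
  n <- 2000
  truth <- c(intercept = 4.0, age = -0.06, sex = 0.4, va = 0.015)
  ab <- sample(AGE_BANDS, 2 * n, replace = TRUE)
  sx <- sample(c("female", "male"), 2 * n, replace = TRUE)
  va <- round(runif(2 * n, 20, 85))
  eta <- truth["intercept"] + truth["age"] * age_band_midpoint(ab) +
    truth["sex"] * (sx == "female") + truth["va"] * va
  grp <- rbinom(2 * n, 1, plogis(eta))
  prof <- data.frame(patient_id = sprintf("P%05d", seq_len(2 * n)),
                     sex = sx, age_band = ab, baseline_va = va,
                     stringsAsFactors = FALSE)
  coh <- prof[grp == 1, ]
  shm <- prof[grp == 0, ]
  names(shm)[1] <- "participant_id"
  pm <- fit_propensity(coh, shm)
  se <- summary(pm$fit)$coefficients[, "Std. Error"]
  expect_true(all(abs(pm$coefficients - truth) < 3 * se))
})

test_that("matching equals the exhaustive best-first oracle on random small instances", {
  set.seed(2024)
  for (rep in 1:200) {
    np <- sample(1:12, 1); ns <- sample(1:12, 1)
    coh <- make_profiles(np, va = sample(25:70, np, replace = TRUE),
                         sex = sample(c("female", "male"), np, TRUE),
                         age_band = sample(AGE_BANDS, np, TRUE))
    shm <- make_profiles(ns, va = sample(25:70, ns, replace = TRUE),
                         sex = sample(c("female", "male"), ns, TRUE),
                         age_band = sample(AGE_BANDS, ns, TRUE),
                         id_prefix = "S")
    names(shm)[names(shm) == "patient_id"] <- "participant_id"
    pm <- tryCatch(suppressWarnings(fit_propensity(coh, shm)),
                   error = function(e) NULL)
    if (is.null(pm)) next  # separation on a tiny instance: skip draw
    ms <- suppressMessages(match_within_calliper(pm))
    sc <- pm$scores
    oracle <- oracle_match(sc$id[sc$group == 1], sc$logit[sc$group == 1],
                           sc$id[sc$group == 0], sc$logit[sc$group == 0],
                           ms$calliper)
    expect_equal(ms$pairs$profile_id, oracle$profile_id)
    expect_equal(ms$pairs$participant_id, oracle$participant_id)
    expect_true(all(ms$pairs$delta_logit <= ms$calliper))
  }
})

test_that("match sets satisfy their structural invariants under random cohorts", {
  for (seed in 1:5) {
    set.seed(seed)
    sc <- default_scenario()
    coh <- gen_patient_profiles(sc, "MEH", n = 80, seed = seed)
    shm <- gen_sham_cohort(sc, seed = seed + 100)$cohort
    pm <- fit_propensity(coh, shm)
    ms <- suppressMessages(match_within_calliper(pm))
    expect_true(all(ms$pairs$delta_logit <= ms$calliper))
    expect_false(any(duplicated(ms$pairs$profile_id)))
    expect_false(any(duplicated(ms$pairs$participant_id)))
    # matched + unmatched partition the cohort
    expect_setequal(c(ms$pairs$profile_id, ms$unmatched$profile_id),
                    coh$patient_id)
    expect_lte(nrow(ms$pairs), min(nrow(coh), nrow(shm)))
  }
})

test_that("matching is invariant to input ordering", {
  set.seed(8)
  sc <- default_scenario()
  coh <- gen_patient_profiles(sc, "MEH", n = 40, seed = 8)
  shm <- gen_sham_cohort(sc, seed = 9)$cohort[1:50, ]
  m1 <- match_within_calliper(fit_propensity(coh, shm))
  m2 <- match_within_calliper(
    fit_propensity(coh[rev(seq_len(nrow(coh))), ],
                   shm[sample(nrow(shm)), ]))
  p1 <- m1$pairs[order(m1$pairs$profile_id), ]
  p2 <- m2$pairs[order(m2$pairs$profile_id), ]
  expect_equal(p1$profile_id, p2$profile_id)
  expect_equal(p1$participant_id, p2$participant_id)
})

test_that("a zero calliper admits only exact logit ties", {
  coh <- make_profiles(3, va = c(50, 50, 60),
                       sex = c("female", "male", "female"),
                       age_band = c("70-74", "70-74", "80-84"))
  shm <- make_profiles(3, va = c(50, 60, 70),
                       sex = c("female", "male", "female"),
                       age_band = c("70-74", "80-84", "80-84"),
                       id_prefix = "S")
  names(shm)[names(shm) == "patient_id"] <- "participant_id"
  pm <- fit_propensity(coh, shm)
  ms <- suppressMessages(match_within_calliper(pm, calliper_mult = 0))
  expect_true(all(ms$pairs$delta_logit == 0))
  # identical-covariate cross pairs exist, so some exact ties match
  expect_gte(nrow(ms$pairs), 1)
})

test_that("matching improves covariate balance on overlapping cohorts", {
  sc <- default_scenario()
  for (seed in 1:10) {
    coh <- gen_patient_profiles(sc, "MEH", n = 500, seed = seed)
    shm <- gen_sham_cohort(sc, seed = seed + 500)$cohort
    shm <- shm[rep(seq_len(nrow(shm)), length.out = 500), ]
    shm$participant_id <- sprintf("S%04d", seq_len(500))
    pm <- fit_propensity(coh, shm)
    ms <- suppressMessages(match_within_calliper(pm))
    des_c <- cbind(age_mid = age_band_midpoint(coh$age_band),
                   female = as.numeric(coh$sex == "female"),
                   va = coh$baseline_va)
    des_s <- cbind(age_mid = age_band_midpoint(shm$age_band),
                   female = as.numeric(shm$sex == "female"),
                   va = shm$baseline_va)
    mc <- match(ms$pairs$profile_id, coh$patient_id)
    msh <- match(ms$pairs$participant_id, shm$participant_id)
    smd_before <- vapply(1:3, function(j)
      abs(standardized_mean_diff(des_c[, j], des_s[, j])), numeric(1))
    smd_after <- vapply(1:3, function(j)
      abs(standardized_mean_diff(des_c[mc, j], des_s[msh, j])), numeric(1))
    expect_lt(mean(smd_after), mean(smd_before))
  }
})
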