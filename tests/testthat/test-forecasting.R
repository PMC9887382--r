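# Decomposition and Holt-Winters smoothing of the weekly demand series.

test_that("additive decomposition recovers trend and seasonality exactly on clean series", {
  # constant series: all structure in the trend
  d <- decompose_additive(rep(5, 20), m = 4)
  expect_equal(d$indices, rep(0, 4), tolerance = 1e-12)
  ok <- !is.na(d$trend)
  expect_equal(d$trend[ok], rep(5, sum(ok)), tolerance = 1e-12)
  expect_equal(d$random[ok], rep(0, sum(ok)), tolerance = 1e-12)

  # known seasonal pattern on a linear trend, no noise
  s <- c(3, -1, -1, -1)  # already centred
  y <- gen_hw_series(0, 2, s, 24)
  d2 <- decompose_additive(y, m = 4)
  expect_equal(d2$indices, s, tolerance = 1e-9)
  ok <- !is.na(d2$trend)
  expect_equal(d2$trend[ok], (2 * seq_along(y))[ok], tolerance = 1e-9)

  # pure trend has no seasonality
  d3 <- decompose_additive(seq_len(12), m = 2)
  expect_equal(d3$indices, c(0, 0), tolerance = 1e-9)
})

test_that("decomposition reconstructs the observations and matches stats::decompose", {
  set.seed(21)
  y <- rpois(120, lambda = 10 + 3 * sin(2 * pi * seq_len(120) / 12))
  d <- decompose_additive(y, m = 12)
  ok <- !is.na(d$trend)
  expect_equal((d$trend + d$seasonal + d$random)[ok], y[ok], tolerance = 1e-12)
  expect_equal(sum(d$indices), 0, tolerance = 1e-9)
  ref <- stats::decompose(ts(y, frequency = 12), type = "additive")
  expect_equal(d$trend, as.numeric(ref$trend), tolerance = 1e-9)
  expect_equal(d$seasonal, as.numeric(ref$seasonal), tolerance = 1e-9)
  expect_error(decompose_additive(y[1:20], m = 12), "shorter")
})

test_that("Holt-Winters reproduces a noiseless trend+seasonal series at every step", {
  s <- c(4, 0, -3, 1, -2, 0)
  y <- gen_hw_series(20, 0.5, s, 30)
  fit <- fit_holt_winters(y, m = 6)
  expect_lt(max(abs(fit$residuals)), 1e-6)   # one-step forecasts exact
  expect_lt(fit$sigma, 1e-6)
  # h-step forecasts continue the closed form
  fc <- forecast_weeks(fit, 12)
  truth <- gen_hw_series(20, 0.5, s, 42)[31:42]
  expect_lt(max(abs(fc$weeks$point - truth)), 1e-6)
  # zero noise implies zero-width prediction intervals
  expect_lt(max(fc$weeks$hi95 - fc$weeks$lo95), 1e-5)
})

test_that("constant series gives constant level, zero trend and zero seasonals", {
  for (p in list(NULL, c(0.3, 0.1, 0.2), c(0.9, 0.9, 0.9))) {
    fit <- fit_holt_winters(rep(7, 24), m = 4, params = p)
    expect_equal(fit$level, 7, tolerance = 1e-8)
    expect_equal(fit$trend, 0, tolerance = 1e-8)
    expect_equal(fit$seasonal, rep(0, 4), tolerance = 1e-8)
  }
  expect_error(fit_holt_winters(rep(7, 7), m = 4), "at least")
})

test_that("initial seasonal indices sum to zero and parameters stay in [0,1]", {
  set.seed(5)
  y <- rpois(60, 12 + 4 * sin(2 * pi * seq_len(60) / 12))
  fit <- fit_holt_winters(y, m = 12)
  expect_lt(abs(sum(fit$init$seasonal)), 1e-6)
  expect_true(all(c(fit$alpha, fit$beta, fit$gamma) >= 0))
  expect_true(all(c(fit$alpha, fit$beta, fit$gamma) <= 1))
})

test_that("forecasts follow the closed-form h-step equation and truncate at zero", {
  st <- structure(list(m = 4, alpha = .2, beta = .1, gamma = .1,
                       level = 10, trend = 0, seasonal = rep(0, 4),
                       sigma = 0, n_obs = 8, last_week = NULL),
                  class = "hw_state")
  fc <- forecast_weeks(st, 20)
  expect_equal(fc$weeks$point, rep(10, 20))
  expect_identical(fc$total, 200L)

  st$trend <- 1
  fc2 <- forecast_weeks(st, 3)
  expect_equal(fc2$weeks$point, c(11, 12, 13))
  expect_identical(fc2$total, 36L)

  st$level <- 1; st$trend <- -1
  fc3 <- forecast_weeks(st, 3)
  expect_equal(fc3$weeks$point, c(0, 0, 0))
  expect_identical(fc3$total, 0L)
  expect_true(all(fc3$weeks$lo95 <= fc3$weeks$point))
  expect_true(all(fc3$weeks$point <= fc3$weeks$hi95))
})

test_that("adding a constant to the series shifts all forecasts by that constant", {
  set.seed(9)
  y <- rpois(48, 15 + 5 * sin(2 * pi * seq_len(48) / 8))
  f1 <- forecast_weeks(fit_holt_winters(y, m = 8), 10)
  f2 <- forecast_weeks(fit_holt_winters(y + 100, m = 8), 10)
  expect_equal(f2$weeks$point - f1$weeks$point, rep(100, 10),
               tolerance = 1e-6)
})

test_that("forecast horizon must contiguously follow the fitted series", {
  sc <- default_scenario()
  ser <- gen_weekly_counts(sc, "MEH", seed = 1)
  fit <- fit_holt_winters(ser, m = 52)
  bad <- iso_week_seq(c(2020L, 13L), c(2020L, 20L))  # skips 2020-W12
  expect_error(forecast_weeks(fit, bad), "2020-W12")
  good <- iso_week_seq(c(2020L, 12L), c(2020L, 31L))
  expect_silent(fc <- forecast_weeks(fit, good))
  expect_equal(nrow(fc$weeks), 20)
})

test_that("our forecasts agree with stats::HoltWinters on a noiseless series", {
  s <- c(5, 1, -2, -4, 0)
  y <- gen_hw_series(30, 0.3, s, 40)
  ours <- forecast_weeks(fit_holt_winters(y, m = 5), 10)$weeks$point
  ref <- stats::HoltWinters(ts(y, frequency = 5))
  theirs <- as.numeric(stats::predict(ref, n.ahead = 10))
  expect_equal(ours, theirs, tolerance = 1e-4)
})

test_that("weekly series validation catches gaps and negative counts", {
  wk <- iso_week_seq(c(2018L, 50L), c(2019L, 3L))
  wk$count <- 1:6
  expect_silent(validate_weekly_series(wk))
  expect_error(validate_weekly_series(wk[-3, ]), "not contiguous")
  wk$count[1] <- -1
  expect_error(validate_weekly_series(wk), ">= 0")
  expect_error(validate_weekly_series(wk[, c("iso_year", "count")]),
               "iso_week")
})
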