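# Weekly demand forecasting: classical additive decomposition and additive
# Holt-Winters exponential smoothing with level, trend and seasonal state.
#
# The series is weekly counts of treatment initiations; the seasonal period
# defaults to 52 weeks (one annual cycle).

#' Validate a weekly count series
#'
#' @param series data.frame with columns `iso_year`, `iso_week`, `count`
#'   (and optionally `centre`); rows must be contiguous calendar weeks.
#' @return the series, invisibly, after validation.
#' @export
validate_weekly_series <- function(series) {
  need <- c("iso_year", "iso_week", "count")
  miss <- setdiff(need, names(series))
  if (length(miss) > 0) {
    stop("weekly series is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (any(series$count < 0)) stop("counts must be >= 0", call. = FALSE)
  if (any(series$iso_week < 1 | series$iso_week > 53)) {
    stop("iso_week outside 1..53", call. = FALSE)
  }
  check_contiguous_weeks(series, "weekly series")
  invisible(series)
}

#' Classical additive decomposition of a seasonal series
#'
#' Splits `x` into trend + seasonal + random: the trend is a centred moving
#' average of window `m` (the usual half-weight endpoints when `m` is even),
#' the seasonal component is the per-period average of the detrended series
#' re-centred to sum to zero over one cycle, and the random component is the
#' remainder. `observed = trend + seasonal + random` holds exactly wherever
#' the trend is defined.
#'
#' @param x numeric vector, length at least `2 * m`.
#' @param m seasonal period (observations per cycle).
#' @return list with components `trend`, `seasonal`, `random` (vectors the
#'   length of `x`; `trend` and `random` are `NA` at the ends) and `indices`
#'   (the `m` seasonal indices, summing to zero).
#' @export
decompose_additive <- function(x, m) {
  n <- length(x)
  if (n < 2 * m) {
    stop(sprintf("series length %d is shorter than two seasonal cycles (2*%d)",
                 n, m), call. = FALSE)
  }
  filt <- if (m %% 2 == 0) c(0.5, rep(1, m - 1), 0.5) / m else rep(1 / m, m)
  trend <- as.numeric(stats::filter(x, filt, sides = 2))
  detr <- x - trend
  pos <- ((seq_len(n) - 1) %% m) + 1
  idx <- vapply(seq_len(m), function(p) {
    mean(detr[pos == p], na.rm = TRUE)
  }, numeric(1))
  idx <- idx - mean(idx)
  seasonal <- idx[pos]
  list(trend = trend, seasonal = seasonal, random = x - trend - seasonal,
       indices = idx, m = m)
}

# one pass of the additive Holt-Winters recursions from a given initial
# state; returns residuals and the final state
.hw_filter <- function(x, m, l0, b0, s0, alpha, beta, gamma) {
  n <- length(x)
  s <- s0
  level <- l0
  trend <- b0
  resid <- numeric(n)
  fitted <- numeric(n)
  for (t in seq_len(n)) {
    p <- ((t - 1) %% m) + 1
    shat <- s[p]
    fitted[t] <- level + trend + shat
    resid[t] <- x[t] - fitted[t]
    new_level <- alpha * (x[t] - shat) + (1 - alpha) * (level + trend)
    trend <- beta * (new_level - level) + (1 - beta) * trend
    s[p] <- gamma * (x[t] - new_level) + (1 - gamma) * shat
    level <- new_level
  }
  list(level = level, trend = trend, seasonal = s,
       fitted = fitted, residuals = resid)
}

#' Fit additive Holt-Winters smoothing to a weekly count series
#'
#' State: level `l`, trend `b` and `m` seasonal indices, updated by the
#' standard additive recursions. Initial level and trend come from a
#' least-squares line through the trend component of the first two cycles'
#' classical decomposition; initial seasonal indices from the same
#' decomposition (they sum to zero). When `params` is omitted the smoothing
#' parameters minimise the in-sample one-step squared error over
#' `[0,1]^3`, seeded from a coarse grid and polished with bounded
#' quasi-Newton optimisation. The one-step residual standard deviation is
#' retained for prediction intervals.
#'
#' @param series weekly series data.frame (see [validate_weekly_series()]),
#'   or a bare numeric vector of counts.
#' @param m seasonal period in weeks; 52 for an annual cycle.
#' @param params optional fixed `c(alpha, beta, gamma)`, each in `[0, 1]`.
#' @return an object of class `hw_state`.
#' @export
fit_holt_winters <- function(series, m = 52, params = NULL) {
  if (is.data.frame(series)) {
    validate_weekly_series(series)
    x <- as.numeric(series$count)
    last_week <- c(series$iso_year[nrow(series)], series$iso_week[nrow(series)])
  } else {
    x <- as.numeric(series)
    last_week <- NULL
  }
  n <- length(x)
  if (n < 2 * m) {
    stop(sprintf("need at least 2*%d = %d weeks to fit, got %d",
                 m, 2 * m, n), call. = FALSE)
  }

  dec <- decompose_additive(x[seq_len(2 * m)], m)
  tt <- seq_len(2 * m)
  ok <- !is.na(dec$trend)
  line <- stats::lm.fit(cbind(1, tt[ok]), dec$trend[ok])
  l0 <- unname(line$coefficients[1])  # level just before the first observation
  b0 <- unname(line$coefficients[2])
  s0 <- dec$indices

  sse <- function(p) sum(.hw_filter(x, m, l0, b0, s0, p[1], p[2], p[3])$residuals^2)

  if (is.null(params)) {
    grid <- as.matrix(expand.grid(a = c(0.1, 0.5, 0.9),
                                  b = c(0.05, 0.3, 0.7),
                                  g = c(0.1, 0.5, 0.9)))
    start <- grid[which.min(apply(grid, 1, sse)), ]
    opt <- tryCatch(
      stats::optim(start, sse, method = "L-BFGS-B", lower = 0, upper = 1),
      error = function(e) {
        stop("Holt-Winters parameter optimisation failed: ",
             conditionMessage(e), call. = FALSE)
      })
    params <- unname(opt$par)
  } else {
    stopifnot(length(params) == 3, all(params >= 0), all(params <= 1))
    params <- unname(params)
  }

  run <- .hw_filter(x, m, l0, b0, s0, params[1], params[2], params[3])
  structure(list(
    m = m, alpha = params[1], beta = params[2], gamma = params[3],
    level = run$level, trend = run$trend, seasonal = run$seasonal,
    sigma = sqrt(mean(run$residuals^2)),
    n_obs = n, last_week = last_week,
    init = list(level = l0, trend = b0, seasonal = s0),
    fitted = run$fitted, residuals = run$residuals
  ), class = "hw_state")
}

#' @export
print.hw_state <- function(x, ...) {
  cat(sprintf(
    "Additive Holt-Winters state (m = %d, n = %d)\n  alpha %.3f  beta %.3f  gamma %.3f\n  level %.3f  trend %.4f  one-step sd %.3f\n",
    x$m, x$n_obs, x$alpha, x$beta, x$gamma, x$level, x$trend, x$sigma))
  invisible(x)
}

#' Forecast future weeks from a fitted Holt-Winters state
#'
#' The h-step point forecast is `level + h * trend + seasonal index`,
#' truncated at zero (counts cannot be negative). 95% prediction intervals
#' are Gaussian, `point +/- 1.96 * sigma * sqrt(h)`, with the lower bound
#' truncated at zero. The horizon total is the rounded sum of the unrounded
#' weekly points, avoiding per-week rounding accumulation.
#'
#' @param state an `hw_state` from [fit_holt_winters()].
#' @param horizon either an integer number of weeks ahead, or a data.frame
#'   of `iso_year`, `iso_week` rows that must contiguously follow the
#'   fitted series.
#' @return an object of class `hw_forecast`: a list with `weeks` (data.frame
#'   `iso_year`, `iso_week`, `point`, `lo95`, `hi95`) and `total`.
#' @export
forecast_weeks <- function(state, horizon) {
  stopifnot(inherits(state, "hw_state"))
  if (is.data.frame(horizon)) {
    check_contiguous_weeks(horizon, "forecast horizon")
    if (!is.null(state$last_week)) {
      nxt <- iso_week_next(state$last_week[1], state$last_week[2])
      if (horizon$iso_year[1] != nxt[1] || horizon$iso_week[1] != nxt[2]) {
        stop(sprintf(
          "forecast horizon must start at %d-W%02d (the week after the fitted series), got %d-W%02d",
          nxt[1], nxt[2], horizon$iso_year[1], horizon$iso_week[1]),
          call. = FALSE)
      }
    }
    hw <- horizon
  } else {
    stopifnot(length(horizon) == 1, horizon >= 1)
    hw <- data.frame(iso_year = NA_integer_, iso_week = seq_len(horizon))
    if (!is.null(state$last_week)) {
      wk <- state$last_week
      rows <- vector("list", horizon)
      for (h in seq_len(horizon)) {
        wk <- iso_week_next(wk[1], wk[2])
        rows[[h]] <- wk
      }
      wk_mat <- do.call(rbind, rows)
      hw <- data.frame(iso_year = wk_mat[, 1], iso_week = wk_mat[, 2])
    }
  }
  H <- nrow(hw)
  h <- seq_len(H)
  s_idx <- ((state$n_obs + h - 1) %% state$m) + 1
  point <- pmax(0, state$level + h * state$trend + state$seasonal[s_idx])
  half <- 1.96 * state$sigma * sqrt(h)
  out <- data.frame(
    iso_year = hw$iso_year, iso_week = hw$iso_week,
    point = point, lo95 = pmax(0, point - half), hi95 = point + half)
  structure(list(weeks = out, total = as.integer(round_half_up(sum(point)))),
            class = "hw_forecast")
}

#' @export
print.hw_forecast <- function(x, ...) {
  cat(sprintf("Holt-Winters forecast: %d weeks, total %d patients\n",
              nrow(x$weeks), x$total))
  invisible(x)
}
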