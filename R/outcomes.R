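# Cohort-level outcome tables: mean acuity over time and the proportions
# crossing the 70 / 25 / 20-letter thresholds, with last observation
# carried forward to keep denominators constant.

#' Carry the last observation forward over a month grid
#'
#' Every trajectory is completed on the full grid: a missing month takes
#' the most recent earlier value. Month 0 must be present for every
#' profile; denominators are then constant across months.
#'
#' @param trajectories data.frame with `profile_id`, `month`, `va` (plus
#'   any other columns, carried from the month-0 row for filled months).
#' @param months the full month grid (default `c(0, 3, 6, 12)`).
#' @return data.frame with every profile defined at every grid month.
#' @export
apply_locf <- function(trajectories, months = TRAJECTORY_MONTHS) {
  months <- sort(months)
  parts <- lapply(split(trajectories, trajectories$profile_id), function(tr) {
    tr <- tr[order(tr$month), , drop = FALSE]
    if (!0 %in% tr$month) {
      stop(sprintf("trajectory %s is missing month 0", tr$profile_id[1]),
           call. = FALSE)
    }
    out <- lapply(months, function(m) {
      have <- tr[tr$month <= m, , drop = FALSE]
      row <- have[nrow(have), , drop = FALSE]  # latest observation <= m
      row$month <- m
      row
    })
    do.call(rbind, out)
  })
  res <- do.call(rbind, parts)
  rownames(res) <- NULL
  res
}

#' Percentage of a cohort crossing a threshold
#'
#' `100 * count / n`, reported to one decimal place (half-up), the
#' convention used in every cohort table.
#'
#' @param count number of eyes crossing the threshold.
#' @param n cohort size.
#' @return percentage to one decimal place.
#' @export
threshold_percent <- function(count, n) round_half_up(100 * count / n, 1)

#' Summarise projected outcomes for one cohort
#'
#' Per month: n, mean and sample sd of VA, and counts/percentages of eyes
#' with VA >= 70 (good vision, inclusive), VA < 25 (below the treatment
#' floor, strict) and VA <= 20 (severe sight impairment, inclusive).
#' Percentages to one decimal place. Requires a complete grid, i.e.
#' [apply_locf()] output.
#'
#' @param trajectories completed trajectory data.frame (`profile_id`,
#'   `month`, `va`).
#' @param centre optional cohort label stored on the result.
#' @return data.frame of class `outcome_table` with columns `centre`,
#'   `month`, `n`, `mean_va`, `sd_va`, `n_ge70`, `pct_ge70`, `n_lt25`,
#'   `pct_lt25`, `n_le20`, `pct_le20`.
#' @export
summarize_outcomes <- function(trajectories, centre = NA_character_) {
  if (nrow(trajectories) == 0) stop("no trajectories to summarise", call. = FALSE)
  months <- sort(unique(trajectories$month))
  n_profiles <- length(unique(trajectories$profile_id))
  counts <- table(trajectories$month)
  if (any(counts != n_profiles)) {
    stop("incomplete month grid; apply_locf() first", call. = FALSE)
  }
  rows <- lapply(months, function(m) {
    va <- trajectories$va[trajectories$month == m]
    n <- length(va)
    data.frame(centre = centre, month = m, n = n,
               mean_va = mean(va), sd_va = sd0(va),
               n_ge70 = sum(va >= 70), pct_ge70 = threshold_percent(sum(va >= 70), n),
               n_lt25 = sum(va < 25), pct_lt25 = threshold_percent(sum(va < 25), n),
               n_le20 = sum(va <= 20), pct_le20 = threshold_percent(sum(va <= 20), n))
  })
  out <- do.call(rbind, rows)
  class(out) <- c("outcome_table", class(out))
  out
}

#' Pool two outcome tables (e.g. matched + modelled cohorts)
#'
#' Counts add; means recombine as size-weighted means; standard deviations
#' recombine with the pooled-variance formula including the between-group
#' mean-shift term, under the sample (n-1) convention. Percentages are
#' recomputed from the pooled counts.
#'
#' @param a,b `outcome_table` data.frames on the same month grid. Either
#'   may be `NULL` or empty (identity).
#' @param centre label for the pooled table (default taken from `a`).
#' @return pooled `outcome_table`.
#' @export
pool_cohorts <- function(a, b, centre = NULL) {
  empty <- function(x) is.null(x) || nrow(x) == 0 || all(x$n == 0)
  if (empty(b)) return(a)
  if (empty(a)) return(b)
  if (!identical(sort(a$month), sort(b$month))) {
    stop("outcome tables are on different month grids", call. = FALSE)
  }
  a <- a[order(a$month), ]; b <- b[order(b$month), ]
  n <- a$n + b$n
  mean_va <- (a$n * a$mean_va + b$n * b$mean_va) / n
  ss <- (a$n - 1) * a$sd_va^2 + (b$n - 1) * b$sd_va^2 +
    a$n * b$n / n * (a$mean_va - b$mean_va)^2
  sd_va <- ifelse(n > 1, sqrt(ss / (n - 1)), 0)
  out <- data.frame(
    centre = if (is.null(centre)) a$centre else centre,
    month = a$month, n = n, mean_va = mean_va, sd_va = sd_va,
    n_ge70 = a$n_ge70 + b$n_ge70,
    pct_ge70 = threshold_percent(a$n_ge70 + b$n_ge70, n),
    n_lt25 = a$n_lt25 + b$n_lt25,
    pct_lt25 = threshold_percent(a$n_lt25 + b$n_lt25, n),
    n_le20 = a$n_le20 + b$n_le20,
    pct_le20 = threshold_percent(a$n_le20 + b$n_le20, n))
  class(out) <- c("outcome_table", class(out))
  out
}
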