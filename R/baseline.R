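# Baseline cohort summaries: the per-centre and pooled demography /
# visual-acuity tables reported for a treatment-initiation cohort.

.CAT_LEVELS <- list(
  sex       = c("female", "male"),
  age_band  = c("<65", "65-69", "70-74", "75-79", "80-84", "85+"),
  ethnicity = c("white", "not_white", "not_reported"),
  smoker    = c("yes", "no_or_unknown")
)

# sample sd with the single-observation convention sd = 0
sd0 <- function(x) if (length(x) < 2) 0 else stats::sd(x)

#' Welch two-sample t-test from summary statistics
#'
#' Unequal-variance t-statistic, Welch-Satterthwaite degrees of freedom and
#' two-sided p-value, computable from group means, SDs and sizes alone (as
#' when only a published table is available).
#'
#' @param m1,s1,n1 mean, sd and size of group 1.
#' @param m2,s2,n2 mean, sd and size of group 2.
#' @return list with `statistic`, `df`, `p_value`.
#' @export
welch_t_from_summary <- function(m1, s1, n1, m2, s2, n2) {
  stopifnot(n1 >= 2, n2 >= 2)
  v1 <- s1^2 / n1
  v2 <- s2^2 / n2
  t_stat <- (m1 - m2) / sqrt(v1 + v2)
  df <- (v1 + v2)^2 / (v1^2 / (n1 - 1) + v2^2 / (n2 - 1))
  list(statistic = t_stat, df = df,
       p_value = 2 * stats::pt(-abs(t_stat), df))
}

#' Summarise a baseline cohort
#'
#' Computes, per centre and pooled over centres, the counts and percentages
#' of each category of sex, age band, ethnicity and smoking status, the
#' visual-acuity distribution (mean, sd, median, min, max), the counts above
#' or below the 70 / 25 / 20-letter thresholds, and — when exactly two
#' centres are present — the Welch t-test comparing centre VA means.
#' Percentages are reported to one decimal place; a single-observation sd is
#' reported as 0 so summaries are always numeric.
#'
#' @param profiles data.frame of patient profiles with at least columns
#'   `centre`, `sex`, `age_band`, `ethnicity`, `smoker`, `baseline_va`.
#' @return an object of class `baseline_summary`: a list with elements
#'   `table` (long data.frame: cohort, variable, level, count, percent),
#'   `va` (per-cohort VA statistics) and `welch` (or `NULL`).
#' @export
summarize_baseline <- function(profiles) {
  if (!is.data.frame(profiles) || nrow(profiles) == 0) {
    stop("'profiles' must be a non-empty data.frame", call. = FALSE)
  }
  if (any(profiles$baseline_va < 0 | profiles$baseline_va > 100)) {
    stop("baseline_va outside [0, 100]", call. = FALSE)
  }
  centres <- sort(unique(as.character(profiles$centre)))
  cohorts <- c(centres, "pooled")

  one_cohort <- function(df, label) {
    n <- nrow(df)
    rows <- lapply(names(.CAT_LEVELS), function(v) {
      lv <- .CAT_LEVELS[[v]]
      cnt <- as.integer(table(factor(df[[v]], levels = lv)))
      data.frame(cohort = label, variable = v, level = lv, count = cnt,
                 percent = round_half_up(100 * cnt / n, 1))
    })
    thr <- data.frame(
      cohort = label,
      variable = c("va_ge70", "va_lt25", "va_le20"),
      level = "yes",
      count = c(sum(df$baseline_va >= 70),
                sum(df$baseline_va < 25),
                sum(df$baseline_va <= 20))
    )
    thr$percent <- round_half_up(100 * thr$count / n, 1)
    list(
      table = rbind(do.call(rbind, rows), thr),
      va = data.frame(cohort = label, n = n,
                      mean = mean(df$baseline_va),
                      sd = sd0(df$baseline_va),
                      median = stats::median(df$baseline_va),
                      min = min(df$baseline_va),
                      max = max(df$baseline_va))
    )
  }

  parts <- lapply(cohorts, function(cc) {
    df <- if (cc == "pooled") profiles else
      profiles[profiles$centre == cc, , drop = FALSE]
    one_cohort(df, cc)
  })
  va <- do.call(rbind, lapply(parts, `[[`, "va"))

  welch <- NULL
  if (length(centres) == 2) {
    a <- va[va$cohort == centres[1], ]
    b <- va[va$cohort == centres[2], ]
    if (a$n >= 2 && b$n >= 2) {
      welch <- welch_t_from_summary(a$mean, a$sd, a$n, b$mean, b$sd, b$n)
    }
  }

  structure(list(table = do.call(rbind, lapply(parts, `[[`, "table")),
                 va = va, welch = welch, centres = centres),
            class = "baseline_summary")
}

#' @export
print.baseline_summary <- function(x, ...) {
  cat("Baseline cohort summary (", paste(x$centres, collapse = ", "),
      ")\n\n", sep = "")
  print(x$va, row.names = FALSE)
  if (!is.null(x$welch)) {
    cat(sprintf("\nWelch t (centre VA means): t = %.3f, df = %.1f, p = %.4g\n",
                x$welch$statistic, x$welch$df, x$welch$p_value))
  }
  invisible(x)
}

#' Write a baseline summary as a long-format CSV
#'
#' @param summary a `baseline_summary` object.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_baseline_summary <- function(summary, path) {
  stopifnot(inherits(summary, "baseline_summary"))
  tab <- summary$table
  va_long <- do.call(rbind, lapply(seq_len(nrow(summary$va)), function(i) {
    r <- summary$va[i, ]
    data.frame(cohort = r$cohort, variable = "va",
               level = c("n", "mean", "sd", "median", "min", "max"),
               count = NA_integer_,
               percent = c(r$n, r$mean, r$sd, r$median, r$min, r$max))
  }))
  names(va_long)[names(va_long) == "percent"] <- "percent"
  utils::write.csv(rbind(tab, va_long), path, row.names = FALSE)
  invisible(path)
}
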