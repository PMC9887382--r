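# Hypothetical-cohort construction: sample the forecasted number of patient
# profiles from the historical pool of the same calendar window
# (ISO weeks 12-31 of the two preceding years).

#' Build the historical sampling pool for a centre
#'
#' Restricts profiles to one centre and to index weeks inside the sampling
#' window: the same ISO weeks as the forecast horizon, in the pool years.
#'
#' @param profiles data.frame of patient profiles (`centre`, `index_year`,
#'   `index_week`, ...).
#' @param centre centre label to keep.
#' @param weeks integer vector of ISO weeks defining the window
#'   (default 12:31).
#' @param years integer vector of pool years (default 2018 and 2019).
#' @return data.frame of the in-window profiles, with attributes `centre`,
#'   `weeks` and `years`.
#' @export
build_pool <- function(profiles, centre, weeks = 12:31,
                       years = c(2018L, 2019L)) {
  keep <- profiles$centre == centre &
    profiles$index_week %in% weeks &
    profiles$index_year %in% years
  pool <- profiles[keep, , drop = FALSE]
  if (nrow(pool) == 0) {
    stop(sprintf(
      "empty sampling pool for centre %s (weeks %d-%d of %s)",
      centre, min(weeks), max(weeks), paste(years, collapse = "/")),
      call. = FALSE)
  }
  message(sprintf("sampling pool for %s: %d profiles (weeks %d-%d, %s)",
                  centre, nrow(pool), min(weeks), max(weeks),
                  paste(years, collapse = "/")))
  attr(pool, "centre") <- centre
  attr(pool, "weeks") <- weeks
  attr(pool, "years") <- years
  pool
}

#' Sample hypothetical patient profiles from a pool
#'
#' Simple uniform random sampling: without replacement when `n` does not
#' exceed the pool size, otherwise with replacement (reported via a
#' message). Sampled rows keep every covariate of their source profile;
#' they receive a fresh id suffixed with the draw index so that duplicate
#' draws stay distinguishable downstream, plus `source_patient_id` and
#' `draw_index` columns.
#'
#' @param pool data.frame from [build_pool()].
#' @param n number of profiles to draw (>= 1).
#' @param seed optional integer seed for reproducibility.
#' @return data.frame of `n` sampled profiles.
#' @export
sample_profiles <- function(pool, n, seed = NULL) {
  if (!is.numeric(n) || length(n) != 1 || n < 1) {
    stop("'n' must be a positive integer", call. = FALSE)
  }
  if (nrow(pool) == 0) stop("pool is empty", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  replace <- n > nrow(pool)
  if (replace) {
    message(sprintf(
      "requested %d draws from a pool of %d: sampling with replacement",
      n, nrow(pool)))
  }
  idx <- sample.int(nrow(pool), size = n, replace = replace)
  out <- pool[idx, , drop = FALSE]
  out$source_patient_id <- out$patient_id
  out$draw_index <- seq_len(n)
  out$patient_id <- sprintf("%s#%d", out$source_patient_id, out$draw_index)
  rownames(out) <- NULL
  out
}
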