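# ISO-8601 week arithmetic for the weekly initiation series.

#' Number of ISO weeks in an ISO year
#'
#' An ISO year has 53 weeks when 1 January falls on a Thursday, or on a
#' Wednesday in a leap year; otherwise 52.
#'
#' @param iso_year integer vector of ISO years.
#' @return integer vector, 52 or 53.
#' @export
weeks_in_iso_year <- function(iso_year) {
  jan1_wday <- function(y) {
    # Zeller-free: weekday of 1 Jan via Date arithmetic, 4 = Thursday
    as.POSIXlt(as.Date(sprintf("%d-01-01", y)))$wday
  }
  leap <- (iso_year %% 4 == 0 & iso_year %% 100 != 0) | iso_year %% 400 == 0
  w <- vapply(iso_year, jan1_wday, numeric(1))
  ifelse(w == 4 | (leap & w == 3), 53L, 52L)
}

#' Sequence of consecutive ISO weeks
#'
#' @param from,to length-2 integer vectors `c(iso_year, iso_week)`,
#'   inclusive bounds.
#' @return data.frame with columns `iso_year`, `iso_week`.
#' @export
iso_week_seq <- function(from, to) {
  stopifnot(length(from) == 2, length(to) == 2)
  y <- from[1]; w <- from[2]
  out_y <- integer(0); out_w <- integer(0)
  repeat {
    out_y <- c(out_y, y); out_w <- c(out_w, w)
    if (y == to[1] && w == to[2]) break
    if (y > to[1] || (y == to[1] && w > to[2])) {
      stop("'from' week is after 'to' week", call. = FALSE)
    }
    w <- w + 1
    if (w > weeks_in_iso_year(y)) { y <- y + 1; w <- 1 }
  }
  data.frame(iso_year = as.integer(out_y), iso_week = as.integer(out_w))
}

# successor of an (iso_year, iso_week) pair
iso_week_next <- function(iso_year, iso_week) {
  if (iso_week < weeks_in_iso_year(iso_year)) {
    c(iso_year, iso_week + 1L)
  } else {
    c(iso_year + 1L, 1L)
  }
}

# check that the rows of a (iso_year, iso_week) frame are contiguous,
# strictly increasing calendar weeks
check_contiguous_weeks <- function(weeks, what = "series") {
  if (nrow(weeks) < 2) return(invisible(TRUE))
  for (i in 2:nrow(weeks)) {
    nxt <- iso_week_next(weeks$iso_year[i - 1], weeks$iso_week[i - 1])
    if (weeks$iso_year[i] != nxt[1] || weeks$iso_week[i] != nxt[2]) {
      stop(sprintf("%s weeks are not contiguous at %d-W%02d -> %d-W%02d",
                   what, weeks$iso_year[i - 1], weeks$iso_week[i - 1],
                   weeks$iso_year[i], weeks$iso_week[i]), call. = FALSE)
    }
  }
  invisible(TRUE)
}
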