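# Visual-acuity scales and patient-record normalisation.

#' Age bands used throughout the pipeline
#'
#' Patient age is only ever available as one of six deidentified bands.
#' `age_band_midpoint()` maps a band to the numeric age (years) used wherever
#' a model needs a number: interior bands map to their midpoint, the open
#' bands `<65` and `85+` to 60 and 88 respectively.
#'
#' @format `AGE_BANDS` is a character vector of the six band labels, in
#'   increasing order of age.
#' @export
AGE_BANDS <- c("<65", "65-69", "70-74", "75-79", "80-84", "85+")

.AGE_MIDPOINTS <- c(`<65` = 60, `65-69` = 67, `70-74` = 72,
                    `75-79` = 77, `80-84` = 82, `85+` = 88)

#' @rdname AGE_BANDS
#' @param age_band character vector of band labels.
#' @return numeric vector of representative ages in years.
#' @export
age_band_midpoint <- function(age_band) {
  bad <- setdiff(unique(age_band), AGE_BANDS)
  if (length(bad) > 0) {
    stop("unknown age band(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  unname(.AGE_MIDPOINTS[age_band])
}

#' Round half away from zero (upwards)
#'
#' The reporting convention for letters, counts and percentages throughout
#' the pipeline (R's own `round()` rounds halves to even).
#'
#' @param x numeric vector.
#' @param digits decimal places to keep.
#' @return rounded vector.
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  floor(x * p + 0.5) / p
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Convert a Snellen fraction to approximate ETDRS letters
#'
#' Letters are computed as `85 + 50 * log10(numerator / denominator)`,
#' rounded half-up to an integer and clamped to `[0, 100]`. The formula
#' reproduces the standard clinical equivalences 6/6 = 85, 6/12 = 70,
#' 6/96 = 25 and 3/60 = 20 letters.
#'
#' @param numerator,denominator positive numbers; e.g. 6 and 12 for Snellen
#'   6/12 (metric) or 20 and 40 for 20/40 (imperial). Vectorised.
#' @return integer vector of approximate ETDRS letter scores in `[0, 100]`.
#' @examples
#' snellen_to_etdrs(6, 12)  # 70
#' snellen_to_etdrs(3, 60)  # 20
#' @export
snellen_to_etdrs <- function(numerator, denominator) {
  if (any(!is.finite(numerator)) || any(!is.finite(denominator)) ||
      any(numerator <= 0) || any(denominator <= 0)) {
    stop("Snellen numerator and denominator must be positive numbers",
         call. = FALSE)
  }
  letters <- 85 + 50 * log10(numerator / denominator)
  as.integer(clamp(round_half_up(letters), 0, 100))
}

#' Designate the study eye from per-eye diagnosis dates
#'
#' The study eye is the first eye diagnosed; when both eyes present on the
#' same date the right eye is designated.
#'
#' @param diagnosis_date_right,diagnosis_date_left `Date` scalars or `NA`
#'   for an eye that never presented.
#' @return `"right"` or `"left"`.
#' @export
designate_study_eye <- function(diagnosis_date_right, diagnosis_date_left) {
  r <- diagnosis_date_right
  l <- diagnosis_date_left
  if ((length(r) != 1) || (length(l) != 1)) {
    stop("diagnosis dates must be scalars", call. = FALSE)
  }
  if (is.na(r) && is.na(l)) {
    stop("at least one eye must have a diagnosis date", call. = FALSE)
  }
  if (is.na(l)) return("right")
  if (is.na(r)) return("left")
  if (as.Date(l) < as.Date(r)) "left" else "right"
}
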