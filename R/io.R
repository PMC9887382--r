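# CSV interchange: fixed schemas, validated on read, plus the packaged
# encodings of the published baseline tables and threshold counts.

.SCHEMAS <- list(
  profiles = c("patient_id", "centre", "sex", "age_band", "ethnicity",
               "smoker", "index_year", "index_week", "study_eye",
               "baseline_va"),
  weekly_counts = c("centre", "iso_year", "iso_week", "count"),
  sham_cohort = c("participant_id", "sex", "age_band", "ethnicity",
                  "smoker", "baseline_va"),
  sham_visits = c("participant_id", "month", "va"),
  hypothetical_cohort = c("patient_id", "centre", "sex", "age_band",
                          "ethnicity", "smoker", "index_year", "index_week",
                          "study_eye", "baseline_va", "source_patient_id",
                          "draw_index"),
  forecast = c("centre", "iso_year", "iso_week", "point", "lo95", "hi95"),
  matches = c("profile_id", "participant_id", "delta_logit"),
  unmatched = c("profile_id", "reason"),
  trajectories = c("profile_id", "source", "partner_id", "month", "va"),
  outcomes = c("centre", "month", "n", "mean_va", "sd_va", "n_ge70",
               "pct_ge70", "n_lt25", "pct_lt25", "n_le20", "pct_le20")
)

#' Read a pipeline CSV with schema validation
#'
#' Readers reject files whose header lacks a required column, naming the
#' file and the column.
#'
#' @param path CSV file path.
#' @param schema one of `names(amdforecast:::.SCHEMAS)`, e.g. `"profiles"`.
#' @return data.frame.
#' @export
read_stage_csv <- function(path, schema) {
  cols <- .SCHEMAS[[schema]]
  if (is.null(cols)) stop("unknown schema: ", schema, call. = FALSE)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(cols, names(df))
  if (length(miss) > 0) {
    stop(sprintf("%s: missing required column(s): %s",
                 basename(path), paste(miss, collapse = ", ")),
         call. = FALSE)
  }
  df
}

#' Write a pipeline CSV
#'
#' @param df data.frame containing at least the schema columns (written in
#'   schema order).
#' @param path output path.
#' @param schema schema name, as for [read_stage_csv()].
#' @return `path`, invisibly.
#' @export
write_stage_csv <- function(df, path, schema) {
  cols <- .SCHEMAS[[schema]]
  if (is.null(cols)) stop("unknown schema: ", schema, call. = FALSE)
  miss <- setdiff(cols, names(df))
  if (length(miss) > 0) {
    stop(sprintf("cannot write %s: missing column(s): %s",
                 basename(path), paste(miss, collapse = ", ")),
         call. = FALSE)
  }
  utils::write.csv(df[, cols, drop = FALSE], path, row.names = FALSE)
  invisible(path)
}

#' Packaged encodings of the published tables
#'
#' Returns the plain-text fixtures shipped with the package:
#' \describe{
#'   \item{table1}{baseline demography and VA margins of the two-centre
#'     cohort (long format, per cohort).}
#'   \item{table2}{the model population: sham arm plus matched/unmatched
#'     centre cohorts, same long format.}
#'   \item{figure3}{pooled per-month counts of eyes crossing the 70/25/20
#'     letter thresholds, with a `source` column distinguishing the
#'     results-text counts (primary) from the variant implied by the
#'     baseline table where the publication is internally inconsistent.}
#'   \item{projection}{mean (sd) projected VA at months 0 and 12 for the
#'     matched and unmatched cohorts of each centre.}
#' }
#'
#' @return list of four data.frames.
#' @export
load_paper_fixtures <- function() {
  rd <- function(f) {
    utils::read.csv(system.file("extdata", f, package = "amdforecast",
                                mustWork = TRUE),
                    stringsAsFactors = FALSE)
  }
  list(table1 = rd("table1_baseline.csv"),
       table2 = rd("table2_model_population.csv"),
       figure3 = rd("figure3_threshold_counts.csv"),
       projection = rd("results_va_projection.csv"))
}
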