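#' Write a cohort as JSONL plus a true-metrics CSV
#'
#' `cohort.jsonl` carries one JSON object per patient (id, chronological
#' age, sex, locale, report text, follow-up and outcome);
#' `true_metrics.csv` carries the generator's ground-truth metric columns
#' for testing and auditing.
#'
#' @param records a `cohort` data.frame.
#' @param dir output directory (created if missing).
#' @return The directory, invisibly.
#' @export
write_cohort <- function(records, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  jl <- records[, intersect(
    c("patient_id", "chrono_age", "sex", "locale", "report_text",
      "followup_time", "mace_event", "mace_event_time"), names(records))]
  con <- file(file.path(dir, "cohort.jsonl"), open = "w", encoding = "UTF-8")
  on.exit(close(con))
  jsonlite::stream_out(jl, con, verbose = FALSE, digits = NA, na = "null")
  truth <- records[, intersect(
    c("patient_id", "cac_au", "cadrads", "vessel_over50",
      "proximal_lad_over70", "soft_plaque_rca_cx_only", "hrp_present",
      "lvef_percent", "edv_ml", "esv_ml", "extracoronary_findings",
      "true_bioage", "injected_failure"), names(records))]
  utils::write.csv(truth, file.path(dir, "true_metrics.csv"), row.names = FALSE)
  invisible(dir)
}

#' Read a cohort JSONL file
#'
#' @param path path to a `cohort.jsonl` written by [write_cohort()] (or any
#'   NDJSON file with the same fields).
#' @return A data.frame of class `cohort`.
#' @export
read_cohort_jsonl <- function(path) {
  con <- file(path, open = "r", encoding = "UTF-8")
  on.exit(close(con))
  df <- jsonlite::stream_in(con, verbose = FALSE)
  if (is.null(df$mace_event_time)) df$mace_event_time <- NA_real_
  class(df) <- c("cohort", "data.frame")
  df
}
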