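config_error <- function(msg) {
  stop(errorCondition(msg, class = c("cardioage_config_error", "error",
                                     "condition")))
}

#' Assemble an end-to-end run configuration
#'
#' @param cohort a [cohort_config()].
#' @param scoring a [scoring_config()].
#' @param batch_sizes optional batch sizes for the consistency table.
#' @param cumulative cumulative prefixes (default) or disjoint batches.
#' @param locale locale hint passed to the parser (`"auto"`, `"de"`,
#'   `"en"`).
#' @param seed optional integer overriding `cohort$seed`.
#' @return List of class `run_config`.
#' @export
run_config <- function(cohort = cohort_config(), scoring = scoring_config(),
                       batch_sizes = NULL, cumulative = TRUE,
                       locale = "auto", seed = NULL) {
  if (!inherits(cohort, "cohort_config")) config_error("cohort must be a cohort_config")
  if (!inherits(scoring, "scoring_config")) config_error("scoring must be a scoring_config")
  if (!locale %in% c("auto", "de", "en")) config_error("locale must be auto/de/en")
  if (!is.null(seed)) cohort$seed <- as.integer(seed)
  structure(list(cohort = cohort, scoring = scoring,
                 batch_sizes = batch_sizes, cumulative = cumulative,
                 locale = locale),
            class = "run_config")
}

#' Read a run configuration from YAML
#'
#' The YAML file may carry `cohort:`, `scoring:` and `eval:` blocks whose
#' keys map one-to-one onto the [cohort_config()], [scoring_config()] and
#' [run_config()] arguments, plus a top-level `seed`.
#'
#' @param path YAML file path.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  coh <- do.call(cohort_config, raw$cohort %||% list())
  sco <- do.call(scoring_config, raw$scoring %||% list())
  ev <- raw$eval %||% list()
  run_config(cohort = coh, scoring = sco,
             batch_sizes = ev$batch_sizes,
             cumulative = ev$cumulative %||% TRUE,
             locale = ev$locale %||% "auto",
             seed = raw$seed)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# parse + score one cohort table; returns the table with parse, score and
# inclusion columns appended
process_records <- function(records, scoring, locale = "auto") {
  n <- nrow(records)
  parse_outcome <- character(n)
  failure_reason <- rep(NA_character_, n)
  parsed_cols <- vector("list", n)
  for (i in seq_len(n)) {
    pr <- parse_report(records$report_text[i], locale)
    parse_outcome[i] <- pr$outcome
    if (pr$outcome == "parsed") {
      parsed_cols[[i]] <- metrics_to_row(pr$metrics)
    } else {
      failure_reason[i] <- pr$failure_reason
    }
  }
  blank <- metrics_to_row(key_metrics(0, "0", 60))
  blank[1, ] <- NA
  parsed <- do.call(rbind, lapply(parsed_cols, function(x) if (is.null(x)) blank else x))
  names(parsed) <- paste0("parsed_", names(parsed))
  out <- cbind(records, parsed)
  out$parse_outcome <- parse_outcome
  out$parse_failure_reason <- failure_reason

  rule_cols <- c("cadrads", "multivessel", "proximal_lad",
                 "soft_plaque_rca_cx", "low_lvef_or_elevated_volumes",
                 "extracoronary")
  for (rc in c("base_years", paste0("inc_", rule_cols), "total_years",
               "display_years", "deviation_years")) {
    out[[rc]] <- NA_real_
  }
  out$plausible <- NA
  out$score_failure_reason <- NA_character_
  for (i in which(parse_outcome == "parsed")) {
    est <- compose_bioage(metrics_from_row(parsed_cols[[i]]),
                          chrono_age = out$chrono_age[i], config = scoring)
    out$base_years[i] <- est$base_years
    led <- est$increment_ledger
    out$inc_cadrads[i] <- sum(led$years[startsWith(led$rule, "cadrads_")])
    for (rc in rule_cols[-1]) {
      out[[paste0("inc_", rc)]][i] <- sum(led$years[led$rule == rc])
    }
    out$total_years[i] <- est$total_years
    out$display_years[i] <- est$display_years
    out$deviation_years[i] <- est$deviation_years
    out$plausible[i] <- est$plausible
    out$score_failure_reason[i] <- est$failure_reason
  }
  out$inclusion_status <- ifelse(
    out$parse_outcome != "parsed",
    paste0("excluded_parse:", out$parse_failure_reason),
    ifelse(out$plausible, "included",
           paste0("excluded_score:", out$score_failure_reason)))
  out
}

#' Run the full simulate / parse / score / evaluate pipeline
#'
#' Either simulates a cohort from `config$cohort` (generation, hostile
#' report injection, MACE simulation) or takes an existing records table,
#' then parses every report, composes the biological age for every parsed
#' record, applies the plausibility filter, and evaluates MACE
#' discrimination on the included records. Excluded records are retained
#' in the per-patient table with their exclusion reason — never silently
#' dropped — and the manifest's count identities hold exactly.
#'
#' @param config a [run_config()].
#' @param records optional existing cohort table (e.g. from
#'   [read_cohort_jsonl()]); when `NULL` a synthetic cohort is simulated.
#' @return List of class `pipeline_result`: `table` (per-patient),
#'   `summary` (an `eval_summary`) and `manifest`.
#' @examples
#' \donttest{
#' res <- run_pipeline(run_config(cohort = cohort_config(n_patients = 60)))
#' res$manifest$success_rate
#' }
#' @export
run_pipeline <- function(config = run_config(), records = NULL) {
  if (!inherits(config, "run_config")) config_error("config must be a run_config")
  validate_cohort_config(config$cohort)
  if (is.null(records)) {
    records <- generate_cohort(config$cohort)
    records <- inject_failures(records, config$cohort)
    records <- simulate_mace(records, config$cohort)
  }
  if (is.null(records$report_text)) {
    stop(errorCondition("records must carry report_text",
                        class = c("cardioage_input_error", "error", "condition")))
  }
  tab <- process_records(records, config$scoring, config$locale)

  uploaded <- nrow(tab)
  parse_failed <- tab$parse_outcome != "parsed"
  parse_by_reason <- as.list(table(tab$parse_failure_reason[parse_failed]))
  implausible <- !parse_failed & !tab$plausible
  included <- tab$inclusion_status == "included"
  n_included <- sum(included)
  if (n_included == 0) {
    dominant <- names(which.max(table(tab$inclusion_status)))
    stop("no records included; dominant exclusion: ", dominant)
  }
  stopifnot(n_included == uploaded - sum(parse_failed) - sum(implausible))

  labels <- binary_labels(tab)
  tab$mace_label <- labels
  batch_sizes <- config$batch_sizes
  if (!is.null(batch_sizes)) {
    # batch sizes refer to included records; clamp to the realized count
    batch_sizes <- sort(unique(pmin(batch_sizes, n_included)))
  }
  summary <- evaluate_cohort(
    bioages = tab$total_years[included],
    chrono_ages = tab$chrono_age[included],
    labels = labels[included],
    batch_sizes = batch_sizes
  )
  manifest <- list(
    package_version = as.character(utils::packageVersion("cardioage")),
    seed = config$cohort$seed,
    config_hash = rlang::hash(config),
    uploaded = uploaded,
    parse_failures = parse_by_reason,
    n_parse_failed = sum(parse_failed),
    n_implausible = sum(implausible),
    included = n_included,
    success_rate = n_included / uploaded,
    n_events_included = sum(labels[included]),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  structure(list(table = tab, summary = summary, manifest = manifest),
            class = "pipeline_result")
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf("cardioage pipeline run: %d uploaded, %d included (%.1f%%)\n",
              x$manifest$uploaded, x$manifest$included,
              100 * x$manifest$success_rate))
  print(x$summary)
  invisible(x)
}

#' Fixed column order of the per-patient CSV
#'
#' @return Character vector of the column names written by
#'   [write_outputs()], in order.
#' @export
patient_csv_columns <- function() {
  c("patient_id", "chrono_age", "sex", "locale",
    "parsed_cac_au", "parsed_cadrads", "parsed_vessel_over50",
    "parsed_proximal_lad_over70", "parsed_soft_plaque_rca_cx_only",
    "parsed_hrp_present", "parsed_lvef_percent", "parsed_edv_ml",
    "parsed_esv_ml", "parsed_extracoronary_findings",
    "base_years", "inc_cadrads", "inc_multivessel", "inc_proximal_lad",
    "inc_soft_plaque_rca_cx", "inc_low_lvef_or_elevated_volumes",
    "inc_extracoronary", "total_years", "display_years", "deviation_years",
    "plausible", "followup_time", "mace_event", "mace_event_time",
    "mace_label", "inclusion_status")
}

#' Write pipeline outputs to a directory
#'
#' Writes `patients.csv` (fixed, documented column order), `summary.json`,
#' `manifest.json` and a human-readable `run.log`.
#'
#' @param result a `pipeline_result`.
#' @param dir output directory (created if missing).
#' @return The output directory, invisibly.
#' @export
write_outputs <- function(result, dir) {
  stopifnot(inherits(result, "pipeline_result"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  cols <- intersect(patient_csv_columns(), names(result$table))
  utils::write.csv(result$table[, cols], file.path(dir, "patients.csv"),
                   row.names = FALSE)
  summary <- result$summary
  summary$deviation <- unclass(summary$deviation)
  jsonlite::write_json(unclass(summary), file.path(dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, na = "null",
                       dataframe = "rows", pretty = TRUE)
  jsonlite::write_json(result$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  log_lines <- c(
    sprintf("cardioage %s", result$manifest$package_version),
    sprintf("seed %d | uploaded %d | parse failures %d | implausible %d | included %d",
            result$manifest$seed, result$manifest$uploaded,
            result$manifest$n_parse_failed, result$manifest$n_implausible,
            result$manifest$included),
    sprintf("success rate %.4f", result$manifest$success_rate),
    sprintf("AUC bioage %.4f | AUC chrono %.4f",
            result$summary$auc_bioage, result$summary$auc_chrono))
  writeLines(log_lines, file.path(dir, "run.log"))
  invisible(dir)
}
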