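#' Binary MACE labels under right censoring
#'
#' A patient is labelled 1 iff a MACE (death — cardiac or not —,
#' myocardial infarction, or late revascularization) occurred within the
#' follow-up window; otherwise 0 (censored event-free).
#'
#' @param records a `cohort` data.frame with `mace_event`,
#'   `mace_event_time` and `followup_time` columns.
#' @return Integer 0/1 vector, one per record.
#' @export
binary_labels <- function(records) {
  ev <- !is.na(records$mace_event) & records$mace_event != "none"
  as.integer(ev & !is.na(records$mace_event_time) &
               records$mace_event_time <= records$followup_time)
}

#' Area under the ROC curve (c-statistic)
#'
#' Mann-Whitney estimator: over all (positive, negative) pairs, a win
#' counts 1 and a tie 0.5; computed via midranks in O(n log n). Equals the
#' trapezoidal ROC area.
#'
#' @param scores numeric predictor values.
#' @param labels 0/1 outcome labels.
#' @return The c-statistic in `[0, 1]`.
#' @examples
#' auc(c(1, 2, 2, 3), c(0, 0, 1, 1)) # 0.875
#' @export
auc <- function(scores, labels) {
  stopifnot(length(scores) == length(labels))
  labels <- as.integer(labels)
  n1 <- sum(labels == 1)
  n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) {
    stop("AUC undefined: both outcome classes must be present")
  }
  r <- rank(scores)
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' DeLong confidence interval and test against chance discrimination
#'
#' Nonparametric structural-components (DeLong) variance of the
#' Mann-Whitney AUC, a Wald 95% confidence interval truncated to `[0, 1]`,
#' and a two-sided normal test of AUC = 0.5. With a degenerate variance
#' (for example perfect separation at small n) the p-value is 0 unless the
#' AUC is exactly 0.5.
#'
#' @param scores numeric predictor values.
#' @param labels 0/1 outcome labels; at least 2 per class.
#' @param conf_level confidence level (default 0.95).
#' @return List with `auc`, `ci` (length-2), `se`, `p_value`, `n_pos`,
#'   `n_neg`.
#' @export
auc_ci_and_test <- function(scores, labels, conf_level = 0.95) {
  labels <- as.integer(labels)
  m <- sum(labels == 1)
  n <- sum(labels == 0)
  if (m < 2 || n < 2) {
    stop("DeLong variance requires at least 2 observations per class")
  }
  x <- scores[labels == 1]
  y <- scores[labels == 0]
  r_all <- rank(c(x, y))
  v10 <- (r_all[seq_len(m)] - rank(x)) / n          # placements of positives
  v01 <- 1 - (r_all[m + seq_len(n)] - rank(y)) / m  # placements of negatives
  a <- mean(v10)
  s10 <- stats::var(v10)
  s01 <- stats::var(v01)
  se <- sqrt(s10 / m + s01 / n)
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  ci <- pmin(pmax(c(a - z * se, a + z * se), 0), 1)
  p <- if (se > 0) 2 * stats::pnorm(-abs(a - 0.5) / se) else as.numeric(a == 0.5)
  list(auc = a, ci = ci, se = se, p_value = p, n_pos = m, n_neg = n)
}

#' Deviation statistics between biological and chronological age
#'
#' Summaries of the intra-individual absolute deviation |bio - chrono|
#' (mean, SD, median, IQR with linearly interpolated quantiles) plus the
#' signed split: the fractions of patients whose biological age exceeds,
#' falls below, or equals their chronological age, and the signed mean/SD.
#'
#' @param bioages numeric vector of biological ages, years.
#' @param chrono_ages numeric vector of chronological ages, years.
#' @return List of class `deviation_stats`.
#' @export
deviation_stats <- function(bioages, chrono_ages) {
  stopifnot(length(bioages) == length(chrono_ages))
  d <- bioages - chrono_ages
  ad <- abs(d)
  q <- stats::quantile(ad, c(0.25, 0.75), type = 7, names = FALSE)
  structure(list(
    mean_abs = mean(ad),
    sd_abs = stats::sd(ad),
    median_abs = stats::median(ad),
    iqr_abs = q[2] - q[1],
    fraction_bio_exceeds_chrono = mean(d > 0),
    fraction_bio_below_chrono = mean(d < 0),
    fraction_equal = mean(d == 0),
    mean_signed = mean(d),
    sd_signed = stats::sd(d),
    n = length(d)
  ), class = "deviation_stats")
}

auc_row <- function(scores, labels) {
  ok <- tryCatch(auc_ci_and_test(scores, labels), error = function(e) NULL)
  if (is.null(ok)) {
    list(auc = NA_real_, ci_lo = NA_real_, ci_hi = NA_real_,
         p = NA_real_, defined = FALSE)
  } else {
    list(auc = ok$auc, ci_lo = ok$ci[1], ci_hi = ok$ci[2],
         p = ok$p_value, defined = TRUE)
  }
}

#' Cumulative batch-consistency analysis
#'
#' For each batch size k, evaluates AUC/CI/p for the biological and the
#' chronological age on the first k records in cohort order (cumulative
#' prefixes, matching batch Ns that grow toward the full cohort); the
#' final row equals the full-cohort analysis exactly. Prefixes with a
#' single outcome class are flagged undefined rather than erroring.
#'
#' @param bioages,chrono_ages,labels aligned per-patient vectors.
#' @param batch_sizes integer vector of prefix sizes.
#' @param cumulative if `FALSE`, evaluate disjoint consecutive groups of
#'   the given sizes instead of cumulative prefixes.
#' @return data.frame with one row per batch: `n`, AUC/CI/p for both
#'   predictors, `n_events`, `event_rate`, `defined`.
#' @export
batch_consistency <- function(bioages, chrono_ages, labels, batch_sizes,
                              cumulative = TRUE) {
  stopifnot(all(batch_sizes >= 1), all(batch_sizes <= length(labels)))
  start <- 1L
  rows <- lapply(seq_along(batch_sizes), function(b) {
    k <- batch_sizes[b]
    idx <- if (cumulative) seq_len(k) else seq.int(start, start + k - 1L)
    if (!cumulative) start <<- start + k
    bio <- auc_row(bioages[idx], labels[idx])
    chr <- auc_row(chrono_ages[idx], labels[idx])
    data.frame(
      n = length(idx),
      auc_bioage = bio$auc, ci_lo_bioage = bio$ci_lo, ci_hi_bioage = bio$ci_hi,
      p_bioage = bio$p,
      auc_chrono = chr$auc, ci_lo_chrono = chr$ci_lo, ci_hi_chrono = chr$ci_hi,
      p_chrono = chr$p,
      n_events = sum(labels[idx]), event_rate = mean(labels[idx]),
      defined = bio$defined && chr$defined
    )
  })
  do.call(rbind, rows)
}

#' Full discrimination and deviation evaluation of a scored cohort
#'
#' Computes MACE discrimination (ROC AUC with DeLong 95% CI and the test
#' against AUC = 0.5) for biological vs chronological age, the deviation
#' statistics, and optionally the cumulative batch-consistency table.
#'
#' @param bioages,chrono_ages,labels aligned vectors over the included
#'   patients.
#' @param batch_sizes optional integer vector for [batch_consistency()].
#' @return List of class `eval_summary` with `n_included`, `n_events`,
#'   `event_rate`, `auc_bioage`, `ci95_bioage`, `p_bioage`, `auc_chrono`,
#'   `ci95_chrono`, `p_chrono`, `deviation` and `batch_table`.
#' @export
evaluate_cohort <- function(bioages, chrono_ages, labels, batch_sizes = NULL) {
  stopifnot(length(bioages) == length(labels),
            length(chrono_ages) == length(labels))
  bio <- auc_ci_and_test(bioages, labels)
  chr <- auc_ci_and_test(chrono_ages, labels)
  dev <- deviation_stats(bioages, chrono_ages)
  batch <- if (!is.null(batch_sizes)) {
    batch_consistency(bioages, chrono_ages, labels, batch_sizes)
  } else NULL
  structure(list(
    n_included = length(labels),
    n_events = sum(as.integer(labels)),
    event_rate = mean(as.integer(labels)),
    auc_bioage = bio$auc, ci95_bioage = bio$ci, p_bioage = bio$p_value,
    auc_chrono = chr$auc, ci95_chrono = chr$ci, p_chrono = chr$p_value,
    deviation = dev,
    batch_table = batch
  ), class = "eval_summary")
}

#' @export
print.eval_summary <- function(x, ...) {
  cat(sprintf("MACE discrimination (n = %d, %d events, rate %.3f)\n",
              x$n_included, x$n_events, x$event_rate))
  cat(sprintf("  BioAGE:     AUC %.3f (95%% CI %.3f-%.3f), p = %.3g\n",
              x$auc_bioage, x$ci95_bioage[1], x$ci95_bioage[2], x$p_bioage))
  cat(sprintf("  ChronoAGE:  AUC %.3f (95%% CI %.3f-%.3f), p = %.3g\n",
              x$auc_chrono, x$ci95_chrono[1], x$ci95_chrono[2], x$p_chrono))
  cat(sprintf("  |bio - chrono|: mean %.2f +/- %.2f, median %.2f, IQR %.2f\n",
              x$deviation$mean_abs, x$deviation$sd_abs,
              x$deviation$median_abs, x$deviation$iqr_abs))
  cat(sprintf("  bio > chrono in %.1f%% of patients\n",
              100 * x$deviation$fraction_bio_exceeds_chrono))
  if (!is.null(x$batch_table)) {
    cat("  batch consistency:\n")
    print(x$batch_table[, c("n", "auc_bioage", "auc_chrono", "n_events")],
          row.names = FALSE)
  }
  invisible(x)
}
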