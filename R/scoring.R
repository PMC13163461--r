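#' Configuration of the biological cardiovascular age score
#'
#' The score is an additive points system on top of a CAC-based base age:
#' `base = intercept + slope * CAC`, plus fixed year increments for the
#' CAD-RADS stenosis category, multivessel disease, a proximal LAD lesion
#' > 70%, soft plaque confined to RCA/CX, impaired LV function
#' (LVEF below threshold or elevated EDV/ESV, applied once), and any
#' extracoronary finding (aortic ectasia/aneurysm and the like, applied
#' once). Totals outside `[plausible_min, plausible_max]` are flagged
#' implausible and excluded from downstream evaluation.
#'
#' The EDV/ESV elevation thresholds and the extracoronary increment have no
#' published magnitude; the defaults (200 mL, 90 mL, +5 years) are package
#' choices and fully configurable.
#'
#' @param cac_base_intercept base age in years at CAC = 0 (default 39).
#' @param cac_slope years of age per Agatston unit (default 0.1).
#' @param increment_cadrads2,increment_cadrads3,increment_cadrads4a,increment_cadrads4b,increment_cadrads5
#'   category increments in years (defaults 5, 10, 15, 20, 20; categories 0
#'   and 1 add nothing).
#' @param increment_multivessel years added when all of LAD, RCA and CX have
#'   a > 50% stenosis (default 15).
#' @param increment_proximal_lad years for a proximal LAD lesion > 70%
#'   (default 10).
#' @param increment_soft_plaque_rca_cx years for soft plaque confined to
#'   RCA/CX (default 5).
#' @param increment_low_lvef_or_elevated_volumes years for impaired LV
#'   function (default 10, applied once).
#' @param lvef_threshold LVEF percent threshold, strict `<` (default 50).
#' @param edv_elevated_threshold,esv_elevated_threshold volume thresholds in
#'   mL, strict `>` (defaults 200, 90); absent volumes never trigger.
#' @param increment_extracoronary years when any extracoronary finding is
#'   present (default 5, applied once).
#' @param plausible_min,plausible_max plausibility bounds in years
#'   (defaults 25, 105).
#' @param rounding `"nearest_integer"` (default, used for the displayed age
#'   only) or `"none"`.
#' @return An object of class `scoring_config`.
#' @export
scoring_config <- function(cac_base_intercept = 39,
                           cac_slope = 0.1,
                           increment_cadrads2 = 5,
                           increment_cadrads3 = 10,
                           increment_cadrads4a = 15,
                           increment_cadrads4b = 20,
                           increment_cadrads5 = 20,
                           increment_multivessel = 15,
                           increment_proximal_lad = 10,
                           increment_soft_plaque_rca_cx = 5,
                           increment_low_lvef_or_elevated_volumes = 10,
                           lvef_threshold = 50,
                           edv_elevated_threshold = 200,
                           esv_elevated_threshold = 90,
                           increment_extracoronary = 5,
                           plausible_min = 25,
                           plausible_max = 105,
                           rounding = c("nearest_integer", "none")) {
  rounding <- match.arg(rounding)
  cfg <- structure(as.list(environment()), class = "scoring_config")
  incs <- unlist(cfg[grep("^increment_", names(cfg))])
  if (any(!is.finite(incs)) || any(incs < 0)) {
    stop("all increments must be finite and >= 0")
  }
  if (!is.finite(cfg$cac_slope) || cfg$cac_slope < 0) {
    stop("cac_slope must be >= 0")
  }
  if (!(cfg$plausible_min < cfg$plausible_max)) {
    stop("plausible_min must be smaller than plausible_max")
  }
  cfg
}

cadrads_increment_vector <- function(config) {
  c("0" = 0, "1" = 0,
    "2" = config$increment_cadrads2,
    "3" = config$increment_cadrads3,
    "4a" = config$increment_cadrads4a,
    "4b" = config$increment_cadrads4b,
    "5" = config$increment_cadrads5)
}

#' CAC-based base component of the biological age
#'
#' Linear approximation `intercept + slope * CAC` mapping the Agatston
#' calcium score to a base age in years (39 years at CAC 0 under defaults).
#'
#' @param cac_au Agatston score, >= 0.
#' @param config a [scoring_config()].
#' @return Base age in years.
#' @examples
#' cac_component(215.3) # 60.53
#' @export
cac_component <- function(cac_au, config = scoring_config()) {
  if (any(!is.finite(cac_au)) || any(cac_au < 0)) {
    stop("cac_au must be a finite non-negative Agatston value")
  }
  config$cac_base_intercept + config$cac_slope * cac_au
}

ledger_entry <- function(rule, years) {
  data.frame(rule = rule, years = years, stringsAsFactors = FALSE)
}

empty_ledger <- function() {
  data.frame(rule = character(), years = numeric(), stringsAsFactors = FALSE)
}

#' Stenosis severity and high-risk anatomy increments
#'
#' Adds the CAD-RADS category increment (categories 2-5; 0 and 1 add
#' nothing) plus, stacking additively: +15 years when all three major
#' vessels (LAD, RCA, CX) carry a > 50% stenosis, +10 years for a proximal
#' LAD lesion > 70%, and +5 years for soft plaque confined to RCA/CX.
#'
#' @param metrics a `key_metrics` object.
#' @param config a [scoring_config()].
#' @return List with `years` (total) and `ledger` (data.frame of applied
#'   rules).
#' @export
stenosis_increment <- function(metrics, config = scoring_config()) {
  validate_key_metrics(metrics)
  ledger <- empty_ledger()
  cat_inc <- unname(cadrads_increment_vector(config)[metrics$cadrads])
  if (cat_inc > 0) {
    ledger <- rbind(ledger, ledger_entry(paste0("cadrads_", metrics$cadrads), cat_inc))
  }
  if (all(.VESSELS %in% metrics$vessel_over50)) {
    ledger <- rbind(ledger, ledger_entry("multivessel", config$increment_multivessel))
  }
  if (metrics$proximal_lad_over70) {
    ledger <- rbind(ledger, ledger_entry("proximal_lad", config$increment_proximal_lad))
  }
  if (metrics$soft_plaque_rca_cx_only) {
    ledger <- rbind(ledger,
                    ledger_entry("soft_plaque_rca_cx", config$increment_soft_plaque_rca_cx))
  }
  list(years = sum(ledger$years), ledger = ledger)
}

#' Functional (LV) increment
#'
#' +10 years (once, under defaults) when LVEF is strictly below the
#' threshold OR EDV/ESV is strictly above its elevation threshold. Absent
#' volumes never trigger.
#'
#' @inheritParams stenosis_increment
#' @return List with `years` and `ledger`.
#' @export
function_increment <- function(metrics, config = scoring_config()) {
  validate_key_metrics(metrics)
  impaired <- metrics$lvef_percent < config$lvef_threshold ||
    (is.finite(metrics$edv_ml) && metrics$edv_ml > config$edv_elevated_threshold) ||
    (is.finite(metrics$esv_ml) && metrics$esv_ml > config$esv_elevated_threshold)
  if (impaired) {
    inc <- config$increment_low_lvef_or_elevated_volumes
    list(years = inc, ledger = ledger_entry("low_lvef_or_elevated_volumes", inc))
  } else {
    list(years = 0, ledger = empty_ledger())
  }
}

#' Extracoronary increment
#'
#' A single increment (default +5 years) when any coded extracoronary
#' finding (aortic ectasia, aortic aneurysm, other) is present, regardless
#' of how many.
#'
#' @inheritParams stenosis_increment
#' @return List with `years` and `ledger`.
#' @export
extracoronary_increment <- function(metrics, config = scoring_config()) {
  validate_key_metrics(metrics)
  if (length(metrics$extracoronary_findings) > 0) {
    inc <- config$increment_extracoronary
    list(years = inc, ledger = ledger_entry("extracoronary", inc))
  } else {
    list(years = 0, ledger = empty_ledger())
  }
}

# Nearest-integer rounding with halves away from zero, so a displayed age is
# independent of the platform's banker's rounding.
round_half_up <- function(x) floor(x + 0.5)

#' Compose the biological cardiovascular age estimate
#'
#' Assembles the full estimate: CAC base component plus stenosis,
#' functional and extracoronary increments, a complete per-rule ledger, the
#' rounded display age, the deviation from chronological age, and the
#' plausibility verdict.
#'
#' @param metrics a `key_metrics` object with all three key metrics present.
#' @param chrono_age chronological age in years (`NA` allowed; the deviation
#'   is then `NA`).
#' @param config a [scoring_config()].
#' @return An object of class `bioage_estimate`: a list with `base_years`,
#'   `increment_ledger`, `total_years`, `display_years`, `deviation_years`,
#'   `plausible` and `failure_reason`.
#' @examples
#' m <- key_metrics(cac_au = 215.3, cadrads = "3", lvef_percent = 77)
#' compose_bioage(m, chrono_age = 66)
#' @export
compose_bioage <- function(metrics, chrono_age = NA_real_,
                           config = scoring_config()) {
  validate_key_metrics(metrics)
  base <- cac_component(metrics$cac_au, config)
  sten <- stenosis_increment(metrics, config)
  fun <- function_increment(metrics, config)
  extra <- extracoronary_increment(metrics, config)
  ledger <- rbind(sten$ledger, fun$ledger, extra$ledger)
  total <- base + sum(ledger$years)
  display <- if (config$rounding == "nearest_integer") round_half_up(total) else total
  plausible <- total >= config$plausible_min && total <= config$plausible_max
  failure <- if (plausible) {
    NA_character_
  } else if (total > config$plausible_max) "implausible_high" else "implausible_low"
  structure(
    list(
      base_years = base,
      increment_ledger = ledger,
      total_years = total,
      display_years = display,
      deviation_years = total - as.numeric(chrono_age),
      chrono_age = as.numeric(chrono_age),
      plausible = plausible,
      failure_reason = failure
    ),
    class = "bioage_estimate"
  )
}

#' @export
print.bioage_estimate <- function(x, ...) {
  cat("Biological cardiovascular age estimate\n")
  cat(sprintf("  base (CAC):  %.2f years\n", x$base_years))
  if (nrow(x$increment_ledger)) {
    for (i in seq_len(nrow(x$increment_ledger))) {
      cat(sprintf("  + %-28s %+.1f years\n",
                  x$increment_ledger$rule[i], x$increment_ledger$years[i]))
    }
  }
  cat(sprintf("  total: %.2f years (display %d)\n", x$total_years,
              as.integer(x$display_years)))
  if (is.finite(x$deviation_years)) {
    cat(sprintf("  deviation from chronological age: %+.2f years\n",
                x$deviation_years))
  }
  if (!x$plausible) cat("  IMPLAUSIBLE (", x$failure_reason, ")\n", sep = "")
  invisible(x)
}

#' Plausibility check of a composed estimate
#'
#' Estimates whose total falls outside the configured bounds are treated as
#' scoring failures (e.g. 123 or 17 years): they are excluded from
#' evaluation but still count in the success-rate denominator.
#'
#' @param estimate a `bioage_estimate` (or a bare total in years).
#' @param config a [scoring_config()].
#' @return List with `pass` (logical) and `reason`
#'   (`"implausible_low"`/`"implausible_high"` or `NA`).
#' @export
plausibility_check <- function(estimate, config = scoring_config()) {
  total <- if (inherits(estimate, "bioage_estimate")) estimate$total_years else as.numeric(estimate)
  if (total < config$plausible_min) {
    list(pass = FALSE, reason = "implausible_low")
  } else if (total > config$plausible_max) {
    list(pass = FALSE, reason = "implausible_high")
  } else {
    list(pass = TRUE, reason = NA_character_)
  }
}

# Vectorized total over flattened metric columns; used by the cohort
# generator and the pipeline scorer. Must agree exactly with
# compose_bioage() (property-tested).
bioage_total_vec <- function(cac_au, cadrads, vessel_over50, proximal_lad_over70,
                             soft_plaque_rca_cx_only, lvef_percent,
                             edv_ml, esv_ml, extracoronary_findings,
                             config = scoring_config()) {
  base <- config$cac_base_intercept + config$cac_slope * cac_au
  inc <- unname(cadrads_increment_vector(config)[as.character(cadrads)])
  multi <- vapply(vessel_over50,
                  function(v) all(.VESSELS %in% split_set(v)), logical(1),
                  USE.NAMES = FALSE)
  impaired <- lvef_percent < config$lvef_threshold |
    (!is.na(edv_ml) & edv_ml > config$edv_elevated_threshold) |
    (!is.na(esv_ml) & esv_ml > config$esv_elevated_threshold)
  extra <- nzchar(ifelse(is.na(extracoronary_findings), "", extracoronary_findings))
  base + inc +
    config$increment_multivessel * multi +
    config$increment_proximal_lad * as.logical(proximal_lad_over70) +
    config$increment_soft_plaque_rca_cx * as.logical(soft_plaque_rca_cx_only) +
    config$increment_low_lvef_or_elevated_volumes * impaired +
    config$increment_extracoronary * extra
}
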