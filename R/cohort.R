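#' Configuration of the synthetic cohort generator
#'
#' Defaults emulate the published cohort profile of a single-centre
#' symptomatic chest-pain population referred for coronary CTA:
#' chronological age 58.5 +/- 10.8 years truncated to 25-81, 39.6% women,
#' CAD-RADS marginal distribution 20.2 / 15.9 / 31.2 / 16.7 / 15.9%
#' (categories 4a/4b/5 split 8.0 / 5.0 / 2.9), mean CAC 108.6 AU with a
#' heavy right tail capped at 24,328, LVEF 69.7 +/- 9.7 truncated to 23-86,
#' 25.4% high-risk plaque, follow-up centred on 4.2 years within a 2-6 year
#' window, and a MACE process auto-calibrated to an 8.7% event rate.
#'
#' A latent atherosclerosis severity, correlated with chronological age via
#' a Gaussian copula (`severity_age_rho`), drives the CAD-RADS draw (cut
#' points at the category quantiles, so the marginal is exact), the
#' stratum-wise zero-inflated log-normal CAC, and the high-risk plaque
#' indicator. The stratum log-means are derived from `cac_target_mean` at
#' construction time so that the expected CAC equals the target
#' analytically; pass `cac_lognormal_params` to override.
#'
#' @param n_patients cohort size (default 346).
#' @param seed integer RNG seed.
#' @param chrono_age_mean,chrono_age_sd,chrono_age_min,chrono_age_max
#'   truncated-normal age model, years.
#' @param female_fraction proportion of women.
#' @param cadrads_probs length-7 probability vector over
#'   `cadrads_levels()`; must sum to 1.
#' @param cac_zero_prob_by_cadrads probability of CAC = 0 per category.
#' @param cac_lognormal_params 7 x 2 matrix (meanlog, sdlog) of the
#'   non-zero CAC distribution per category, or `NULL` to derive it from
#'   `cac_target_mean`.
#' @param cac_target_mean target expected CAC in AU (default 108.6).
#' @param cac_max hard cap on generated CAC (default 24328).
#' @param lvef_mean,lvef_sd,lvef_min,lvef_max truncated-normal LVEF model,
#'   percent.
#' @param lvef_shift_cadrads4plus additive LVEF shift (percent, usually
#'   <= 0) for CAD-RADS >= 4a; default 0 so the LVEF marginal is untouched.
#' @param hrp_prevalence marginal prevalence of high-risk plaque.
#' @param hrp_severity_rho copula correlation of HRP with the latent
#'   severity.
#' @param severity_age_rho copula correlation of severity with age.
#' @param multivessel_prob_given_cadrads4plus probability that a CAD-RADS
#'   >= 4a patient has all three vessels > 50%.
#' @param proximal_lad_prob_given_cadrads4plus probability of a proximal
#'   LAD lesion > 70% given CAD-RADS >= 4a.
#' @param soft_plaque_only_prob_given_cadrads12 probability of soft plaque
#'   confined to RCA/CX given CAD-RADS 1-2.
#' @param extracoronary_prob probability of any extracoronary finding.
#' @param followup_mean,followup_sd,followup_min,followup_max
#'   truncated-normal follow-up model, years.
#' @param mace_intercept logistic intercept; `NA` (default) requests
#'   auto-calibration to `target_event_rate`.
#' @param mace_slope_per_bioage_year logistic slope per year of true
#'   biological age. The default 0.035 is calibrated so the population ROC
#'   AUC of the true biological age for MACE is about 0.77 (with
#'   chronological age near 0.58), matching the discrimination the score is
#'   meant to emulate.
#' @param target_event_rate expected MACE rate used by auto-calibration.
#' @param parse_failure_rate fraction of reports rewritten into a
#'   parse-hostile variant by [inject_failures()]. The default 0.052
#'   emulates the text-level failure share of the study's 10.4% total
#'   failure rate (half text-level, half implausible scores); the
#'   implausible-score share arises naturally from the heavy CAC tail.
#' @param locale_mix proportion of German-language reports (default 1: the
#'   emulated study was all-German).
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(n_patients = 346,
                          seed = 1L,
                          chrono_age_mean = 58.5,
                          chrono_age_sd = 10.8,
                          chrono_age_min = 25,
                          chrono_age_max = 81,
                          female_fraction = 0.396,
                          cadrads_probs = c(0.202, 0.159, 0.312, 0.167,
                                            0.080, 0.050, 0.029) / 0.999,
                          cac_zero_prob_by_cadrads = c(0.85, 0.25, 0.10,
                                                       0.02, 0.01, 0.01, 0.01),
                          cac_lognormal_params = NULL,
                          cac_target_mean = 108.6,
                          cac_max = 24328,
                          lvef_mean = 69.7,
                          lvef_sd = 9.7,
                          lvef_min = 23,
                          lvef_max = 86,
                          lvef_shift_cadrads4plus = 0,
                          hrp_prevalence = 0.254,
                          hrp_severity_rho = 0.5,
                          severity_age_rho = 0.35,
                          multivessel_prob_given_cadrads4plus = 0.30,
                          proximal_lad_prob_given_cadrads4plus = 0.25,
                          soft_plaque_only_prob_given_cadrads12 = 0.15,
                          extracoronary_prob = 0.05,
                          followup_mean = 4.2,
                          followup_sd = 1.2,
                          followup_min = 2,
                          followup_max = 6,
                          mace_intercept = NA_real_,
                          mace_slope_per_bioage_year = 0.035,
                          target_event_rate = 0.087,
                          parse_failure_rate = 0.052,
                          locale_mix = 1.0) {
  cfg <- structure(as.list(environment()), class = "cohort_config")
  if (length(cfg$cadrads_probs) != 7 ||
      length(cfg$cac_zero_prob_by_cadrads) != 7) {
    stop("fields 'cadrads_probs' and 'cac_zero_prob_by_cadrads' must have length 7")
  }
  if (is.null(cfg$cac_lognormal_params)) {
    cfg$cac_lognormal_params <- derive_cac_lognormal_params(cfg)
  }
  validate_cohort_config(cfg)
}

# Relative severity profile of the mean non-zero CAC per CAD-RADS stratum;
# scaled so that the marginal E[CAC] equals cac_target_mean exactly.
.CAC_STRATUM_SHAPE <- c(5, 20, 70, 160, 320, 420, 550)
.CAC_SDLOG <- 1.1

derive_cac_lognormal_params <- function(cfg) {
  w <- cfg$cadrads_probs * (1 - cfg$cac_zero_prob_by_cadrads)
  scale <- cfg$cac_target_mean / sum(w * .CAC_STRATUM_SHAPE)
  meanlog <- log(scale * .CAC_STRATUM_SHAPE) - .CAC_SDLOG^2 / 2
  cbind(meanlog = meanlog, sdlog = rep(.CAC_SDLOG, 7))
}

#' Validate a cohort_config
#'
#' @param cfg a `cohort_config`.
#' @return `cfg` invisibly, or an error naming the offending field.
#' @export
validate_cohort_config <- function(cfg) {
  stopifnot(inherits(cfg, "cohort_config"))
  check_prop <- function(name) {
    v <- cfg[[name]]
    if (any(!is.finite(v)) || any(v < 0) || any(v > 1)) {
      stop("field '", name, "' must lie in [0, 1]")
    }
  }
  for (nm in c("female_fraction", "cadrads_probs", "cac_zero_prob_by_cadrads",
               "hrp_prevalence", "multivessel_prob_given_cadrads4plus",
               "proximal_lad_prob_given_cadrads4plus",
               "soft_plaque_only_prob_given_cadrads12", "extracoronary_prob",
               "target_event_rate", "parse_failure_rate", "locale_mix")) {
    check_prop(nm)
  }
  if (length(cfg$cadrads_probs) != 7 ||
      abs(sum(cfg$cadrads_probs) - 1) > 1e-9) {
    stop("field 'cadrads_probs' must be a 7-vector summing to 1")
  }
  if (cfg$n_patients < 1) stop("field 'n_patients' must be >= 1")
  if (!(cfg$chrono_age_min < cfg$chrono_age_max)) {
    stop("field 'chrono_age_min' must be smaller than chrono_age_max")
  }
  for (nm in c("chrono_age_sd", "lvef_sd", "followup_sd")) {
    if (!is.finite(cfg[[nm]]) || cfg[[nm]] <= 0) {
      stop("field '", nm, "' must be > 0")
    }
  }
  if (!is.matrix(cfg$cac_lognormal_params) ||
      !all(dim(cfg$cac_lognormal_params) == c(7, 2))) {
    stop("field 'cac_lognormal_params' must be a 7 x 2 (meanlog, sdlog) matrix")
  }
  if (!is.na(cfg$mace_slope_per_bioage_year) &&
      !is.finite(cfg$mace_slope_per_bioage_year)) {
    stop("field 'mace_slope_per_bioage_year' must be finite")
  }
  invisible(cfg)
}

# Inverse-CDF truncated normal draw from uniforms in (0,1).
qtruncnorm <- function(u, mean, sd, lo, hi) {
  plo <- stats::pnorm(lo, mean, sd)
  phi <- stats::pnorm(hi, mean, sd)
  stats::qnorm(plo + u * (phi - plo), mean, sd)
}

#' Generate a synthetic coronary CTA cohort
#'
#' Draws a seeded cohort of patients with the configured marginal structure
#' (age, sex, CAD-RADS, CAC, LV function, high-risk anatomy, extracoronary
#' findings, follow-up) and an age-coupled latent atherosclerosis severity,
#' computes each patient's true biological age via the scoring module, and
#' optionally renders each patient's structured report text.
#'
#' @param config a [cohort_config()].
#' @param render_text render German/English report text per patient
#'   (default `TRUE`; set `FALSE` for large calibration runs where only the
#'   numeric columns are needed).
#' @return A data.frame of class `cohort` with one row per patient:
#'   identifiers, demographics, flattened true metrics, `true_bioage`,
#'   follow-up, locale and (optionally) `report_text`.
#' @examples
#' coh <- generate_cohort(cohort_config(n_patients = 5, seed = 42))
#' coh$true_bioage
#' @export
generate_cohort <- function(config = cohort_config(), render_text = TRUE) {
  validate_cohort_config(config)
  set.seed(config$seed %% 2147483647L)
  n <- config$n_patients

  # Age via inverse CDF; its underlying uniform doubles as the standard
  # normal age signal of the severity copula.
  u_age <- stats::runif(n)
  chrono_age <- round(qtruncnorm(u_age, config$chrono_age_mean, config$chrono_age_sd,
                                 config$chrono_age_min, config$chrono_age_max), 1)
  z_age <- stats::qnorm(u_age)
  sex <- ifelse(stats::runif(n) < config$female_fraction, "female", "male")

  rho <- config$severity_age_rho
  severity <- rho * z_age + sqrt(1 - rho^2) * stats::rnorm(n)
  cuts <- stats::qnorm(cumsum(config$cadrads_probs)[-7])
  cat_idx <- findInterval(severity, cuts) + 1L
  cadrads <- .CADRADS[cat_idx]

  # zero-inflated log-normal CAC per stratum, capped
  zero <- stats::runif(n) < config$cac_zero_prob_by_cadrads[cat_idx]
  cac <- stats::rlnorm(n,
                       meanlog = config$cac_lognormal_params[cat_idx, 1],
                       sdlog = config$cac_lognormal_params[cat_idx, 2])
  cac <- round(pmin(ifelse(zero, 0, cac), config$cac_max), 1)

  rho_h <- config$hrp_severity_rho
  h <- rho_h * severity + sqrt(1 - rho_h^2) * stats::rnorm(n)
  hrp <- h > stats::qnorm(1 - config$hrp_prevalence)

  cad4p <- cat_idx >= 5L
  multivessel <- cad4p & stats::runif(n) < config$multivessel_prob_given_cadrads4plus
  proximal_lad <- cad4p & stats::runif(n) < config$proximal_lad_prob_given_cadrads4plus
  soft_plaque <- cat_idx %in% c(2L, 3L) &
    stats::runif(n) < config$soft_plaque_only_prob_given_cadrads12

  # vessels > 50%: none below CAD-RADS 3; one or two vessels at category 3;
  # one vessel (plus LAD if proximal lesion) or all three at >= 4a
  pick <- stats::runif(n)
  second <- stats::runif(n) < 0.3
  vessel_over50 <- character(n)
  for (i in seq_len(n)) {
    v <- character()
    if (cat_idx[i] == 4L) {
      v <- .VESSELS[ceiling(pick[i] * 3)]
      if (second[i]) v <- unique(c(v, .VESSELS[(match(v, .VESSELS) %% 3) + 1]))
    } else if (cat_idx[i] >= 5L) {
      v <- if (multivessel[i]) .VESSELS else .VESSELS[ceiling(pick[i] * 3)]
      if (proximal_lad[i]) v <- unique(c(v, "LAD"))
    }
    vessel_over50[i] <- paste(sort(v), collapse = ",")
  }

  lvef <- qtruncnorm(stats::runif(n), config$lvef_mean, config$lvef_sd,
                     config$lvef_min, config$lvef_max)
  lvef <- pmin(pmax(lvef + config$lvef_shift_cadrads4plus * cad4p,
                    config$lvef_min), config$lvef_max)
  lvef <- round(lvef)

  edv_mean <- ifelse(sex == "female", 120, 142)
  edv_sd <- ifelse(sex == "female", 21, 24)
  edv <- round(qtruncnorm(stats::runif(n), edv_mean, edv_sd, 60, 300))
  esv <- pmax(round(edv * (1 - lvef / 100)), 1)

  has_extra <- stats::runif(n) < config$extracoronary_prob
  extra_type <- sample(.EXTRACORONARY, n, replace = TRUE,
                       prob = c(0.7, 0.2, 0.1))
  extracoronary <- ifelse(has_extra, extra_type, "")

  followup <- round(qtruncnorm(stats::runif(n), config$followup_mean,
                               config$followup_sd, config$followup_min,
                               config$followup_max), 2)
  locale <- ifelse(stats::runif(n) < config$locale_mix, "de", "en")
  style_seed <- sample.int(1e6L, n, replace = TRUE)

  true_bioage <- bioage_total_vec(
    cac_au = cac, cadrads = cadrads, vessel_over50 = vessel_over50,
    proximal_lad_over70 = proximal_lad, soft_plaque_rca_cx_only = soft_plaque,
    lvef_percent = lvef, edv_ml = edv, esv_ml = esv,
    extracoronary_findings = extracoronary
  )

  records <- data.frame(
    patient_id = sprintf("P%05d", seq_len(n)),
    chrono_age = chrono_age,
    sex = sex,
    locale = locale,
    cac_au = cac,
    cadrads = cadrads,
    vessel_over50 = vessel_over50,
    proximal_lad_over70 = proximal_lad,
    soft_plaque_rca_cx_only = soft_plaque,
    hrp_present = hrp,
    lvef_percent = lvef,
    edv_ml = edv,
    esv_ml = esv,
    extracoronary_findings = extracoronary,
    true_bioage = true_bioage,
    followup_time = followup,
    style_seed = style_seed,
    stringsAsFactors = FALSE
  )
  if (render_text) {
    records$report_text <- vapply(seq_len(n), function(i) {
      render_report(metrics_from_row(records[i, ]),
                    locale = records$locale[i],
                    style_seed = records$style_seed[i])
    }, character(1))
  }
  class(records) <- c("cohort", "data.frame")
  records
}

#' Calibrate the MACE logistic intercept to a target event rate
#'
#' Solves the intercept so that the mean predicted event probability over
#' the realized true biological ages equals the target rate.
#'
#' @param bioage numeric vector of true biological ages.
#' @param slope logistic slope per year.
#' @param target_rate target expected event rate.
#' @return The calibrated intercept.
#' @export
calibrate_mace_intercept <- function(bioage, slope, target_rate) {
  if (!is.finite(slope)) stop("mace slope must be finite")
  if (target_rate <= 0 || target_rate >= 1) {
    stop("target_event_rate must lie in (0, 1)")
  }
  f <- function(b0) mean(stats::plogis(b0 + slope * bioage)) - target_rate
  stats::uniroot(f, interval = c(-200, 200), tol = 1e-10)$root
}

#' Simulate right-censored MACE outcomes
#'
#' Draws a binary MACE indicator from a logistic model on the true
#' biological age, assigns the event type from the fixed 2:5:22
#' death / myocardial infarction / late revascularization composition, and
#' places the event time uniformly within the patient's follow-up window.
#' With `mace_intercept = NA` the intercept is auto-calibrated so the
#' expected event rate matches `target_event_rate`.
#'
#' @param records a `cohort` data.frame carrying `true_bioage` and
#'   `followup_time`.
#' @param config the [cohort_config()] used to generate the cohort.
#' @return The records with `mace_event` (`"none"`, `"death"`,
#'   `"myocardial_infarction"`, `"late_revascularization"`) and
#'   `mace_event_time` columns.
#' @export
simulate_mace <- function(records, config = cohort_config()) {
  if (is.null(records$true_bioage)) {
    stop("records must carry a true_bioage column")
  }
  slope <- config$mace_slope_per_bioage_year
  if (!is.finite(slope)) stop("mace slope must be finite")
  b0 <- config$mace_intercept
  if (is.na(b0)) {
    b0 <- calibrate_mace_intercept(records$true_bioage, slope,
                                   config$target_event_rate)
  } else if (!is.finite(b0)) {
    stop("mace_intercept must be finite or NA for auto-calibration")
  }
  set.seed((config$seed + 101L) %% 2147483647L)
  n <- nrow(records)
  p <- stats::plogis(b0 + slope * records$true_bioage)
  event <- stats::runif(n) < p
  type <- sample(c("death", "myocardial_infarction", "late_revascularization"),
                 n, replace = TRUE, prob = c(2, 5, 22) / 29)
  records$mace_event <- ifelse(event, type, "none")
  records$mace_event_time <- ifelse(
    event, round(stats::runif(n) * records$followup_time, 3), NA_real_)
  # event time in (0, followup]; guard the measure-zero zero draw
  records$mace_event_time <- ifelse(
    !is.na(records$mace_event_time) & records$mace_event_time == 0,
    0.001, records$mace_event_time)
  attr(records, "mace_intercept") <- b0
  records
}
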