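test_that("cohort generation is deterministic under a fixed seed", {
  cfg <- cohort_config(n_patients = 80, seed = 5)
  a <- simulate_mace(inject_failures(generate_cohort(cfg), cfg), cfg)
  b <- simulate_mace(inject_failures(generate_cohort(cfg), cfg), cfg)
  expect_identical(a, b)
  c2 <- generate_cohort(cohort_config(n_patients = 80, seed = 6))
  expect_false(identical(a$cac_au, c2$cac_au))
})

test_that("config validation names the offending field", {
  expect_error(cohort_config(female_fraction = 1.4), "female_fraction")
  expect_error(cohort_config(cadrads_probs = rep(1 / 6, 6)), "cadrads_probs")
  expect_error(cohort_config(n_patients = 0), "n_patients")
  expect_error(cohort_config(chrono_age_min = 90), "chrono_age_min")
  expect_error(cohort_config(followup_sd = 0), "followup_sd")
})

test_that("generated records satisfy the structural invariants", {
  cfg <- cohort_config(n_patients = 500, seed = 17)
  coh <- simulate_mace(generate_cohort(cfg, render_text = FALSE), cfg)
  expect_true(all(coh$chrono_age >= cfg$chrono_age_min &
                    coh$chrono_age <= cfg$chrono_age_max))
  expect_true(all(coh$lvef_percent >= cfg$lvef_min &
                    coh$lvef_percent <= cfg$lvef_max))
  expect_true(all(coh$esv_ml < coh$edv_ml))
  expect_true(all(coh$cac_au >= 0 & coh$cac_au <= cfg$cac_max))
  # event time present iff an event occurred, and inside follow-up
  has_event <- coh$mace_event != "none"
  expect_identical(has_event, !is.na(coh$mace_event_time))
  expect_true(all(coh$mace_event_time[has_event] > 0))
  expect_true(all(coh$mace_event_time[has_event] <=
                    coh$followup_time[has_event]))
  # obstructive categories carry at least one qualifying lesion
  obstr <- coh$cadrads %in% c("4a", "4b", "5")
  expect_true(all(nzchar(coh$vessel_over50[obstr]) |
                    coh$proximal_lad_over70[obstr]))
  # soft plaque never coexists with a > 50% LAD lesion
  expect_false(any(coh$soft_plaque_rca_cx_only &
                     grepl("LAD", coh$vessel_over50)))
})

test_that("marginals track the configured cohort profile", {
  cfg <- cohort_config(n_patients = 20000, seed = 29)
  coh <- generate_cohort(cfg, render_text = FALSE)
  n <- nrow(coh)
  se <- function(p) sqrt(p * (1 - p) / n)
  expect_lt(abs(mean(coh$sex == "female") - cfg$female_fraction),
            3 * se(cfg$female_fraction))
  expect_lt(abs(mean(coh$hrp_present) - cfg$hrp_prevalence),
            3 * se(cfg$hrp_prevalence))
  emp <- prop.table(table(factor(coh$cadrads, cadrads_levels())))
  for (k in 1:7) {
    expect_lt(abs(emp[k] - cfg$cadrads_probs[k]), 3 * se(cfg$cadrads_probs[k]))
  }
  expect_lt(abs(mean(coh$lvef_percent) -
                  truncnorm_mean(cfg$lvef_mean, cfg$lvef_sd,
                                 cfg$lvef_min, cfg$lvef_max)),
            3 * cfg$lvef_sd / sqrt(n) + 0.3) # + integer rounding slack
  # severity coupling: CAC and CAD-RADS rank increase with age tertile
  expect_gt(cor(cadrads_rank(coh$cadrads), coh$chrono_age), 0.15)
})

test_that("MACE simulation hits the configured logistic rates", {
  cfg0 <- cohort_config(n_patients = 20000, seed = 37,
                        mace_slope_per_bioage_year = 0,
                        mace_intercept = stats::qlogis(0.087))
  coh <- simulate_mace(generate_cohort(cfg0, render_text = FALSE), cfg0)
  rate <- mean(coh$mace_event != "none")
  expect_lt(abs(rate - 0.087), 3 * sqrt(0.087 * 0.913 / 20000) + 0.001)

  # auto-calibration agrees with an independent root-finder
  cfg1 <- cohort_config(n_patients = 5000, seed = 37, target_event_rate = 0.10)
  coh1 <- generate_cohort(cfg1, render_text = FALSE)
  got <- calibrate_mace_intercept(coh1$true_bioage,
                                  cfg1$mace_slope_per_bioage_year, 0.10)
  f <- function(b0) mean(stats::plogis(b0 + cfg1$mace_slope_per_bioage_year *
                                         coh1$true_bioage)) - 0.10
  lo <- -60; hi <- 60
  for (i in 1:200) { # bisection oracle
    mid <- (lo + hi) / 2
    if (f(mid) > 0) hi <- mid else lo <- mid
  }
  expect_equal(got, (lo + hi) / 2, tolerance = 1e-6)
  expect_error(simulate_mace(coh1, cohort_config(mace_intercept = Inf)),
               "intercept")
})

test_that("event types follow the 2:5:22 composition", {
  cfg <- cohort_config(n_patients = 30000, seed = 41)
  coh <- simulate_mace(generate_cohort(cfg, render_text = FALSE), cfg)
  tt <- table(coh$mace_event[coh$mace_event != "none"])
  props <- prop.table(tt)[c("death", "myocardial_infarction",
                            "late_revascularization")]
  expect_equal(unname(as.vector(props)), c(2, 5, 22) / 29, tolerance = 0.15)
})

test_that("failure injection respects the rate and breaks parsing as tagged", {
  cfg <- cohort_config(n_patients = 120, seed = 43, parse_failure_rate = 0)
  coh <- generate_cohort(cfg)
  coh0 <- inject_failures(coh, cfg)
  expect_identical(coh0$report_text, coh$report_text)
  expect_true(all(is.na(coh0$injected_failure)))

  cfg2 <- cohort_config(n_patients = 400, seed = 43, parse_failure_rate = 0.5)
  coh2 <- inject_failures(generate_cohort(cfg2), cfg2)
  reason_by_mode <- c(cadrads_deleted = "missing_cadrads",
                      einengung_synonym = "missing_cadrads",
                      cac_deleted = "missing_cac")
  for (mode in names(reason_by_mode)) {
    idx <- which(coh2$injected_failure == mode)
    expect_gt(length(idx), 0)
    for (i in idx[seq_len(min(10, length(idx)))]) {
      pr <- parse_report(coh2$report_text[i])
      expect_identical(pr$outcome, "failed")
      expect_identical(pr$failure_reason, unname(reason_by_mode[mode]))
    }
  }
  intact <- which(is.na(coh2$injected_failure))
  for (i in intact[seq_len(min(10, length(intact)))]) {
    expect_identical(parse_report(coh2$report_text[i])$outcome, "parsed")
  }
})

test_that("the discrimination signal lives in the biological age", {
  set.seed(47)
  res <- t(vapply(1:30, function(s) {
    cfg <- cohort_config(n_patients = 346, seed = 7000 + s)
    coh <- simulate_mace(generate_cohort(cfg, render_text = FALSE), cfg)
    lab <- binary_labels(coh)
    c(auc(coh$true_bioage, lab), auc(coh$chrono_age, lab))
  }, numeric(2)))
  expect_gt(stats::median(res[, 1]), 0.5)
  expect_gt(stats::median(res[, 1]), stats::median(res[, 2]))
})
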