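test_that("CAC base component follows the linear approximation", {
  expect_equal(cac_component(0), 39)
  expect_equal(cac_component(215.3), 60.53)
  expect_equal(cac_component(24328), 2471.8)
  expect_error(cac_component(-1), "non-negative")
})

test_that("stenosis increments stack additively over rule families", {
  cfg <- scoring_config()
  m0 <- key_metrics(0, "0", 60)
  expect_equal(stenosis_increment(m0, cfg)$years, 0)
  m1 <- key_metrics(0, "1", 60)
  expect_equal(stenosis_increment(m1, cfg)$years, 0)
  m3 <- key_metrics(0, "3", 60)
  expect_equal(stenosis_increment(m3, cfg)$years, 10)
  m2 <- key_metrics(0, "2", 60)
  expect_equal(stenosis_increment(m2, cfg)$years, 5)
  # category + multivessel + proximal LAD stack: 15 + 15 + 10
  m4 <- key_metrics(0, "4a", 60, vessel_over50 = c("LAD", "RCA", "CX"),
                    proximal_lad_over70 = TRUE)
  out <- stenosis_increment(m4, cfg)
  expect_equal(out$years, 40)
  expect_setequal(out$ledger$rule, c("cadrads_4a", "multivessel", "proximal_lad"))
  msoft <- key_metrics(0, "1", 60, soft_plaque_rca_cx_only = TRUE)
  expect_equal(stenosis_increment(msoft, cfg)$years, 5)
})

test_that("functional increment uses strict thresholds and applies once", {
  cfg <- scoring_config()
  expect_equal(function_increment(key_metrics(0, "0", 77), cfg)$years, 0)
  expect_equal(function_increment(key_metrics(0, "0", 45), cfg)$years, 10)
  expect_equal(function_increment(key_metrics(0, "0", 50), cfg)$years, 0)
  # both criteria true still adds 10 once
  both <- key_metrics(0, "0", 40, edv_ml = 250, esv_ml = 120)
  expect_equal(function_increment(both, cfg)$years, 10)
  # absent volumes never trigger
  expect_equal(function_increment(key_metrics(0, "0", 60), cfg)$years, 0)
  elevated_esv <- key_metrics(0, "0", 60, edv_ml = 150, esv_ml = 95)
  expect_equal(function_increment(elevated_esv, cfg)$years, 10)
})

test_that("extracoronary increment applies once regardless of finding count", {
  cfg <- scoring_config()
  expect_equal(extracoronary_increment(key_metrics(0, "0", 60), cfg)$years, 0)
  one <- key_metrics(0, "0", 60, extracoronary_findings = "aortic_ectasia")
  expect_equal(extracoronary_increment(one, cfg)$years, 5)
  two <- key_metrics(0, "0", 60,
                     extracoronary_findings = c("aortic_ectasia", "aortic_aneurysm"))
  expect_equal(extracoronary_increment(two, cfg)$years, 5)
})

test_that("composed estimates match hand-evaluated sums and round for display", {
  est <- compose_bioage(key_metrics(215.3, "3", 77), chrono_age = 66)
  expect_equal(est$total_years, 70.53)
  expect_equal(est$display_years, 71)
  expect_equal(est$deviation_years, 4.53)
  expect_true(est$plausible)

  est0 <- compose_bioage(key_metrics(0, "0", 77))
  expect_equal(est0$total_years, 39)

  est2 <- compose_bioage(key_metrics(100, "2", 40))
  expect_equal(est2$total_years, 64) # 39 + 10 + 5 + 10
})

test_that("ledger identity holds exactly for randomized metrics", {
  set.seed(42)
  for (i in 1:200) {
    m <- random_metrics()
    est <- compose_bioage(m, chrono_age = 60)
    expect_identical(est$total_years,
                     est$base_years + sum(est$increment_ledger$years))
    expect_identical(est$deviation_years, est$total_years - 60)
  }
})

test_that("composed total agrees with the brute-force rule evaluator", {
  set.seed(7)
  cfgs <- list(scoring_config(),
               scoring_config(increment_cadrads4b = 25, increment_extracoronary = 8,
                              lvef_threshold = 45, edv_elevated_threshold = 180))
  for (cfg in cfgs) {
    for (i in 1:500) {
      m <- random_metrics()
      expect_equal(compose_bioage(m, config = cfg)$total_years,
                   oracle_bioage(m, cfg))
    }
  }
})

test_that("vectorized scoring path equals the composed estimate", {
  cfg <- cohort_config(n_patients = 200, seed = 9)
  coh <- generate_cohort(cfg, render_text = FALSE)
  scalar <- vapply(seq_len(nrow(coh)), function(i) {
    compose_bioage(metrics_from_row(coh[i, ]))$total_years
  }, numeric(1))
  expect_equal(coh$true_bioage, scalar)
})

test_that("score is monotone in CAC, CAD-RADS order and flag flips", {
  base <- function(cac = 10, cadrads = "2", lvef = 60, ...) {
    compose_bioage(key_metrics(cac, cadrads, lvef, ...))$total_years
  }
  cacs <- c(0, 10, 100, 500, 5000)
  expect_true(all(diff(vapply(cacs, function(c) base(cac = c), numeric(1))) >= 0))

  by_cat <- vapply(cadrads_levels(), function(cr) {
    compose_bioage(key_metrics(10, cr, 60,
                               vessel_over50 = if (cr %in% c("4a", "4b", "5")) "RCA"
                               else character()))$total_years
  }, numeric(1))
  expect_true(all(diff(by_cat) >= 0))

  # any false -> true flag flip never decreases the total
  set.seed(11)
  for (i in 1:100) {
    m <- random_metrics()
    t0 <- compose_bioage(m)$total_years
    for (flag in c("proximal_lad_over70", "soft_plaque_rca_cx_only",
                   "hrp_present")) {
      if (m[[flag]]) next
      m2 <- m
      m2[[flag]] <- TRUE
      if (flag == "proximal_lad_over70") {
        m2$vessel_over50 <- sort(union(m2$vessel_over50, "LAD"))
        if (m2$soft_plaque_rca_cx_only) next
      }
      t1 <- tryCatch(compose_bioage(m2)$total_years, error = function(e) NA)
      if (!is.na(t1)) expect_gte(t1, t0)
    }
  }
})

test_that("zeroed increments and slope reduce the score to the intercept", {
  cfg <- scoring_config(cac_slope = 0, increment_cadrads2 = 0,
                        increment_cadrads3 = 0, increment_cadrads4a = 0,
                        increment_cadrads4b = 0, increment_cadrads5 = 0,
                        increment_multivessel = 0, increment_proximal_lad = 0,
                        increment_soft_plaque_rca_cx = 0,
                        increment_low_lvef_or_elevated_volumes = 0,
                        increment_extracoronary = 0)
  set.seed(13)
  for (i in 1:50) {
    expect_equal(compose_bioage(random_metrics(), config = cfg)$total_years, 39)
  }
})

test_that("plausibility filter rejects the documented failure ages", {
  expect_identical(plausibility_check(123),
                   list(pass = FALSE, reason = "implausible_high"))
  expect_identical(plausibility_check(17),
                   list(pass = FALSE, reason = "implausible_low"))
  expect_true(plausibility_check(57.2)$pass)
  # a maximal-range CAC is implausible after composition
  est <- compose_bioage(key_metrics(24328, "0", 77))
  expect_false(est$plausible)
  expect_identical(est$failure_reason, "implausible_high")
})

test_that("scoring config rejects invalid parameters", {
  expect_error(scoring_config(increment_cadrads3 = -1), "increments")
  expect_error(scoring_config(cac_slope = -0.1), "cac_slope")
  expect_error(scoring_config(plausible_min = 110), "plausible_min")
})
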