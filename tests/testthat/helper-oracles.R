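# Independent oracles and randomized-fixture builders shared by the suite.
# They deliberately avoid the package's own computation paths.

# Brute-force re-derivation of the additive age score from the rule list.
oracle_bioage <- function(m, cfg = scoring_config()) {
  total <- cfg$cac_base_intercept + cfg$cac_slope * m$cac_au
  total <- total + switch(m$cadrads,
                          "0" = 0, "1" = 0,
                          "2" = cfg$increment_cadrads2,
                          "3" = cfg$increment_cadrads3,
                          "4a" = cfg$increment_cadrads4a,
                          "4b" = cfg$increment_cadrads4b,
                          "5" = cfg$increment_cadrads5)
  if (all(c("LAD", "RCA", "CX") %in% m$vessel_over50)) {
    total <- total + cfg$increment_multivessel
  }
  if (m$proximal_lad_over70) total <- total + cfg$increment_proximal_lad
  if (m$soft_plaque_rca_cx_only) total <- total + cfg$increment_soft_plaque_rca_cx
  if (m$lvef_percent < cfg$lvef_threshold ||
      (is.finite(m$edv_ml) && m$edv_ml > cfg$edv_elevated_threshold) ||
      (is.finite(m$esv_ml) && m$esv_ml > cfg$esv_elevated_threshold)) {
    total <- total + cfg$increment_low_lvef_or_elevated_volumes
  }
  if (length(m$extracoronary_findings) > 0) {
    total <- total + cfg$increment_extracoronary
  }
  total
}

# Exhaustive pair counting: wins 1, ties 0.5, over all (positive, negative)
# pairs.
oracle_auc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  s <- 0
  for (x in pos) for (y in neg) s <- s + (x > y) + 0.5 * (x == y)
  s / (length(pos) * length(neg))
}

# Draw one valid random key_metrics (uses the session RNG; seed at call
# site).
random_metrics <- function() {
  cadrads <- sample(cadrads_levels(), 1)
  cac <- round(if (stats::runif(1) < 0.25) 0 else exp(stats::runif(1, 0, 7.8)), 1)
  proximal <- FALSE
  vessels <- character()
  if (cadrads == "3") {
    vessels <- sample(c("LAD", "RCA", "CX"), sample(0:2, 1))
  } else if (cadrads %in% c("4a", "4b", "5")) {
    proximal <- stats::runif(1) < 0.3
    vessels <- sample(c("LAD", "RCA", "CX"), sample(1:3, 1))
  }
  soft <- !("LAD" %in% vessels) && !proximal && stats::runif(1) < 0.3
  edv <- esv <- NA_real_
  u <- stats::runif(1)
  if (u < 0.6) {
    edv <- sample(80:300, 1)
    esv <- sample(20:(edv - 1), 1)
  } else if (u < 0.7) {
    edv <- sample(80:300, 1)
  } else if (u < 0.8) {
    esv <- sample(20:150, 1)
  }
  key_metrics(
    cac_au = cac, cadrads = cadrads,
    lvef_percent = sample(23:86, 1),
    vessel_over50 = vessels,
    proximal_lad_over70 = proximal,
    soft_plaque_rca_cx_only = soft,
    hrp_present = stats::runif(1) < 0.25,
    edv_ml = edv, esv_ml = esv,
    extracoronary_findings = sample(c("aortic_ectasia", "aortic_aneurysm",
                                      "other"), sample(0:2, 1))
  )
}

expect_metrics_equal <- function(got, want) {
  for (f in names(want)) {
    expect_equal(got[[f]], want[[f]], label = paste0("field ", f))
  }
}

# Analytic mean of a normal truncated to [lo, hi].
truncnorm_mean <- function(mean, sd, lo, hi) {
  a <- (lo - mean) / sd
  b <- (hi - mean) / sd
  mean + sd * (stats::dnorm(a) - stats::dnorm(b)) /
    (stats::pnorm(b) - stats::pnorm(a))
}
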