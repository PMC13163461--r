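# Report templating. Every section has 3 phrase variants; the variant of
# section k is (style_seed + k) %% 3, so style seeds 0..2 jointly cover all
# variants and any integer seed is valid. Rendering is pure: deterministic
# in (metrics, locale, style_seed) and independent of the global RNG.

#' Template style seeds covering all phrase variants
#'
#' @return Integer vector of style seeds that jointly exercise every
#'   phrase variant of every report section.
#' @export
template_styles <- function() 0:2

fmt_num <- function(x, locale) {
  s <- formatC(x, format = "f", digits = if (x %% 1 == 0) 0 else 1)
  if (locale == "de") sub(".", ",", s, fixed = TRUE) else s
}

# deterministic stenosis percent consistent with the flag thresholds:
# proximal LAD lesions render at 70-80%, other >50% lesions at 50-65%
stenosis_percent <- function(style_seed, proximal) {
  if (proximal) 70 + (style_seed %% 3) * 5 else 50 + (style_seed %% 4) * 5
}

#' Render a structured coronary CTA report
#'
#' Emits a multi-section plain-text report (calcium score with Agatston
#' value, per-vessel stenosis narrative, an explicit CAD-RADS token,
#' high-risk plaque and soft-plaque wording, LV function with LVEF/EDV/ESV,
#' extracoronary findings) in German or English. German reports use the
#' decimal comma. Phrase choice is deterministic in `style_seed`, and the
#' output satisfies the round-trip contract
#' `parse_report(render_report(m))` recovering `m` exactly.
#'
#' @param metrics a `key_metrics` object.
#' @param locale `"de"` or `"en"`.
#' @param style_seed non-negative integer selecting phrase variants.
#' @return A single string, sections separated by newlines.
#' @examples
#' m <- key_metrics(cac_au = 215.3, cadrads = "3", lvef_percent = 77)
#' cat(render_report(m, locale = "en"))
#' @export
render_report <- function(metrics, locale = c("en", "de"), style_seed = 0L) {
  validate_key_metrics(metrics)
  locale <- match.arg(locale)
  style_seed <- as.integer(style_seed)
  if (is.na(style_seed) || style_seed < 0) stop("style_seed must be a non-negative integer")
  vr <- function(k) (style_seed + k) %% 3L
  de <- locale == "de"
  lines <- character()

  headers <- if (de) {
    c("Koronar-CTA Befund.",
      "Computertomographische Koronarangiographie - strukturierter Befund.",
      "CT-Angiographie der Koronararterien.")
  } else {
    c("Coronary CTA report.",
      "Cardiac CT angiography - structured report.",
      "CTA of the coronary arteries.")
  }
  lines <- c(lines, headers[vr(0) + 1])

  cacs <- fmt_num(metrics$cac_au, locale)
  cac_line <- if (de) {
    switch(vr(1) + 1L,
           sprintf("Kalkscore (Agatston): %s.", cacs),
           sprintf("Calcium-Score: %s AU.", cacs),
           sprintf("Agatston-Score gesamt: %s.", cacs))
  } else {
    switch(vr(1) + 1L,
           sprintf("Calcium score (Agatston): %s AU.", cacs),
           sprintf("CAC score: %s AU.", cacs),
           sprintf("Total Agatston calcium score: %s.", cacs))
  }
  lines <- c(lines, cac_line)

  v2 <- vr(2)
  for (vessel in metrics$vessel_over50) {
    proximal <- vessel == "LAD" && metrics$proximal_lad_over70
    seg <- if (vessel == "LAD") (if (proximal) "proximal" else "mid") else "none"
    pct <- stenosis_percent(style_seed, proximal)
    if (de) {
      name <- if (v2 == 1) c(LAD = "RIVA", RCA = "RCA", CX = "RCX")[[vessel]] else vessel
      seg_txt <- c(proximal = "proximalen ", mid = "mittleren ", none = "")[[seg]]
      line <- switch(v2 + 1L,
                     sprintf("Stenose der %s%s: %d%%.", seg_txt, name, pct),
                     sprintf("%d%%ige Stenose der %s%s.", pct, seg_txt, name),
                     sprintf("Nachweis einer Stenose der %s%s (%d%%).",
                             seg_txt, name, pct))
    } else {
      seg_txt <- c(proximal = "proximal ", mid = "mid ", none = "")[[seg]]
      line <- switch(v2 + 1L,
                     sprintf("Stenosis of the %s%s: %d%%.", seg_txt, vessel, pct),
                     sprintf("%s%s stenosis %d%%.", seg_txt, vessel, pct),
                     sprintf("There is a %d%% stenosis of the %s%s.",
                             pct, seg_txt, vessel))
    }
    lines <- c(lines, line)
  }
  if (length(metrics$vessel_over50) == 0) {
    lines <- c(lines, if (de) "Keine signifikanten Koronarstenosen." else
      "No significant coronary stenosis.")
  }

  if (metrics$soft_plaque_rca_cx_only) {
    rv <- if (style_seed %% 2 == 0) "RCA" else if (de) "RCX" else "CX"
    soft <- if (de) {
      switch(vr(3) + 1L,
             sprintf("Nicht verkalkte Plaque in der %s ohne signifikante Stenose.", rv),
             sprintf("Weiche Plaque der %s, keine relevante Stenose.", rv),
             sprintf("%s: ausschliesslich nicht verkalkte (weiche) Plaque.", rv))
    } else {
      switch(vr(3) + 1L,
             sprintf("Non-calcified plaque in the %s without significant stenosis.", rv),
             sprintf("Soft plaque of the %s, no relevant stenosis.", rv),
             sprintf("%s: non-calcified (soft) plaque only.", rv))
    }
    lines <- c(lines, soft)
  }

  if (metrics$hrp_present) {
    hrp <- if (de) {
      switch(vr(4) + 1L,
             "Hochrisiko-Plaque mit positivem Remodeling.",
             "Napkin-Ring-Zeichen als Hochrisikomerkmal.",
             "Plaque mit fleckiger Verkalkung und positivem Remodeling (Hochrisiko).")
    } else {
      switch(vr(4) + 1L,
             "High-risk plaque features: positive remodeling and spotty calcification.",
             "Napkin-ring sign consistent with high-risk plaque.",
             "Plaque with positive remodeling (high-risk features).")
    }
    lines <- c(lines, hrp)
  }

  cr_line <- switch(vr(5) + 1L,
                    sprintf("CAD-RADS %s.", metrics$cadrads),
                    sprintf("CADRADS %s.", metrics$cadrads),
                    sprintf("%s: CAD-RADS %s.",
                            if (de) "Klassifikation" else "Classification",
                            metrics$cadrads))
  lines <- c(lines, cr_line)

  l <- fmt_num(metrics$lvef_percent, locale)
  vol_parts <- c(
    if (is.finite(metrics$edv_ml)) sprintf("EDV %s ml", fmt_num(metrics$edv_ml, locale)),
    if (is.finite(metrics$esv_ml)) sprintf("ESV %s ml", fmt_num(metrics$esv_ml, locale)))
  voltxt <- if (length(vol_parts)) {
    paste0(" ", paste(vol_parts, collapse = ", "), ".")
  } else ""
  fun_line <- if (de) {
    switch(vr(6) + 1L,
           sprintf("Linksventrikulaere Funktion: LVEF %s %%.%s", l, voltxt),
           sprintf("Ejektionsfraktion (EF): %s %%.%s", l, voltxt),
           sprintf("LVEF %s%%.%s", l, voltxt))
  } else {
    switch(vr(6) + 1L,
           sprintf("LV function: LVEF %s%%.%s", l, voltxt),
           sprintf("Ejection fraction (EF): %s %%.%s", l, voltxt),
           sprintf("LVEF %s%%.%s", l, voltxt))
  }
  lines <- c(lines, fun_line)

  if (length(metrics$extracoronary_findings) == 0) {
    none_line <- if (de) {
      switch(vr(7) + 1L,
             "Keine relevanten extrakardialen Nebenbefunde.",
             "Extrakardiale Strukturen unauffaellig.",
             "Keine extrakardialen Auffaelligkeiten.")
    } else {
      switch(vr(7) + 1L,
             "No relevant extracoronary findings.",
             "Extracoronary structures unremarkable.",
             "No extracardiac abnormalities.")
    }
    lines <- c(lines, none_line)
  } else {
    finding_line <- c(
      aortic_ectasia = if (de) "Ektasie der Aorta ascendens." else
        "Ectasia of the ascending aorta.",
      aortic_aneurysm = if (de) "Aneurysma der Aorta ascendens." else
        "Aneurysm of the ascending aorta.",
      other = if (de) "Unspezifischer pulmonaler Rundherd." else
        "Incidental pulmonary nodule.")
    lines <- c(lines, unname(finding_line[metrics$extracoronary_findings]))
  }

  paste(lines, collapse = "\n")
}

#' Inject parse-hostile report variants into a cohort
#'
#' Rewrites a seeded Bernoulli subset of the cohort's reports with one of
#' three failure modes observed with real structured reports: (a) the
#' CAD-RADS token is deleted, (b) stenosis is described only with synonym
#' vocabulary ("Einengung" / "luminal narrowing") and the CAD-RADS token is
#' dropped, (c) the calcium-score section is deleted. Altered records are
#' tagged in the `injected_failure` column for test assertions.
#'
#' @param records a `cohort` data.frame with a `report_text` column.
#' @param config the [cohort_config()]; `parse_failure_rate` sets the
#'   alteration probability.
#' @return The records with rewritten `report_text` where altered and an
#'   `injected_failure` column (`NA`, `"cadrads_deleted"`,
#'   `"einengung_synonym"` or `"cac_deleted"`).
#' @export
inject_failures <- function(records, config = cohort_config()) {
  if (is.null(records$report_text)) stop("records must carry report_text")
  rate <- config$parse_failure_rate
  if (rate < 0 || rate > 1) stop("parse_failure_rate must lie in [0, 1]")
  set.seed((config$seed + 202L) %% 2147483647L)
  n <- nrow(records)
  hit <- stats::runif(n) < rate
  mode <- sample(c("cadrads_deleted", "einengung_synonym", "cac_deleted"),
                 n, replace = TRUE)
  records$injected_failure <- ifelse(hit, mode, NA_character_)
  for (i in which(hit)) {
    records$report_text[i] <- corrupt_report(records$report_text[i], mode[i],
                                             records$locale[i])
  }
  records
}

corrupt_report <- function(text, mode, locale) {
  lines <- strsplit(text, "\n", fixed = TRUE)[[1]]
  is_cadrads <- grepl("CAD[- ]?RADS", lines, ignore.case = TRUE)
  is_cac <- grepl("CAC|Agatston|Kalkscore|Calcium", lines, ignore.case = TRUE)
  is_sten <- grepl("\\b(LAD|RIVA|RCA|RCX|CX)\\b", lines) & grepl("%", lines)
  if (mode == "cadrads_deleted") {
    lines <- lines[!is_cadrads]
  } else if (mode == "einengung_synonym") {
    synonym <- if (identical(locale, "en")) {
      "Marked luminal narrowing of the coronary arteries."
    } else {
      "Deutliche Einengung der Herzkranzgefaesse."
    }
    lines <- lines[!is_cadrads & !is_sten]
    lines <- append(lines, synonym, after = min(2L, length(lines)))
  } else if (mode == "cac_deleted") {
    lines <- lines[!is_cac]
  } else {
    stop("unknown failure mode: ", mode)
  }
  paste(lines, collapse = "\n")
}
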