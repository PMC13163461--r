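test_that("calcium score extraction handles lexicon, zero and locale commas", {
  expect_equal(extract_cac("Calcium score (Agatston): 215.3 AU")$value, 215.3)
  expect_equal(extract_cac("Kalkscore: 0")$value, 0)
  expect_equal(extract_cac("Kalkscore: 1.204,5", locale = "de")$value, 1204.5)
  expect_equal(extract_cac("CAC score: 215,3 AU")$value, 215.3)
  expect_true(is.na(extract_cac("no calcium information here")$value))
  bad <- extract_cac("Calcium score: 12.3.4 AU")
  expect_true(bad$malformed)
})

test_that("CAD-RADS extraction matches token variants and takes the maximum", {
  expect_equal(extract_cadrads("Findings ... CAD-RADS 3 ...")$value, "3")
  expect_equal(extract_cadrads("CADRADS 4a")$value, "4a")
  expect_equal(extract_cadrads("CAD-RADS 2 in RCA. CAD-RADS 3 in LAD.")$value, "3")
  expect_equal(extract_cadrads("cad-rads 4B")$value, "4b")
  missing <- extract_cadrads("no classification given")
  expect_true(is.na(missing$value) && !missing$ambiguous)
  amb <- extract_cadrads("CAD-RADS not assessable")
  expect_true(is.na(amb$value) && amb$ambiguous)
})

test_that("anatomy flags follow the clause-level percentage rules", {
  de <- extract_anatomy_flags("proximale LAD Stenose 80%")
  expect_true(de$proximal_lad_over70)
  expect_equal(de$vessel_over50, "LAD")

  multi <- extract_anatomy_flags("LAD 60%, RCA 55%, CX 70%")
  expect_equal(multi$vessel_over50, c("CX", "LAD", "RCA"))
  expect_false(multi$proximal_lad_over70)

  soft <- extract_anatomy_flags(
    "non-calcified plaque RCA, no stenosis elsewhere, CAD-RADS 1")
  expect_true(soft$soft_plaque_rca_cx_only)

  # soft plaque wording is not 'only' when the LAD carries a >50% lesion
  notsoft <- extract_anatomy_flags("soft plaque of the RCA. LAD stenosis 60%.")
  expect_false(notsoft$soft_plaque_rca_cx_only)

  below <- extract_anatomy_flags("LAD stenosis 40%")
  expect_length(below$vessel_over50, 0)

  riva <- extract_anatomy_flags("70%ige Stenose der proximalen RIVA.")
  expect_true(riva$proximal_lad_over70)
  expect_equal(riva$vessel_over50, "LAD")

  hrp <- extract_anatomy_flags("Napkin-ring sign and spotty calcification.")
  expect_true(hrp$hrp_present)
})

test_that("LV function extraction finds LVEF/EF tokens; volumes stay optional", {
  expect_equal(extract_function("LVEF 77%")$lvef, 77)
  expect_equal(extract_function("EF: 23 %")$lvef, 23)
  fx <- extract_function("LV function: LVEF 58%. EDV 180 ml, ESV 76 ml.")
  expect_equal(fx$lvef, 58)
  expect_equal(fx$edv, 180)
  expect_equal(fx$esv, 76)
  expect_true(is.na(extract_function("volumes not measured")$lvef))
})

test_that("parse gate requires all three key metrics with prioritized reasons", {
  m <- key_metrics(215.3, "3", 77)
  txt <- render_report(m, "en")
  pr <- parse_report(txt)
  expect_identical(pr$outcome, "parsed")
  expect_metrics_equal(pr$metrics, m)

  no_cadrads <- paste(grep("CAD-RADS", strsplit(txt, "\n")[[1]],
                           invert = TRUE, value = TRUE), collapse = "\n")
  pr2 <- parse_report(no_cadrads)
  expect_identical(pr2$outcome, "failed")
  expect_identical(pr2$failure_reason, "missing_cadrads")

  no_cac <- paste(grep("Calcium|CAC|Agatston", strsplit(txt, "\n")[[1]],
                       invert = TRUE, value = TRUE), collapse = "\n")
  expect_identical(parse_report(no_cac)$failure_reason, "missing_cac")

  no_fun <- paste(grep("LVEF|EF", strsplit(txt, "\n")[[1]],
                       invert = TRUE, value = TRUE), collapse = "\n")
  expect_identical(parse_report(no_fun)$failure_reason, "missing_function")

  # German synonym phrasing without a CAD-RADS token fails
  einengung <- paste("Koronar-CTA Befund.", "Kalkscore (Agatston): 88,4.",
                     "Deutliche Einengung der Herzkranzgefaesse.",
                     "LVEF 62 %.", sep = "\n")
  pr3 <- parse_report(einengung)
  expect_identical(pr3$outcome, "failed")
  expect_true(pr3$failure_reason %in% c("missing_cadrads", "ambiguous_phrasing"))
})

test_that("empty input raises an input error distinct from a parse failure", {
  expect_error(parse_report(""), class = "cardioage_input_error")
  expect_error(parse_report("   \n"), class = "cardioage_input_error")
})

test_that("matched spans reference real substrings of the input", {
  m <- key_metrics(321.7, "4a", 55, vessel_over50 = c("LAD", "RCA"),
                   proximal_lad_over70 = TRUE, hrp_present = TRUE,
                   edv_ml = 210, esv_ml = 95,
                   extracoronary_findings = "aortic_ectasia")
  for (loc in c("en", "de")) {
    txt <- render_report(m, loc, style_seed = 1)
    pr <- parse_report(txt)
    expect_identical(pr$outcome, "parsed")
    sp <- pr$matched_spans
    expect_gt(nrow(sp), 0)
    expect_true(all(sp$start >= 1 & sp$end <= nchar(txt) & sp$start <= sp$end))
    cac_span <- substr(txt, sp$start[sp$field == "cac_au"],
                       sp$end[sp$field == "cac_au"])
    expect_match(cac_span, "^321[.,]7$")
  }
})

test_that("parsing is deterministic and render/parse round-trips exactly", {
  set.seed(23)
  for (i in 1:150) {
    m <- random_metrics()
    for (loc in c("en", "de")) {
      for (ss in template_styles()) {
        txt <- render_report(m, loc, ss)
        pr <- parse_report(txt)
        expect_identical(pr$outcome, "parsed")
        expect_metrics_equal(pr$metrics, m)
        expect_identical(pr, parse_report(txt))
      }
    }
  }
})

test_that("German reports carry decimal commas and both locales keep tokens", {
  m <- key_metrics(215.3, "3", 77)
  de <- render_report(m, "de")
  expect_match(de, "215,3")
  expect_match(de, "CAD-RADS 3", fixed = TRUE)
  en <- render_report(m, "en")
  expect_match(en, "215.3", fixed = TRUE)
  expect_match(en, "CAD-RADS 3", fixed = TRUE)
})

test_that("locale auto-detection separates the two template languages", {
  set.seed(31)
  for (i in 1:25) {
    m <- random_metrics()
    expect_identical(parse_report(render_report(m, "de", i))$locale, "de")
    expect_identical(parse_report(render_report(m, "en", i))$locale, "en")
  }
})
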