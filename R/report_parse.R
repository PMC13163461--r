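# Deterministic rule-based extraction of the three key report metrics
# (CAC, CAD-RADS, LV function) plus anatomy flags and extracoronary
# findings. This is the reproducible stand-in for an LLM extraction step:
# the downstream analysis depends on the extracted metrics, not on the
# extractor's identity.

.CAC_LEXICON <- "(?i)(kalkscore|calcium[- ]?score|agatston|\\bCAC\\b)"
.CADRADS_TOKEN <- "(?i)CAD[- ]?RADS"
.VESSEL_TOKEN <- "\\b(LAD|RIVA|RCA|RCX|CX)\\b"
.SOFT_PLAQUE <- "(?i)(non[- ]?calcified|soft plaque|nicht[ -]?verkalkt|weiche[n]? Plaque)"
.HRP_LEXICON <- paste0("(?i)(high[- ]?risk plaque|high[- ]?risk feature|hochrisiko|",
                       "napkin[- ]?ring|spotty calcification|fleckige[rn]? Verkalkung|",
                       "positive[sm]? remodeling)")

canonical_vessel <- function(v) {
  c(LAD = "LAD", RIVA = "LAD", RCA = "RCA", CX = "CX", RCX = "CX")[[v]]
}

# Normalize a matched number string to a numeric value. Decimal commas are
# accepted; an unambiguous single comma is always a decimal mark; dot groups
# of three digits under the German locale are thousands separators.
normalize_number <- function(s, locale = "en") {
  s <- gsub("^[^0-9]+|[^0-9]+$", "", s)
  if (!nzchar(s)) return(NA_real_)
  has_dot <- grepl(".", s, fixed = TRUE)
  has_comma <- grepl(",", s, fixed = TRUE)
  if (has_dot && has_comma) {
    # the rightmost separator is the decimal mark
    if (regexpr("\\.[0-9]*$", s) > regexpr(",[0-9]*$", s)) {
      s <- gsub(",", "", s, fixed = TRUE)
    } else {
      s <- gsub(".", "", s, fixed = TRUE)
      s <- sub(",", ".", s, fixed = TRUE)
    }
  } else if (has_comma) {
    if (lengths(regmatches(s, gregexpr(",", s, fixed = TRUE))) == 1L) {
      s <- sub(",", ".", s, fixed = TRUE)
    } else {
      s <- gsub(",", "", s, fixed = TRUE)
    }
  } else if (has_dot && locale == "de" &&
             grepl("^[0-9]{1,3}(\\.[0-9]{3})+$", s)) {
    s <- gsub(".", "", s, fixed = TRUE)
  }
  suppressWarnings(as.numeric(s))
}

span_row <- function(field, start, len) {
  data.frame(field = field, start = start, end = start + len - 1L,
             stringsAsFactors = FALSE)
}

empty_spans <- function() {
  data.frame(field = character(), start = integer(), end = integer(),
             stringsAsFactors = FALSE)
}

#' Extract the Agatston calcium score from report text
#'
#' Scans for the calcium-score lexicon ("CAC", "Agatston", "Kalkscore",
#' "Calcium-Score") and returns the first non-negative number within that
#' line, normalizing decimal commas and (under the German locale)
#' dot-grouped thousands separators.
#'
#' @param text report text.
#' @param locale `"de"` or `"en"` (affects thousands-separator handling).
#' @return List with `value` (Agatston units or `NA`), `malformed`
#'   (`TRUE` when a number was present but unparseable) and `span`.
#' @examples
#' extract_cac("Calcium score (Agatston): 215.3 AU")$value
#' extract_cac("Kalkscore: 1.204,5", locale = "de")$value # 1204.5
#' @export
extract_cac <- function(text, locale = "en") {
  hit <- regexpr(.CAC_LEXICON, text, perl = TRUE)
  if (hit < 0) return(list(value = NA_real_, malformed = FALSE, span = empty_spans()))
  rest_start <- hit + attr(hit, "match.length")
  line_end <- regexpr("\n", substring(text, rest_start))
  scope <- if (line_end < 0) substring(text, rest_start) else
    substring(text, rest_start, rest_start + line_end - 2L)
  num <- regexpr("[0-9][0-9.,]*", scope)
  if (num < 0) return(list(value = NA_real_, malformed = FALSE, span = empty_spans()))
  raw <- sub("[.,]+$", "", regmatches(scope, num)) # strip sentence punctuation
  value <- normalize_number(raw, locale)
  list(value = value, malformed = is.na(value),
       span = span_row("cac_au", rest_start + as.integer(num) - 1L, nchar(raw)))
}

#' Extract the CAD-RADS category from report text
#'
#' Matches "CAD-RADS"/"CADRADS" tokens followed by a category in
#' 0, 1, 2, 3, 4a, 4b, 5 (case-insensitive, optional hyphen/space). When
#' several tokens appear, the maximum category wins, following the
#' convention that per-vessel CAD-RADS reporting takes the patient-level
#' maximum.
#'
#' @param text report text.
#' @return List with `value` (category string or `NA`), `ambiguous`
#'   (`TRUE` when a token is present but no category can be read) and
#'   `span` of the winning match.
#' @examples
#' extract_cadrads("CAD-RADS 2. CAD-RADS 3.")$value # "3"
#' @export
extract_cadrads <- function(text) {
  pat <- "(?i)CAD[- ]?RADS[^0-9a-z\n]{0,3}([0-5])\\s?(a|b)?"
  m <- gregexpr(pat, text, perl = TRUE)[[1]]
  if (m[1] < 0) {
    token <- regexpr(.CADRADS_TOKEN, text, perl = TRUE)
    return(list(value = NA_character_, ambiguous = token > 0,
                span = empty_spans()))
  }
  cats <- vapply(regmatches(text, list(m))[[1]], function(s) {
    digit <- regmatches(s, regexpr("[0-5]", s))
    suffix <- tolower(regmatches(s, regexpr("(?i)[0-5]\\s?[ab]", s, perl = TRUE)))
    if (length(suffix)) paste0(digit, substr(suffix, nchar(suffix), nchar(suffix)))
    else digit
  }, character(1), USE.NAMES = FALSE)
  valid <- cats %in% .CADRADS
  if (!any(valid)) {
    return(list(value = NA_character_, ambiguous = TRUE, span = empty_spans()))
  }
  best <- which.max(ifelse(valid, cadrads_rank(ifelse(valid, cats, "0")), 0L))
  list(value = cats[best], ambiguous = FALSE,
       span = span_row("cadrads", as.integer(m[best]),
                       attr(m, "match.length")[best]))
}

# split text into clauses, tracking each clause's character offset
split_clauses <- function(text) {
  m <- gregexpr("[^.;\n]+", text)[[1]]
  if (m[1] < 0) return(data.frame(clause = character(), start = integer()))
  data.frame(clause = regmatches(text, list(m))[[1]],
             start = as.integer(m), stringsAsFactors = FALSE)
}

#' Extract high-risk anatomy flags from report text
#'
#' Clause-level rules: a clause naming a vessel (LAD/RIVA, RCA, CX/RCX)
#' with a stenosis percentage assigns that percentage to the vessel
#' (nearest percent within the clause); >= 50% sets membership in
#' `vessel_over50`; a proximal LAD clause at >= 70% sets
#' `proximal_lad_over70`; soft/non-calcified plaque wording confined to
#' RCA/CX with no >= 50% LAD lesion sets `soft_plaque_rca_cx_only`; the
#' high-risk plaque lexicon (napkin ring, spotty calcification, positive
#' remodeling, ...) sets `hrp_present`.
#'
#' @param text report text.
#' @param locale `"de"` or `"en"` (unused by the current lexicon, kept for
#'   symmetry with the other extractors).
#' @return List with `vessel_over50`, `proximal_lad_over70`,
#'   `soft_plaque_rca_cx_only`, `hrp_present` and `spans`.
#' @export
extract_anatomy_flags <- function(text, locale = "en") {
  clauses <- split_clauses(text)
  over50 <- character()
  proximal <- FALSE
  soft_candidate <- FALSE
  spans <- empty_spans()
  for (i in seq_len(nrow(clauses))) {
    cl <- clauses$clause[i]
    vm <- gregexpr(.VESSEL_TOKEN, cl)[[1]]
    pm <- gregexpr("([0-9]{1,3})\\s*%", cl)[[1]]
    if (vm[1] > 0 && pm[1] > 0) {
      vnames <- regmatches(cl, list(vm))[[1]]
      pvals <- as.numeric(sub("\\s*%", "", regmatches(cl, list(pm))[[1]]))
      for (k in seq_along(vnames)) {
        j <- which.min(abs(as.integer(pm) - vm[k]))
        pct <- pvals[j]
        vessel <- canonical_vessel(vnames[k])
        if (pct >= 50) {
          over50 <- union(over50, vessel)
          spans <- rbind(spans, span_row(paste0("vessel_", vessel),
                                         clauses$start[i] + vm[k] - 1L,
                                         attr(vm, "match.length")[k]))
        }
        if (vessel == "LAD" && pct >= 70 &&
            grepl("(?i)proximal", cl, perl = TRUE)) {
          proximal <- TRUE
        }
      }
    }
    if (grepl(.SOFT_PLAQUE, cl, perl = TRUE) && vm[1] > 0) {
      vnames <- vapply(regmatches(cl, list(vm))[[1]], canonical_vessel,
                       character(1), USE.NAMES = FALSE)
      if (all(vnames %in% c("RCA", "CX"))) soft_candidate <- TRUE
    }
  }
  hrp_hit <- regexpr(.HRP_LEXICON, text, perl = TRUE)
  if (hrp_hit > 0) {
    spans <- rbind(spans, span_row("hrp_present", as.integer(hrp_hit),
                                   attr(hrp_hit, "match.length")))
  }
  list(
    vessel_over50 = sort(over50),
    proximal_lad_over70 = proximal,
    soft_plaque_rca_cx_only = soft_candidate && !("LAD" %in% over50),
    hrp_present = hrp_hit > 0,
    spans = spans
  )
}

#' Extract LV function metrics from report text
#'
#' LVEF is taken from the first "LVEF"/"EF" token followed by a percent;
#' EDV and ESV (mL) are optional.
#'
#' @param text report text.
#' @param locale `"de"` or `"en"`.
#' @return List with `lvef`, `edv`, `esv` (numeric, `NA` when absent) and
#'   `spans`.
#' @examples
#' extract_function("EF: 23 %")$lvef
#' @export
extract_function <- function(text, locale = "en") {
  spans <- empty_spans()
  grab <- function(pat, field) {
    m <- regexpr(pat, text, perl = TRUE)
    if (m < 0) return(NA_real_)
    s <- regmatches(text, m)
    num <- regexpr("[0-9][0-9.,]*", s)
    spans <<- rbind(spans, span_row(field, as.integer(m) + as.integer(num) - 1L,
                                    attr(num, "match.length")))
    normalize_number(regmatches(s, num), locale)
  }
  lvef <- grab("(?i)\\b(LVEF|EF)\\b[^0-9%\n]{0,15}[0-9][0-9.,]*", "lvef_percent")
  edv <- grab("(?i)\\bEDV\\b[^0-9\n]{0,10}[0-9][0-9.,]*", "edv_ml")
  esv <- grab("(?i)\\bESV\\b[^0-9\n]{0,10}[0-9][0-9.,]*", "esv_ml")
  list(lvef = lvef, edv = edv, esv = esv, spans = spans)
}

#' Extract coded extracoronary findings from report text
#'
#' @param text report text.
#' @param locale `"de"` or `"en"`.
#' @return Character vector, subset of
#'   `c("aortic_ectasia", "aortic_aneurysm", "other")`.
#' @export
extract_extracoronary <- function(text, locale = "en") {
  out <- character()
  if (grepl("(?i)(ectasia|ektasie)", text, perl = TRUE)) {
    out <- c(out, "aortic_ectasia")
  }
  if (grepl("(?i)(aneurysm)", text, perl = TRUE)) {
    out <- c(out, "aortic_aneurysm")
  }
  if (grepl("(?i)(pulmonary nodule|pulmonaler Rundherd)", text, perl = TRUE)) {
    out <- c(out, "other")
  }
  sort(out)
}

detect_locale <- function(text) {
  de_hits <- lengths(regmatches(text, gregexpr(
    paste0("(?i)(Befund|Kalkscore|Stenose|Keine|Nachweis|Funktion|",
           "Klassifikation|Einengung|verkalkt|Weiche|unauffaellig|",
           "Nebenbefund|Herzkranz|Ektasie|Rundherd|Volumina)"),
    text, perl = TRUE)))
  en_hits <- lengths(regmatches(text, gregexpr(
    paste0("(?i)(report|stenosis|calcium score|function|plaque only|",
           "findings|narrowing|unremarkable|there is|ascending)"),
    text, perl = TRUE)))
  if (de_hits >= en_hits) "de" else "en"
}

parse_failure <- function(reason, spans, locale) {
  structure(list(outcome = "failed", metrics = NULL, failure_reason = reason,
                 matched_spans = spans, locale = locale),
            class = "parse_result")
}

#' Parse a structured coronary CTA report
#'
#' Applies, in order: locale detection (keyword voting when `"auto"`), CAC
#' extraction, CAD-RADS extraction, anatomy flags, LV function and
#' extracoronary findings. The parse succeeds only when all three key
#' metrics (CAC, CAD-RADS, LVEF) are found; otherwise a typed failure is
#' returned, prioritized CAC, then CAD-RADS, then function — mirroring the
#' order in which a reader would re-query a report with missing metrics.
#' Reports whose extracted metrics violate the key-metrics invariants (for
#' example an obstructive CAD-RADS with no stenosed vessel) fail as
#' `ambiguous_phrasing`.
#'
#' @param text one report as a UTF-8 string; must be non-empty.
#' @param locale `"de"`, `"en"` or `"auto"`.
#' @return An object of class `parse_result`: `outcome`
#'   (`"parsed"`/`"failed"`), `metrics` (a `key_metrics` when parsed),
#'   `failure_reason` (`missing_cac`, `malformed_number`,
#'   `missing_cadrads`, `ambiguous_phrasing` or `missing_function`),
#'   `matched_spans` (field, start, end — all referencing substrings of the
#'   input) and `locale`.
#' @examples
#' m <- key_metrics(cac_au = 215.3, cadrads = "3", lvef_percent = 77)
#' parse_report(render_report(m, "en"))
#' @export
parse_report <- function(text, locale = c("auto", "de", "en")) {
  locale <- match.arg(locale)
  if (length(text) != 1 || is.na(text) || !nzchar(trimws(text))) {
    stop(errorCondition("empty report text", class = c("cardioage_input_error",
                                                       "error", "condition")))
  }
  if (locale == "auto") locale <- detect_locale(text)

  cac <- extract_cac(text, locale)
  spans <- cac$span
  if (cac$malformed) return(parse_failure("malformed_number", spans, locale))
  if (is.na(cac$value)) return(parse_failure("missing_cac", spans, locale))

  cr <- extract_cadrads(text)
  spans <- rbind(spans, cr$span)
  if (is.na(cr$value)) {
    reason <- if (cr$ambiguous) "ambiguous_phrasing" else "missing_cadrads"
    return(parse_failure(reason, spans, locale))
  }

  flags <- extract_anatomy_flags(text, locale)
  spans <- rbind(spans, flags$spans)
  fun <- extract_function(text, locale)
  spans <- rbind(spans, fun$spans)
  if (is.na(fun$lvef)) return(parse_failure("missing_function", spans, locale))
  extra <- extract_extracoronary(text, locale)

  metrics <- tryCatch(
    key_metrics(
      cac_au = cac$value,
      cadrads = cr$value,
      lvef_percent = fun$lvef,
      vessel_over50 = flags$vessel_over50,
      proximal_lad_over70 = flags$proximal_lad_over70,
      soft_plaque_rca_cx_only = flags$soft_plaque_rca_cx_only,
      hrp_present = flags$hrp_present,
      edv_ml = fun$edv, esv_ml = fun$esv,
      extracoronary_findings = extra
    ),
    error = function(e) NULL
  )
  if (is.null(metrics)) return(parse_failure("ambiguous_phrasing", spans, locale))
  structure(list(outcome = "parsed", metrics = metrics,
                 failure_reason = NA_character_,
                 matched_spans = spans, locale = locale),
            class = "parse_result")
}

#' @export
print.parse_result <- function(x, ...) {
  if (x$outcome == "parsed") {
    cat("Parsed CTA report (locale ", x$locale, ")\n", sep = "")
    print(x$metrics)
  } else {
    cat("Parse failure (", x$failure_reason, ", locale ", x$locale, ")\n",
        sep = "")
  }
  invisible(x)
}
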