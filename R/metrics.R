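#' @keywords internal
"_PACKAGE"

# Ordered CAD-RADS categories; 4 is split into 4a/4b, 5 = occlusion.
.CADRADS <- c("0", "1", "2", "3", "4a", "4b", "5")
.VESSELS <- c("LAD", "RCA", "CX")
.EXTRACORONARY <- c("aortic_ectasia", "aortic_aneurysm", "other")

#' CAD-RADS category levels in severity order
#'
#' @return Character vector `c("0","1","2","3","4a","4b","5")`, ordered from
#'   no disease to total occlusion.
#' @export
cadrads_levels <- function() .CADRADS

#' Rank of a CAD-RADS category along the severity order
#'
#' @param cadrads character vector of categories.
#' @return Integer rank, 1 for category "0" through 7 for "5".
#' @export
cadrads_rank <- function(cadrads) {
  r <- match(as.character(cadrads), .CADRADS)
  if (anyNA(r)) {
    stop("unknown CAD-RADS category: ",
         paste(unique(setdiff(as.character(cadrads), .CADRADS)), collapse = ", "))
  }
  r
}

#' Structured key metrics of one coronary CTA report
#'
#' Container for the three key report metrics (CAC score, CAD-RADS category,
#' LV function) plus the high-risk anatomy flags and extracoronary findings
#' that enter the biological-age score.
#'
#' @param cac_au coronary artery calcium score, Agatston units, >= 0.
#' @param cadrads CAD-RADS category, one of `cadrads_levels()`.
#' @param lvef_percent left-ventricular ejection fraction in (0, 100].
#' @param vessel_over50 character subset of `c("LAD","RCA","CX")` with a
#'   stenosis > 50%.
#' @param proximal_lad_over70 logical, proximal LAD stenosis > 70%.
#' @param soft_plaque_rca_cx_only logical, soft (non-calcified) plaque
#'   confined to RCA/CX with no >= 50% LAD lesion.
#' @param hrp_present logical, high-risk plaque features present.
#' @param edv_ml,esv_ml LV end-diastolic / end-systolic volumes in mL,
#'   `NA` when not reported.
#' @param extracoronary_findings character subset of
#'   `c("aortic_ectasia","aortic_aneurysm","other")`.
#' @return An object of class `key_metrics`.
#' @examples
#' key_metrics(cac_au = 215.3, cadrads = "3", lvef_percent = 77)
#' @export
key_metrics <- function(cac_au, cadrads, lvef_percent,
                        vessel_over50 = character(),
                        proximal_lad_over70 = FALSE,
                        soft_plaque_rca_cx_only = FALSE,
                        hrp_present = FALSE,
                        edv_ml = NA_real_, esv_ml = NA_real_,
                        extracoronary_findings = character()) {
  vessel_over50 <- as.character(vessel_over50)
  # a proximal LAD lesion > 70% is in particular a > 50% LAD lesion
  if (isTRUE(proximal_lad_over70)) vessel_over50 <- c(vessel_over50, "LAD")
  m <- structure(
    list(
      cac_au = as.numeric(cac_au),
      cadrads = as.character(cadrads),
      vessel_over50 = sort(unique(vessel_over50)),
      proximal_lad_over70 = isTRUE(proximal_lad_over70),
      soft_plaque_rca_cx_only = isTRUE(soft_plaque_rca_cx_only),
      hrp_present = isTRUE(hrp_present),
      lvef_percent = as.numeric(lvef_percent),
      edv_ml = as.numeric(edv_ml),
      esv_ml = as.numeric(esv_ml),
      extracoronary_findings = sort(unique(as.character(extracoronary_findings)))
    ),
    class = "key_metrics"
  )
  validate_key_metrics(m)
}

#' Validate a key_metrics object
#'
#' Checks the domain invariants: non-negative CAC, known CAD-RADS category,
#' LVEF in (0, 100], vessel set membership, obstructive categories (4a/4b/5)
#' implying at least one > 50% vessel or a proximal LAD lesion, soft-plaque
#' flag excluding LAD involvement, and ESV < EDV when both are present.
#'
#' @param m a `key_metrics` object.
#' @return `m`, invisibly unchanged, or an error naming the violated rule.
#' @export
validate_key_metrics <- function(m) {
  stopifnot(inherits(m, "key_metrics"))
  if (!is.finite(m$cac_au) || m$cac_au < 0) {
    stop("cac_au must be a finite non-negative Agatston value")
  }
  cadrads_rank(m$cadrads)
  if (!is.finite(m$lvef_percent) || m$lvef_percent <= 0 || m$lvef_percent > 100) {
    stop("lvef_percent must lie in (0, 100]")
  }
  if (!all(m$vessel_over50 %in% .VESSELS)) {
    stop("vessel_over50 must be a subset of {LAD, RCA, CX}")
  }
  if (!all(m$extracoronary_findings %in% .EXTRACORONARY)) {
    stop("extracoronary_findings must be a subset of {",
         paste(.EXTRACORONARY, collapse = ", "), "}")
  }
  if (m$cadrads %in% c("4a", "4b", "5") &&
      length(m$vessel_over50) == 0 && !m$proximal_lad_over70) {
    stop("CAD-RADS ", m$cadrads,
         " requires at least one vessel > 50% or a proximal LAD lesion")
  }
  if (m$soft_plaque_rca_cx_only && "LAD" %in% m$vessel_over50) {
    stop("soft_plaque_rca_cx_only excludes a >50% LAD lesion")
  }
  if (is.finite(m$edv_ml) && is.finite(m$esv_ml) && !(m$esv_ml < m$edv_ml)) {
    stop("esv_ml must be smaller than edv_ml when both are present")
  }
  invisible(m)
}

#' @export
print.key_metrics <- function(x, ...) {
  cat("CTA key metrics\n")
  cat("  CAC:", x$cac_au, "AU | CAD-RADS:", x$cadrads,
      "| LVEF:", x$lvef_percent, "%\n")
  if (length(x$vessel_over50)) {
    cat("  vessels > 50%:", paste(x$vessel_over50, collapse = ", "), "\n")
  }
  flags <- c("proximal LAD > 70%" = x$proximal_lad_over70,
             "soft plaque RCA/CX only" = x$soft_plaque_rca_cx_only,
             "high-risk plaque" = x$hrp_present)
  if (any(flags)) cat("  flags:", paste(names(flags)[flags], collapse = "; "), "\n")
  if (is.finite(x$edv_ml) || is.finite(x$esv_ml)) {
    cat("  EDV:", x$edv_ml, "mL | ESV:", x$esv_ml, "mL\n")
  }
  if (length(x$extracoronary_findings)) {
    cat("  extracoronary:", paste(x$extracoronary_findings, collapse = ", "), "\n")
  }
  invisible(x)
}

# Flatten a key_metrics object to a one-row data.frame (set fields become
# comma-joined strings, "" when empty).
metrics_to_row <- function(m) {
  data.frame(
    cac_au = m$cac_au,
    cadrads = m$cadrads,
    vessel_over50 = paste(m$vessel_over50, collapse = ","),
    proximal_lad_over70 = m$proximal_lad_over70,
    soft_plaque_rca_cx_only = m$soft_plaque_rca_cx_only,
    hrp_present = m$hrp_present,
    lvef_percent = m$lvef_percent,
    edv_ml = m$edv_ml,
    esv_ml = m$esv_ml,
    extracoronary_findings = paste(m$extracoronary_findings, collapse = ","),
    stringsAsFactors = FALSE
  )
}

split_set <- function(x) {
  if (is.na(x) || !nzchar(x)) character() else strsplit(x, ",", fixed = TRUE)[[1]]
}

#' Rebuild a key_metrics object from a flattened table row
#'
#' Inverse of the flattened representation used in cohort tables and CSV
#' output, where the set-valued fields are comma-joined strings.
#'
#' @param row a one-row data.frame (or list) with the flattened metric columns.
#' @return A `key_metrics` object.
#' @export
metrics_from_row <- function(row) {
  key_metrics(
    cac_au = row$cac_au,
    cadrads = row$cadrads,
    lvef_percent = row$lvef_percent,
    vessel_over50 = split_set(row$vessel_over50),
    proximal_lad_over70 = isTRUE(row$proximal_lad_over70),
    soft_plaque_rca_cx_only = isTRUE(row$soft_plaque_rca_cx_only),
    hrp_present = isTRUE(row$hrp_present),
    edv_ml = if (is.null(row$edv_ml)) NA_real_ else row$edv_ml,
    esv_ml = if (is.null(row$esv_ml)) NA_real_ else row$esv_ml,
    extracoronary_findings = split_set(row$extracoronary_findings)
  )
}
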