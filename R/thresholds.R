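#' Guideline rule thresholds
#'
#' The numeric cut-points used by the rules engine, collected in one place
#' so that they can be inspected, documented, and (for the configurable
#' ones) overridden. Units follow field convention: blood pressure in
#' mm Hg, lipids and glucose in mg/dL, heart rate in beats/min, BMI in
#' kg/m^2, waist in cm.
#'
#' The inclusivity of each comparison follows the printed guideline
#' operator: `>=` cut-points are inclusive (e.g. SBP >= 160 mm Hg), `>`
#' cut-points strict (e.g. TC/HDL ratio > 8, heart rate > 100).
#'
#' @param ... Named overrides for individual thresholds, e.g.
#'   `cvd_thresholds(dysglycemia_lo = 100)`. Unknown names error.
#'
#' @return A named list of thresholds with class `"cvd_thresholds"`.
#' @examples
#' th <- cvd_thresholds()
#' th$chr_sbp
#' @export
cvd_thresholds <- function(...) {
  th <- list(
    # clinically-high-risk single-factor cut-points (inclusive >=, ratio strict >)
    chr_sbp   = 160,
    chr_dbp   = 100,
    chr_tc    = 320,
    chr_ldl   = 240,
    chr_ratio = 8,
    # diabetes / dysglycemia (mg/dL)
    fasting_diabetes = 126,
    random_diabetes  = 200,
    dysglycemia_lo   = 110,
    dysglycemia_hi   = 125,
    # risk-underestimation flags
    heart_rate  = 100,   # strict >
    tg          = 180,   # strict >
    hdl_male    = 40,    # strict <
    hdl_female  = 50,    # strict <
    bmi_obese   = 27.5,  # inclusive >=, WHO Asian cut-point
    waist_male  = 90,    # inclusive >=
    waist_female = 80,   # inclusive >=
    # BP medication tiers (disjunctive systolic/diastolic)
    bp1_sbp = 160, bp1_dbp = 100,
    bp2_sbp = 140, bp2_dbp = 90,
    bp3_sbp = 130, bp3_dbp = 80,
    # statin lipid gate under age >= 40 and risk > 20%
    statin_age = 40,
    statin_tc  = 200,
    statin_ldl = 120,
    # unit conversion
    mgdl_per_mmol_tc = 38.67
  )
  dots <- list(...)
  if (length(dots)) {
    bad <- setdiff(names(dots), names(th))
    if (length(bad)) {
      stop("unknown threshold name(s): ", paste(bad, collapse = ", "),
           call. = FALSE)
    }
    th[names(dots)] <- dots
  }
  structure(th, class = "cvd_thresholds")
}

#' @export
print.cvd_thresholds <- function(x, ...) {
  cat("<cvd_thresholds>\n")
  nm <- names(x)
  for (i in seq_along(x)) cat(sprintf("  %-18s %s\n", nm[i], format(x[[i]])))
  invisible(x)
}

# Risk category machinery -----------------------------------------------

#' Ordered 10-year CVD risk categories
#'
#' Chart risk bands in increasing order of risk: below 10%, 10-20%,
#' 20-30%, 30-40%, above 40%.
#'
#' @return Character vector of the five chart band labels, lowest first.
#' @export
risk_categories <- function() {
  c("LT10", "R10_20", "R20_30", "R30_40", "GT40")
}

#' Ordered adjusted risk categories
#'
#' Chart bands followed by the override categories: clinically high risk
#' (CHR, single extreme risk factor without established CVD), established
#' CVD, and CVD together with CHR-level risk factors. The override
#' categories rank above every chart band: guideline rules treat all of
#' them as exceeding both the 20% and 30% risk gates.
#'
#' @return Character vector of the eight adjusted category labels, lowest
#'   risk first.
#' @export
adjusted_categories <- function() {
  c(risk_categories(), "CHR", "CVD", "CVD_AND_CHR")
}

# integer rank of an adjusted category label (vectorised)
adjusted_rank <- function(x) {
  match(x, adjusted_categories())
}

# risk-band gates used by medication rules: override categories count as
# exceeding both gates
risk_over_20 <- function(adjusted) {
  adjusted_rank(adjusted) >= match("R20_30", adjusted_categories())
}
risk_over_30 <- function(adjusted) {
  r <- adjusted_rank(adjusted)
  r >= match("R30_40", adjusted_categories())
}

# round half away from zero, matching the reporting style of printed
# screening percentages (base round() is round-half-even)
round_half_up <- function(x) {
  floor(x + 0.5)
}
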