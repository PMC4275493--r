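# The guideline rules engine.
#
# Every operation is vectorised over a table of patient records and is a
# pure function of (records, chart, thresholds). Missingness discipline:
# an optional input that is absent never triggers a rule; derived
# variables whose inputs are absent are reported as NA ("not evaluable"),
# never silently defaulted.

# comparison helpers: NA never triggers a criterion
.ge <- function(x, t) !is.na(x) & x >= t
.gt <- function(x, t) !is.na(x) & x > t
.lt <- function(x, t) !is.na(x) & x < t

# keep NA (not evaluable) but treat it as FALSE inside aggregates
.na_false <- function(x) !is.na(x) & x

#' Established cardiovascular disease
#'
#' True when the record reports a history of angina or myocardial
#' infarction, stroke, or peripheral vascular disease.
#'
#' @param records Data frame of patient records (see
#'   [patient_record_columns()]).
#' @return Logical vector, one element per record.
#' @export
established_cvd <- function(records) {
  records$hx_angina_or_mi | records$hx_stroke | records$hx_pvd
}

#' Diabetes status
#'
#' True for a previous diagnosis of diabetes, a fasting capillary
#' glucose of 126 mg/dL or more, or a random glucose of 200 mg/dL or
#' more. Absent glucose values contribute false.
#'
#' @inheritParams established_cvd
#' @param thresholds A [cvd_thresholds()] list.
#' @return Logical vector, one element per record.
#' @export
diabetes_status <- function(records, thresholds = cvd_thresholds()) {
  records$hx_diabetes |
    .ge(records$fasting_glucose, thresholds$fasting_diabetes) |
    .ge(records$random_glucose, thresholds$random_diabetes)
}

#' Clinically-high-risk classification
#'
#' A single extreme risk factor puts a patient at high cardiovascular
#' risk irrespective of the chart band: SBP >= 160 mm Hg, DBP >= 100
#' mm Hg, total cholesterol >= 320 mg/dL, LDL-C >= 240 mg/dL, or a
#' TC/HDL-C ratio strictly above 8. Reasons needing an absent lab value
#' are skipped, not errors. The reasons are recorded for every record;
#' the classification contributes the CHR category only for patients
#' without established CVD (see [assess_risk()]).
#'
#' @inheritParams diabetes_status
#' @return A tibble with `flag` (logical) and `reasons`
#'   (semicolon-joined codes among `SBP>=160; DBP>=100; TC>=320;
#'   LDL>=240; TC/HDL>8`).
#' @export
clinically_high_risk <- function(records, thresholds = cvd_thresholds()) {
  m <- cbind(
    `SBP>=160` = .ge(records$sbp, thresholds$chr_sbp),
    `DBP>=100` = .ge(records$dbp, thresholds$chr_dbp),
    `TC>=320`  = .ge(records$tc, thresholds$chr_tc),
    `LDL>=240` = .ge(records$ldl, thresholds$chr_ldl),
    `TC/HDL>8` = .gt(records$tc / records$hdl, thresholds$chr_ratio)
  )
  tibble::tibble(
    flag = rowSums(m) > 0,
    reasons = apply(m, 1, function(r) paste(colnames(m)[r], collapse = ";"))
  )
}

#' Risk-underestimation flags
#'
#' Conditions under which the chart risk band is considered an
#' underestimate: antihypertensive therapy, obesity (BMI >= 27.5 kg/m^2
#' or central obesity: waist >= 90 cm in males / >= 80 cm in females),
#' family history of premature CHD or stroke, raised triglycerides
#' (> 180 mg/dL), low HDL-C (< 40 mg/dL males, < 50 mg/dL females),
#' fasting dysglycemia (fasting glucose 110-125 mg/dL), and raised
#' resting heart rate (> 100 beats/min). Each flag is evaluated only
#' when its inputs are present.
#'
#' @inheritParams diabetes_status
#' @return A tibble with `flag` (any condition present) and `reasons`
#'   (semicolon-joined codes).
#' @export
underestimation_flags <- function(records, thresholds = cvd_thresholds()) {
  male <- records$sex == "male"
  bmi <- records$weight / (records$height / 100)^2
  central <- ifelse(is.na(records$waist), NA,
                    .ge(records$waist, ifelse(male, thresholds$waist_male,
                                              thresholds$waist_female)))
  obesity <- .ge(bmi, thresholds$bmi_obese) | .na_false(central)
  m <- cbind(
    on_bp_med = records$on_bp_lowering,
    obesity = obesity,
    family_history = records$fam_hx_premature_chd_or_stroke,
    raised_tg = .gt(records$tg, thresholds$tg),
    low_hdl = .lt(records$hdl, ifelse(male, thresholds$hdl_male,
                                      thresholds$hdl_female)),
    fasting_dysglycemia = .ge(records$fasting_glucose,
                              thresholds$dysglycemia_lo) &
      !is.na(records$fasting_glucose) &
      records$fasting_glucose <= thresholds$dysglycemia_hi,
    raised_heart_rate = .gt(records$heart_rate, thresholds$heart_rate)
  )
  tibble::tibble(
    flag = rowSums(m) > 0,
    reasons = apply(m, 1, function(r) paste(colnames(m)[r], collapse = ";"))
  )
}

#' Assess 10-year CVD risk
#'
#' Chart lookup plus the category adjustments: established CVD overrides
#' everything (category `CVD`, or `CVD_AND_CHR` when CHR-level risk
#' factors are also present); clinically high risk without CVD gives
#' `CHR`; otherwise the chart band stands. The high-information chart is
#' used when total cholesterol is measured, the low-information chart
#' otherwise.
#'
#' @inheritParams diabetes_status
#' @param chart A `cvd_chart` object.
#' @return A tibble with `imputed_age`, `pathway`, `chart_category`,
#'   `adjusted_category`, `chr_reasons`, and `underestimation_reasons`.
#' @examples
#' chart <- synthetic_chart()
#' rec <- boundary_suite()[1, ]
#' assess_risk(rec, chart)
#' @export
assess_risk <- function(records, chart, thresholds = cvd_thresholds()) {
  cvd <- established_cvd(records)
  chr <- clinically_high_risk(records, thresholds)
  under <- underestimation_flags(records, thresholds)
  dm <- diabetes_status(records, thresholds)
  look <- lookup_risk(chart, records$sex, dm, records$current_smoker,
                      records$age, records$sbp, records$tc,
                      tc_units = "mg/dL")
  adjusted <- dplyr::case_when(
    cvd & chr$flag ~ "CVD_AND_CHR",
    cvd ~ "CVD",
    chr$flag ~ "CHR",
    TRUE ~ look$category
  )
  tibble::tibble(
    imputed_age = impute_chart_age(records$age),
    pathway = look$pathway,
    chart_category = look$category,
    adjusted_category = adjusted,
    chr_reasons = chr$reasons,
    underestimation_reasons = under$reasons
  )
}

# medication indications ------------------------------------------------

.extreme_lipids <- function(records, thresholds) {
  .ge(records$tc, thresholds$chr_tc) |
    .ge(records$ldl, thresholds$chr_ldl) |
    .gt(records$tc / records$hdl, thresholds$chr_ratio)
}

.reason_join <- function(m) {
  apply(m, 1, function(r) paste(colnames(m)[r], collapse = ";"))
}

#' BP-lowering medication indication
#'
#' Indicated for established CVD; BP >= 160/100 mm Hg; BP >= 140/90 with
#' 10-year risk above 20%; BP >= 130/80 with risk above 30%; or extreme
#' lipids (TC >= 320, LDL-C >= 240, or TC/HDL > 8). Compound BP
#' thresholds are disjunctive (either systolic or diastolic suffices),
#' and the CHR/CVD categories count as exceeding both risk gates.
#'
#' @inheritParams diabetes_status
#' @param assessment Result of [assess_risk()] for the same records.
#' @return A tibble with `flag` and semicolon-joined `reasons`.
#' @export
bp_med_indication <- function(records, assessment,
                              thresholds = cvd_thresholds()) {
  gt20 <- risk_over_20(assessment$adjusted_category)
  gt30 <- risk_over_30(assessment$adjusted_category)
  m <- cbind(
    established_cvd = established_cvd(records),
    bp_160_100 = .ge(records$sbp, thresholds$bp1_sbp) |
      .ge(records$dbp, thresholds$bp1_dbp),
    bp_140_90_risk_gt20 = (.ge(records$sbp, thresholds$bp2_sbp) |
                             .ge(records$dbp, thresholds$bp2_dbp)) & gt20,
    bp_130_80_risk_gt30 = (.ge(records$sbp, thresholds$bp3_sbp) |
                             .ge(records$dbp, thresholds$bp3_dbp)) & gt30,
    extreme_lipids = .extreme_lipids(records, thresholds)
  )
  tibble::tibble(flag = rowSums(m) > 0, reasons = .reason_join(m))
}

#' Statin indication
#'
#' Indicated for established CVD; diabetes (diagnosed or by glucose
#' threshold); extreme lipids; BP >= 160/100; 10-year risk above 30%; or
#' age >= 40 with risk above 20% and TC >= 200 or LDL-C >= 120 mg/dL.
#'
#' @inheritParams bp_med_indication
#' @return A tibble with `flag` and semicolon-joined `reasons`.
#' @export
statin_indication <- function(records, assessment,
                              thresholds = cvd_thresholds()) {
  gt20 <- risk_over_20(assessment$adjusted_category)
  gt30 <- risk_over_30(assessment$adjusted_category)
  m <- cbind(
    established_cvd = established_cvd(records),
    diabetes = diabetes_status(records, thresholds),
    extreme_lipids = .extreme_lipids(records, thresholds),
    bp_160_100 = .ge(records$sbp, thresholds$bp1_sbp) |
      .ge(records$dbp, thresholds$bp1_dbp),
    risk_gt30 = gt30,
    age40_risk_gt20_lipids = records$age >= thresholds$statin_age & gt20 &
      (.ge(records$tc, thresholds$statin_tc) |
         .ge(records$ldl, thresholds$statin_ldl))
  )
  tibble::tibble(flag = rowSums(m) > 0, reasons = .reason_join(m))
}

#' Antiplatelet indication
#'
#' Indicated for established atherosclerotic CVD; extreme lipids;
#' BP >= 160/100; or 10-year risk above 30%.
#'
#' @inheritParams bp_med_indication
#' @return A tibble with `flag` and semicolon-joined `reasons`.
#' @export
antiplatelet_indication <- function(records, assessment,
                                    thresholds = cvd_thresholds()) {
  m <- cbind(
    atherosclerotic_cvd = established_cvd(records),
    extreme_lipids = .extreme_lipids(records, thresholds),
    bp_160_100 = .ge(records$sbp, thresholds$bp1_sbp) |
      .ge(records$dbp, thresholds$bp1_dbp),
    risk_gt30 = risk_over_30(assessment$adjusted_category)
  )
  tibble::tibble(flag = rowSums(m) > 0, reasons = .reason_join(m))
}

#' Treatment targets
#'
#' BP target below 130/80 mm Hg for patients with established CVD,
#' diabetes, or extreme lipids; below 140/90 for all others. Lipid
#' targets by tier: TC < 160, LDL-C < 80, HDL-C > 45 mg/dL with
#' established CVD; TC < 180, LDL-C < 100, HDL-C > 45 with diabetes;
#' TC < 200, LDL-C < 120, HDL-C > 40 otherwise.
#'
#' @inheritParams bp_med_indication
#' @return A tibble with `bp_target_systolic`, `bp_target_diastolic`,
#'   `tc_target`, `ldl_target`, `hdl_target`.
#' @export
treatment_targets <- function(records, assessment,
                              thresholds = cvd_thresholds()) {
  cvd <- established_cvd(records)
  dm <- diabetes_status(records, thresholds)
  tight_bp <- cvd | dm | .extreme_lipids(records, thresholds)
  tibble::tibble(
    bp_target_systolic = ifelse(tight_bp, 130, 140),
    bp_target_diastolic = ifelse(tight_bp, 80, 90),
    tc_target = dplyr::case_when(cvd ~ 160, dm ~ 180, TRUE ~ 200),
    ldl_target = dplyr::case_when(cvd ~ 80, dm ~ 100, TRUE ~ 120),
    hdl_target = dplyr::case_when(cvd | dm ~ 45, TRUE ~ 40)
  )
}

#' Referral and lifestyle advice
#'
#' Referral to the primary health centre is indicated for any adjusted
#' category at or above 20% risk (including CHR/CVD), any medication
#' indication, or newly detected elevated glucose without a prior
#' diabetes diagnosis. Smoking-cessation advice goes to current smokers;
#' diet and physical-activity advice to anyone with the obesity flag,
#' any risk-underestimation condition, or a referral indication.
#'
#' @inheritParams bp_med_indication
#' @param plan A tibble with logical columns `bp_med_indicated`,
#'   `statin_indicated`, `antiplatelet_indicated` for the same records.
#' @return A tibble with `referral_indicated` and `lifestyle_advice`
#'   (semicolon-joined subset of `smoking_cessation; diet;
#'   physical_activity`).
#' @export
referral_and_lifestyle <- function(records, assessment, plan,
                                   thresholds = cvd_thresholds()) {
  dm <- diabetes_status(records, thresholds)
  new_dm <- dm & !records$hx_diabetes
  high_cat <- assessment$adjusted_category %in%
    c("R20_30", "R30_40", "GT40", "CHR", "CVD", "CVD_AND_CHR")
  referral <- high_cat | plan$bp_med_indicated | plan$statin_indicated |
    plan$antiplatelet_indicated | new_dm
  under <- underestimation_flags(records, thresholds)
  male <- records$sex == "male"
  bmi <- records$weight / (records$height / 100)^2
  central <- ifelse(is.na(records$waist), NA,
                    .ge(records$waist, ifelse(male, thresholds$waist_male,
                                              thresholds$waist_female)))
  obesity <- .ge(bmi, thresholds$bmi_obese) | .na_false(central)
  diet_pa <- obesity | under$flag | referral
  m <- cbind(
    smoking_cessation = records$current_smoker,
    diet = diet_pa,
    physical_activity = diet_pa
  )
  tibble::tibble(referral_indicated = referral,
                 lifestyle_advice = .reason_join(m))
}

#' Names of the 42 calculated variables
#'
#' The canonical registry of derived variables the engine computes for
#' every record, in fixed order.
#'
#' @return Character vector of length 42.
#' @export
calculated_variable_names <- function() {
  c("imputed_chart_age", "age_band", "sbp_band", "tc_band", "tc_mmol",
    "tc_hdl_ratio", "bmi", "obesity_flag", "central_obesity_flag",
    "established_cvd", "atherosclerotic_cvd", "diabetes_status",
    "elevated_fasting_glucose", "elevated_random_glucose",
    "elevated_glucose_any", "chr_sbp", "chr_dbp", "chr_tc", "chr_ldl",
    "chr_ratio", "clinically_high_risk", "under_bp_med", "under_obesity",
    "under_fam_hx", "under_tg", "under_hdl", "under_dysglycemia",
    "under_heart_rate", "underestimation_any", "info_pathway",
    "chart_risk_category", "adjusted_risk_category", "bp_med_indicated",
    "statin_indicated", "antiplatelet_indicated", "bp_target_systolic",
    "bp_target_diastolic", "tc_target", "ldl_target", "hdl_target",
    "referral_indicated", "lifestyle_advice_any")
}

#' Compute the 42 calculated variables
#'
#' The full derived-variable vector for each record: banded chart
#' coordinates, derived physiology (BMI, TC/HDL ratio), classification
#' flags, the chart and adjusted risk categories, medication
#' indications, treatment targets, and referral/lifestyle outputs.
#' Variables whose optional inputs are absent are `NA` (not evaluable);
#' aggregate flags treat a not-evaluable contributor as not triggered.
#'
#' @inheritParams assess_risk
#' @return A tibble with `participant_id` plus the 42 columns of
#'   [calculated_variable_names()], one row per record.
#' @examples
#' chart <- synthetic_chart()
#' calculated_variables(boundary_suite()[1:3, ], chart)
#' @export
calculated_variables <- function(records, chart,
                                 thresholds = cvd_thresholds()) {
  records <- validate_records(records)
  th <- thresholds
  male <- records$sex == "male"

  bmi <- records$weight / (records$height / 100)^2
  central <- ifelse(is.na(records$waist), NA,
                    .ge(records$waist,
                        ifelse(male, th$waist_male, th$waist_female)))
  obesity <- .ge(bmi, th$bmi_obese) | .na_false(central)

  tc_mmol <- records$tc / th$mgdl_per_mmol_tc
  ratio <- ifelse(is.na(records$tc) | is.na(records$hdl), NA_real_,
                  records$tc / records$hdl)

  cvd <- established_cvd(records)
  dm <- diabetes_status(records, th)
  elev_f <- ifelse(is.na(records$fasting_glucose), NA,
                   records$fasting_glucose >= th$fasting_diabetes)
  elev_r <- ifelse(is.na(records$random_glucose), NA,
                   records$random_glucose >= th$random_diabetes)
  elev_any <- ifelse(is.na(elev_f) & is.na(elev_r), NA,
                     .na_false(elev_f) | .na_false(elev_r))

  chr_sbp <- records$sbp >= th$chr_sbp
  chr_dbp <- records$dbp >= th$chr_dbp
  chr_tc <- ifelse(is.na(records$tc), NA, records$tc >= th$chr_tc)
  chr_ldl <- ifelse(is.na(records$ldl), NA, records$ldl >= th$chr_ldl)
  chr_ratio <- ifelse(is.na(ratio), NA, ratio > th$chr_ratio)
  chr <- chr_sbp | chr_dbp | .na_false(chr_tc) | .na_false(chr_ldl) |
    .na_false(chr_ratio)

  under <- underestimation_flags(records, th)
  under_tg <- ifelse(is.na(records$tg), NA, records$tg > th$tg)
  under_hdl <- ifelse(is.na(records$hdl), NA,
                      records$hdl < ifelse(male, th$hdl_male, th$hdl_female))
  under_dys <- ifelse(is.na(records$fasting_glucose), NA,
                      records$fasting_glucose >= th$dysglycemia_lo &
                        records$fasting_glucose <= th$dysglycemia_hi)

  assessment <- assess_risk(records, chart, th)
  bp_med <- bp_med_indication(records, assessment, th)
  statin <- statin_indication(records, assessment, th)
  anti <- antiplatelet_indication(records, assessment, th)
  targets <- treatment_targets(records, assessment, th)
  plan <- tibble::tibble(bp_med_indicated = bp_med$flag,
                         statin_indicated = statin$flag,
                         antiplatelet_indicated = anti$flag)
  refer <- referral_and_lifestyle(records, assessment, plan, th)

  tibble::tibble(
    participant_id = records$participant_id,
    imputed_chart_age = assessment$imputed_age,
    age_band = band_index(assessment$imputed_age, chart$axes$age),
    sbp_band = band_index(pmax(chart$axes$sbp[1], records$sbp),
                          chart$axes$sbp),
    tc_band = ifelse(is.na(records$tc), NA_integer_,
                     band_index(tc_mmol, chart$axes$tc)),
    tc_mmol = tc_mmol,
    tc_hdl_ratio = ratio,
    bmi = bmi,
    obesity_flag = obesity,
    central_obesity_flag = central,
    established_cvd = cvd,
    atherosclerotic_cvd = cvd,
    diabetes_status = dm,
    elevated_fasting_glucose = elev_f,
    elevated_random_glucose = elev_r,
    elevated_glucose_any = elev_any,
    chr_sbp = chr_sbp,
    chr_dbp = chr_dbp,
    chr_tc = chr_tc,
    chr_ldl = chr_ldl,
    chr_ratio = chr_ratio,
    clinically_high_risk = chr,
    under_bp_med = records$on_bp_lowering,
    under_obesity = obesity,
    under_fam_hx = records$fam_hx_premature_chd_or_stroke,
    under_tg = under_tg,
    under_hdl = under_hdl,
    under_dysglycemia = under_dys,
    under_heart_rate = records$heart_rate > th$heart_rate,
    underestimation_any = under$flag,
    info_pathway = assessment$pathway,
    chart_risk_category = assessment$chart_category,
    adjusted_risk_category = assessment$adjusted_category,
    bp_med_indicated = bp_med$flag,
    statin_indicated = statin$flag,
    antiplatelet_indicated = anti$flag,
    bp_target_systolic = targets$bp_target_systolic,
    bp_target_diastolic = targets$bp_target_diastolic,
    tc_target = targets$tc_target,
    ldl_target = targets$ldl_target,
    hdl_target = targets$hdl_target,
    referral_indicated = refer$referral_indicated,
    lifestyle_advice_any = refer$lifestyle_advice != ""
  )
}

#' Assess a screening cohort
#'
#' The main entry point: runs the full rules engine over a table of
#' patient records and returns the input columns together with all 42
#' calculated variables and the reason codes behind each classification
#' and indication (semicolon-joined).
#'
#' @inheritParams assess_risk
#' @return A tibble with the 28 input columns, the 42 calculated
#'   variables, and reason columns `chr_reasons`, `underestimation_reasons`,
#'   `bp_med_reasons`, `statin_reasons`, `antiplatelet_reasons`,
#'   `lifestyle_advice`.
#' @examples
#' chart <- synthetic_chart()
#' cohort <- generate_cohort(20, seed = 1)
#' out <- assess_cohort(cohort, chart)
#' dplyr::count(out, adjusted_risk_category)
#' @export
assess_cohort <- function(records, chart, thresholds = cvd_thresholds()) {
  records <- validate_records(records)
  calc <- calculated_variables(records, chart, thresholds)
  assessment <- assess_risk(records, chart, thresholds)
  bp_med <- bp_med_indication(records, assessment, thresholds)
  statin <- statin_indication(records, assessment, thresholds)
  anti <- antiplatelet_indication(records, assessment, thresholds)
  plan <- tibble::tibble(bp_med_indicated = bp_med$flag,
                         statin_indicated = statin$flag,
                         antiplatelet_indicated = anti$flag)
  refer <- referral_and_lifestyle(records, assessment, plan, thresholds)
  dplyr::bind_cols(
    records,
    calc[calculated_variable_names()],
    tibble::tibble(
      chr_reasons = assessment$chr_reasons,
      underestimation_reasons = assessment$underestimation_reasons,
      bp_med_reasons = bp_med$reasons,
      statin_reasons = statin$reasons,
      antiplatelet_reasons = anti$reasons,
      lifestyle_advice = refer$lifestyle_advice
    )
  )
}

#' Single-patient assessment report
#'
#' Formats one assessed record as a human-readable key-value report.
#'
#' @param assessed One row of [assess_cohort()] output.
#' @return Character vector of report lines, invisibly; also printed.
#' @export
patient_report <- function(assessed) {
  stopifnot(nrow(assessed) == 1)
  fmt <- function(x) {
    if (is.logical(x)) return(ifelse(is.na(x), "not evaluable",
                                     ifelse(x, "yes", "no")))
    ifelse(is.na(x), "not evaluable", format(x, digits = 4))
  }
  keys <- c("participant_id", "age", "sex", "sbp", "dbp",
            "info_pathway", "chart_risk_category", "adjusted_risk_category",
            "chr_reasons", "underestimation_reasons",
            "bp_med_indicated", "bp_med_reasons",
            "statin_indicated", "statin_reasons",
            "antiplatelet_indicated", "antiplatelet_reasons",
            "bp_target_systolic", "bp_target_diastolic",
            "tc_target", "ldl_target", "hdl_target",
            "referral_indicated", "lifestyle_advice")
  lines <- vapply(keys, function(k) {
    sprintf("%-26s: %s", k, fmt(assessed[[k]][1]))
  }, character(1))
  cat(lines, sep = "\n")
  invisible(lines)
}
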