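chart <- fixture_chart()

test_that("established CVD is any of angina/MI, stroke, PVD history", {
  recs <- make_records(
    list(hx_stroke = TRUE),
    list(hx_pvd = TRUE),
    list(hx_angina_or_mi = TRUE),
    list()
  )
  expect_equal(established_cvd(recs), c(TRUE, TRUE, TRUE, FALSE))
})

test_that("clinically-high-risk fires at its printed cut-points and not below", {
  at <- make_record(sbp = 160, dbp = 80)
  expect_true(clinically_high_risk(at)$flag)
  expect_equal(clinically_high_risk(at)$reasons, "SBP>=160")

  # every criterion one unit on the strict side: flag must stay off
  below <- make_record(sbp = 159, dbp = 99, tc = 319, ldl = 239, hdl = 39.875)
  stopifnot(below$tc / below$hdl == 8)  # ratio exactly 8 is not > 8
  out <- clinically_high_risk(below)
  expect_false(out$flag)
  expect_equal(out$reasons, "")

  # single-criterion case with a missing co-input: ratio is skipped
  tc_only <- make_record(tc = 320, hdl = NA_real_, ldl = NA_real_,
                         tg = NA_real_)
  out2 <- clinically_high_risk(tc_only)
  expect_true(out2$flag)
  expect_equal(out2$reasons, "TC>=320")
})

test_that("underestimation flags respect operators and sex-specific cut-offs", {
  get_reasons <- function(...) underestimation_flags(make_record(...))$reasons
  expect_match(get_reasons(heart_rate = 101), "raised_heart_rate")
  expect_no_match(get_reasons(heart_rate = 100), "raised_heart_rate")
  expect_match(get_reasons(sex = "male", hdl = 39), "low_hdl")
  expect_no_match(get_reasons(sex = "male", hdl = 40), "low_hdl")
  expect_match(get_reasons(sex = "female", hdl = 49), "low_hdl")
  expect_no_match(get_reasons(sex = "female", hdl = 50), "low_hdl")
  expect_match(get_reasons(tg = 181), "raised_tg")
  expect_no_match(get_reasons(tg = 180), "raised_tg")
  expect_match(get_reasons(fasting_glucose = 110), "fasting_dysglycemia")
  expect_match(get_reasons(fasting_glucose = 125), "fasting_dysglycemia")
  expect_no_match(get_reasons(fasting_glucose = 126), "fasting_dysglycemia")
  expect_match(get_reasons(on_bp_lowering = TRUE), "on_bp_med")
  expect_match(get_reasons(fam_hx_premature_chd_or_stroke = TRUE),
               "family_history")
  # obesity by BMI (27.5 kg/m^2 at height 160 cm is ~70.4 kg) and by waist
  expect_match(get_reasons(weight = 70.5), "obesity")
  expect_no_match(get_reasons(weight = 70.0), "obesity")
  expect_match(get_reasons(sex = "female", waist = 80), "obesity")
  expect_match(get_reasons(sex = "male", waist = 90), "obesity")
  expect_no_match(get_reasons(sex = "male", waist = 89), "obesity")
})

test_that("diabetes status combines history with glucose thresholds", {
  expect_true(diabetes_status(make_record(fasting_glucose = 126)))
  expect_false(diabetes_status(make_record(fasting_glucose = 125)))
  expect_false(diabetes_status(make_record(glucose_is_fasting = FALSE,
                                           fasting_glucose = NA_real_,
                                           random_glucose = 199)))
  expect_true(diabetes_status(make_record(glucose_is_fasting = FALSE,
                                          fasting_glucose = NA_real_,
                                          random_glucose = 200)))
  expect_true(diabetes_status(make_record(hx_diabetes = TRUE,
                                          fasting_glucose = NA_real_)))
})

test_that("adjusted category layers CVD and CHR over the chart band", {
  both <- assess_risk(make_record(hx_stroke = TRUE, sbp = 170), chart)
  expect_equal(both$adjusted_category, "CVD_AND_CHR")
  cvd_only <- assess_risk(make_record(hx_stroke = TRUE), chart)
  expect_equal(cvd_only$adjusted_category, "CVD")
  chr_only <- assess_risk(make_record(sbp = 170), chart)
  expect_equal(chr_only$adjusted_category, "CHR")
  plain <- assess_risk(make_record(), chart)
  expect_equal(plain$adjusted_category, plain$chart_category)
})

test_that("BP medication rules combine BP tiers with risk gates", {
  # chart band R20_30 via age 65 + SBP 145 + TC 271 (female non-smoker)
  r1 <- make_record(age = 65, sbp = 145, dbp = 88, tc = 271)
  a1 <- assess_risk(r1, chart)
  expect_equal(a1$adjusted_category, "R20_30")
  out1 <- bp_med_indication(r1, a1)
  expect_true(out1$flag)
  expect_equal(out1$reasons, "bp_140_90_risk_gt20")

  # R30_40 via age 75 + smoker + TC 271 at SBP 132
  r2 <- make_record(age = 75, sbp = 132, dbp = 78, current_smoker = TRUE,
                    tc = 271)
  a2 <- assess_risk(r2, chart)
  expect_equal(a2$adjusted_category, "R30_40")
  out2 <- bp_med_indication(r2, a2)
  expect_true(out2$flag)
  expect_equal(out2$reasons, "bp_130_80_risk_gt30")

  r3 <- make_record(sbp = 128, dbp = 78)
  a3 <- assess_risk(r3, chart)
  expect_false(bp_med_indication(r3, a3)$flag)
})

test_that("statin rules apply the age-40 gate on the moderate-risk lipid arm", {
  r1 <- make_record(age = 45, sex = "male", current_smoker = TRUE,
                    sbp = 145, tc = 271)
  a1 <- assess_risk(r1, chart)
  expect_equal(a1$adjusted_category, "R20_30")
  out1 <- statin_indication(r1, a1)
  expect_true(out1$flag)
  expect_equal(out1$reasons, "age40_risk_gt20_lipids")

  r2 <- make_record(age = 39, sex = "male", current_smoker = TRUE,
                    sbp = 145, tc = 271)
  a2 <- assess_risk(r2, chart)
  expect_equal(a2$adjusted_category, "R20_30")  # chart age imputed to 40
  expect_false(statin_indication(r2, a2)$flag)  # raw age misses the gate

  r3 <- make_record(hx_diabetes = TRUE)
  out3 <- statin_indication(r3, assess_risk(r3, chart))
  expect_true(out3$flag)
  expect_match(out3$reasons, "diabetes")
})

test_that("antiplatelet indication needs risk strictly above 30% absent other criteria", {
  r_hi <- make_record(sex = "male", age = 75, sbp = 118, dbp = 76, tc = 271)
  a_hi <- assess_risk(r_hi, chart)
  expect_equal(a_hi$adjusted_category, "R30_40")
  out_hi <- antiplatelet_indication(r_hi, a_hi)
  expect_true(out_hi$flag)
  expect_equal(out_hi$reasons, "risk_gt30")

  r_mid <- make_record(sex = "male", age = 65, sbp = 118, dbp = 76, tc = 271)
  a_mid <- assess_risk(r_mid, chart)
  expect_equal(a_mid$adjusted_category, "R20_30")
  expect_false(antiplatelet_indication(r_mid, a_mid)$flag)

  r_cvd <- make_record(hx_angina_or_mi = TRUE)
  expect_true(antiplatelet_indication(r_cvd, assess_risk(r_cvd, chart))$flag)
})

test_that("treatment targets tier by CVD, diabetes, then default", {
  tt <- function(...) {
    r <- make_record(...)
    treatment_targets(r, assess_risk(r, chart))
  }
  cvd <- tt(hx_stroke = TRUE)
  expect_equal(c(cvd$bp_target_systolic, cvd$bp_target_diastolic), c(130, 80))
  expect_equal(c(cvd$tc_target, cvd$ldl_target, cvd$hdl_target),
               c(160, 80, 45))
  plain <- tt()
  expect_equal(c(plain$bp_target_systolic, plain$bp_target_diastolic),
               c(140, 90))
  expect_equal(plain$tc_target, 200)
  dm <- tt(hx_diabetes = TRUE)
  expect_equal(c(dm$bp_target_systolic, dm$bp_target_diastolic), c(130, 80))
  expect_equal(c(dm$tc_target, dm$ldl_target, dm$hdl_target), c(180, 100, 45))
})

test_that("referral and lifestyle advice follow risk, indications, and smoking", {
  run <- function(...) {
    r <- make_record(...)
    a <- assess_risk(r, chart)
    bp <- bp_med_indication(r, a); st <- statin_indication(r, a)
    ap <- antiplatelet_indication(r, a)
    plan <- tibble::tibble(bp_med_indicated = bp$flag,
                           statin_indicated = st$flag,
                           antiplatelet_indicated = ap$flag)
    referral_and_lifestyle(r, a, plan)
  }
  smoker <- run(current_smoker = TRUE)
  expect_match(smoker$lifestyle_advice, "smoking_cessation")
  chr <- run(sbp = 170)
  expect_true(chr$referral_indicated)
  clean <- run()
  expect_false(clean$referral_indicated)
  expect_equal(clean$lifestyle_advice, "")
  # newly detected elevated glucose refers even at low chart risk
  new_dm <- run(fasting_glucose = 130)
  expect_true(new_dm$referral_indicated)
})

test_that("calculated variables form the complete 42-entry registry", {
  expect_length(calculated_variable_names(), 42)
  out <- calculated_variables(make_record(), chart)
  expect_equal(setdiff(names(out), "participant_id"),
               calculated_variable_names())

  # a complete record evaluates every entry
  complete <- calculated_variables(
    make_record(waist = 80, random_glucose = 150), chart)
  expect_true(all(!is.na(complete[calculated_variable_names()])))

  # without cholesterol: low-information pathway, lipid derivations NA
  no_tc <- calculated_variables(
    make_record(tc = NA_real_, ldl = NA_real_, hdl = NA_real_,
                tg = NA_real_), chart)
  expect_equal(no_tc$info_pathway, "low_info")
  for (v in c("tc_band", "tc_mmol", "tc_hdl_ratio", "chr_tc", "chr_ldl",
              "chr_ratio", "under_tg", "under_hdl")) {
    expect_true(is.na(no_tc[[v]]), label = v)
  }
})

test_that("record validation enforces schema and physiologic domains", {
  expect_error(validate_records(make_record(age = 15)), "age")
  expect_error(validate_records(make_record(sbp = 310)), "sbp")
  expect_error(validate_records(make_record(dbp = 130, sbp = 120)),
               "dbp must be below sbp")
  expect_error(validate_records(make_record(heart_rate = 10)), "heart_rate")
  expect_error(validate_records(make_record(tc = -5)), "negative tc")
  expect_error(validate_records(make_record()[, -5]), "missing column")
  expect_length(patient_record_columns(), 28)
})
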