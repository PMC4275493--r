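# Shared fixtures: the bundled monotone chart and a record constructor.

fixture_chart <- function() synthetic_chart()

# one healthy baseline record; override any field by name
make_record <- function(...) {
  rec <- tibble::tibble(
    participant_id = "T001", assessment_date = "2026-01-15",
    assessor_role = "NPHW", village_code = "V01",
    age = 55, sex = "female", current_smoker = FALSE,
    hx_angina_or_mi = FALSE, hx_stroke = FALSE, hx_pvd = FALSE,
    hx_diabetes = FALSE, fam_hx_premature_chd_or_stroke = FALSE,
    on_bp_lowering = FALSE, on_lipid_lowering = FALSE,
    on_antiplatelet = FALSE,
    sbp = 120, dbp = 78, heart_rate = 72, height = 160, weight = 60,
    waist = 75, glucose_is_fasting = TRUE, fasting_glucose = 95,
    random_glucose = NA_real_, tc = 170, ldl = 95, hdl = 55, tg = 120
  )
  dots <- list(...)
  for (nm in names(dots)) rec[[nm]] <- dots[[nm]]
  rec
}

# several records built from per-field override lists
make_records <- function(...) {
  dplyr::bind_rows(purrr::imap(list(...), function(ov, i) {
    r <- do.call(make_record, as.list(ov))
    r$participant_id <- sprintf("T%03d", i)
    r
  }))
}
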