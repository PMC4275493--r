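# Patient record schema and validation.

#' Canonical patient record columns
#'
#' The 28 raw inputs collected at a screening visit, in canonical order:
#' identifiers and visit metadata, demographics, past history and
#' medication flags, physical measurements, and optional point-of-care
#' laboratory values. Optional fields (`waist`, the glucose fields, and
#' the four lipid fields) may be `NA`; a rule that needs an absent value
#' is never triggered by it.
#'
#' @return Character vector of the 28 column names.
#' @export
patient_record_columns <- function() {
  c("participant_id", "assessment_date", "assessor_role", "village_code",
    "age", "sex", "current_smoker",
    "hx_angina_or_mi", "hx_stroke", "hx_pvd", "hx_diabetes",
    "fam_hx_premature_chd_or_stroke",
    "on_bp_lowering", "on_lipid_lowering", "on_antiplatelet",
    "sbp", "dbp", "heart_rate", "height", "weight", "waist",
    "glucose_is_fasting", "fasting_glucose", "random_glucose",
    "tc", "ldl", "hdl", "tg")
}

.optional_record_columns <- function() {
  c("waist", "glucose_is_fasting", "fasting_glucose", "random_glucose",
    "tc", "ldl", "hdl", "tg")
}

#' Validate a table of patient records
#'
#' Checks the canonical 28-column schema and the physiologic domain
#' invariants: age in \[18, 110\] years, SBP in \[60, 300\] and DBP in
#' \[30, 200\] mm Hg with DBP < SBP, heart rate in \[20, 250\] beats/min,
#' and all laboratory values non-negative where present.
#'
#' @param records Data frame of patient records.
#' @return The records as a tibble, invisibly usable downstream; errors
#'   on the first violated invariant, naming the offending rows.
#' @export
validate_records <- function(records) {
  records <- tibble::as_tibble(records)
  missing_cols <- setdiff(patient_record_columns(), names(records))
  if (length(missing_cols)) {
    stop("patient records are missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  required <- setdiff(patient_record_columns(), .optional_record_columns())
  for (col in required) {
    if (anyNA(records[[col]])) {
      stop("required column '", col, "' has missing values (rows ",
           paste(utils::head(which(is.na(records[[col]])), 5),
                 collapse = ", "), ")", call. = FALSE)
    }
  }
  fail <- function(cond, what) {
    bad <- which(cond)
    if (length(bad)) {
      stop(what, " (rows ", paste(utils::head(bad, 5), collapse = ", "), ")",
           call. = FALSE)
    }
  }
  fail(records$age < 18 | records$age > 110, "age outside [18, 110] years")
  fail(records$sbp < 60 | records$sbp > 300, "sbp outside [60, 300] mm Hg")
  fail(records$dbp < 30 | records$dbp > 200, "dbp outside [30, 200] mm Hg")
  fail(records$dbp >= records$sbp, "dbp must be below sbp")
  fail(records$heart_rate < 20 | records$heart_rate > 250,
       "heart_rate outside [20, 250] beats/min")
  fail(!(records$sex %in% c("male", "female")),
       "sex must be 'male' or 'female'")
  for (col in c("fasting_glucose", "random_glucose", "tc", "ldl", "hdl",
                "tg", "waist")) {
    fail(!is.na(records[[col]]) & records[[col]] < 0,
         paste0("negative ", col))
  }
  records
}

#' Read patient records from a delimited text file
#'
#' Comma-separated with a header row carrying the canonical 28 column
#' names ([patient_record_columns()]); an empty field means missing.
#' Malformed rows (wrong field count, unparsable numbers, or violated
#' domain invariants) are dropped with a warning naming their line
#' numbers, mirroring the error-tolerant handling field data entry
#' requires; the file as a whole fails only if unreadable.
#'
#' @param path Path to the patient CSV file.
#' @return A tibble of validated records, with an attribute
#'   `"n_rejected"` giving the number of dropped rows.
#' @export
read_patient_records <- function(path) {
  raw <- readr::read_csv(
    path, comment = "#", show_col_types = FALSE, progress = FALSE,
    col_types = readr::cols(
      participant_id = readr::col_character(),
      assessment_date = readr::col_character(),
      assessor_role = readr::col_character(),
      village_code = readr::col_character(),
      sex = readr::col_character(),
      .default = readr::col_double()
    )
  )
  missing_cols <- setdiff(patient_record_columns(), names(raw))
  if (length(missing_cols)) {
    stop("patient file is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  prob <- readr::problems(raw)
  bad_rows <- integer(0)
  if (nrow(prob)) bad_rows <- unique(prob$row)
  for (col in c("current_smoker", "hx_angina_or_mi", "hx_stroke", "hx_pvd",
                "hx_diabetes", "fam_hx_premature_chd_or_stroke",
                "on_bp_lowering", "on_lipid_lowering", "on_antiplatelet",
                "glucose_is_fasting")) {
    raw[[col]] <- !is.na(raw[[col]]) & raw[[col]] != 0
  }
  # row-level invariant screen: drop rows a strict validator would reject
  ok <- !is.na(raw$age) & raw$age >= 18 & raw$age <= 110 &
    !is.na(raw$sbp) & raw$sbp >= 60 & raw$sbp <= 300 &
    !is.na(raw$dbp) & raw$dbp >= 30 & raw$dbp <= 200 & raw$dbp < raw$sbp &
    !is.na(raw$heart_rate) & raw$heart_rate >= 20 & raw$heart_rate <= 250 &
    raw$sex %in% c("male", "female") &
    !is.na(raw$height) & !is.na(raw$weight)
  for (col in c("fasting_glucose", "random_glucose", "tc", "ldl", "hdl",
                "tg", "waist")) {
    ok <- ok & (is.na(raw[[col]]) | raw[[col]] >= 0)
  }
  bad_rows <- sort(union(bad_rows, which(!ok)))
  if (length(bad_rows)) {
    warning(length(bad_rows), " malformed row(s) dropped (data rows: ",
            paste(utils::head(bad_rows, 10), collapse = ", "), ")",
            call. = FALSE)
    raw <- raw[-bad_rows, , drop = FALSE]
  }
  out <- validate_records(raw[patient_record_columns()])
  attr(out, "n_rejected") <- length(bad_rows)
  out
}

#' Write patient records to a delimited text file
#'
#' @param records Data frame of patient records.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_patient_records <- function(records, path) {
  records <- tibble::as_tibble(records)[patient_record_columns()]
  for (col in c("current_smoker", "hx_angina_or_mi", "hx_stroke", "hx_pvd",
                "hx_diabetes", "fam_hx_premature_chd_or_stroke",
                "on_bp_lowering", "on_lipid_lowering", "on_antiplatelet",
                "glucose_is_fasting")) {
    records[[col]] <- as.integer(records[[col]])
  }
  readr::write_csv(records, path, na = "")
  invisible(path)
}
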