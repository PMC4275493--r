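# Dual-implementation validation harness.
#
# oracle_assess() is an independently coded, record-at-a-time decision
# table: every guideline cut-point is written out literally, the chart
# is read by scanning its cell table row by row, and no engine helper is
# reused. Contract-level equality with calculated_variables() is the
# validation endpoint; sharing no code path with the engine is the point.

# scan the chart cell table directly for one patient; no band arithmetic
.oracle_chart_read <- function(chart, pathway, sex, diabetes, smoking,
                               chart_age, sbp, tc_mmol) {
  cells <- chart$cells[chart$cells$pathway == pathway &
                         chart$cells$sex == sex &
                         chart$cells$diabetes == diabetes &
                         chart$cells$smoking == smoking, , drop = FALSE]
  hit <- rep(TRUE, nrow(cells))
  hit <- hit & cells$age_lo <= chart_age & chart_age < cells$age_hi
  s <- max(sbp, min(cells$sbp_lo))
  hit <- hit & cells$sbp_lo <= s & s < cells$sbp_hi
  if (pathway == "high_info") {
    hit <- hit & cells$tc_lo <= tc_mmol & tc_mmol < cells$tc_hi
  }
  cat_hit <- cells$category[hit]
  if (length(cat_hit) != 1) {
    stop("oracle chart read matched ", length(cat_hit), " cells",
         call. = FALSE)
  }
  cat_hit
}

.oracle_one <- function(r, chart) {
  # r: one-row data frame. Flat re-derivation of all 42 variables.
  out <- list(participant_id = r$participant_id)

  # chart age: clamp into [40, 79]
  a <- r$age
  if (a < 40) a <- 40
  if (a > 79) a <- 79
  out$imputed_chart_age <- a

  if (a < 50) out$age_band <- 1L
  else if (a < 60) out$age_band <- 2L
  else if (a < 70) out$age_band <- 3L
  else out$age_band <- 4L

  if (r$sbp < 140) out$sbp_band <- 1L
  else if (r$sbp < 160) out$sbp_band <- 2L
  else if (r$sbp < 180) out$sbp_band <- 3L
  else out$sbp_band <- 4L

  tc_mmol <- if (is.na(r$tc)) NA_real_ else r$tc / 38.67
  out$tc_mmol <- tc_mmol
  if (is.na(tc_mmol)) {
    out$tc_band <- NA_integer_
  } else if (tc_mmol < 4) out$tc_band <- 1L
  else if (tc_mmol < 5) out$tc_band <- 2L
  else if (tc_mmol < 6) out$tc_band <- 3L
  else if (tc_mmol < 7) out$tc_band <- 4L
  else out$tc_band <- 5L

  ratio <- if (is.na(r$tc) || is.na(r$hdl)) NA_real_ else r$tc / r$hdl
  out$tc_hdl_ratio <- ratio

  bmi <- r$weight / (r$height / 100)^2
  out$bmi <- bmi

  central <- if (is.na(r$waist)) {
    NA
  } else if (r$sex == "male") {
    r$waist >= 90
  } else {
    r$waist >= 80
  }
  out$central_obesity_flag <- central
  obesity <- bmi >= 27.5 || isTRUE(central)
  out$obesity_flag <- obesity

  cvd <- isTRUE(r$hx_angina_or_mi) || isTRUE(r$hx_stroke) ||
    isTRUE(r$hx_pvd)
  out$established_cvd <- cvd
  out$atherosclerotic_cvd <- cvd

  elev_f <- if (is.na(r$fasting_glucose)) NA else r$fasting_glucose >= 126
  elev_r <- if (is.na(r$random_glucose)) NA else r$random_glucose >= 200
  out$elevated_fasting_glucose <- elev_f
  out$elevated_random_glucose <- elev_r
  out$elevated_glucose_any <- if (is.na(elev_f) && is.na(elev_r)) {
    NA
  } else {
    isTRUE(elev_f) || isTRUE(elev_r)
  }
  dm <- isTRUE(r$hx_diabetes) || isTRUE(elev_f) || isTRUE(elev_r)
  out$diabetes_status <- dm

  chr_sbp <- r$sbp >= 160
  chr_dbp <- r$dbp >= 100
  chr_tc <- if (is.na(r$tc)) NA else r$tc >= 320
  chr_ldl <- if (is.na(r$ldl)) NA else r$ldl >= 240
  chr_ratio <- if (is.na(ratio)) NA else ratio > 8
  out$chr_sbp <- chr_sbp; out$chr_dbp <- chr_dbp
  out$chr_tc <- chr_tc; out$chr_ldl <- chr_ldl; out$chr_ratio <- chr_ratio
  chr <- chr_sbp || chr_dbp || isTRUE(chr_tc) || isTRUE(chr_ldl) ||
    isTRUE(chr_ratio)
  out$clinically_high_risk <- chr

  out$under_bp_med <- isTRUE(r$on_bp_lowering)
  out$under_obesity <- obesity
  out$under_fam_hx <- isTRUE(r$fam_hx_premature_chd_or_stroke)
  out$under_tg <- if (is.na(r$tg)) NA else r$tg > 180
  out$under_hdl <- if (is.na(r$hdl)) {
    NA
  } else if (r$sex == "male") {
    r$hdl < 40
  } else {
    r$hdl < 50
  }
  out$under_dysglycemia <- if (is.na(r$fasting_glucose)) {
    NA
  } else {
    r$fasting_glucose >= 110 && r$fasting_glucose <= 125
  }
  out$under_heart_rate <- r$heart_rate > 100
  out$underestimation_any <- out$under_bp_med || obesity ||
    out$under_fam_hx || isTRUE(out$under_tg) || isTRUE(out$under_hdl) ||
    isTRUE(out$under_dysglycemia) || out$under_heart_rate

  pathway <- if (is.na(r$tc)) "low_info" else "high_info"
  out$info_pathway <- pathway
  chart_cat <- .oracle_chart_read(chart, pathway, r$sex, dm,
                                  isTRUE(r$current_smoker), a, r$sbp,
                                  tc_mmol)
  out$chart_risk_category <- chart_cat

  adjusted <- if (cvd && chr) {
    "CVD_AND_CHR"
  } else if (cvd) {
    "CVD"
  } else if (chr) {
    "CHR"
  } else {
    chart_cat
  }
  out$adjusted_risk_category <- adjusted

  gt20 <- adjusted %in% c("R20_30", "R30_40", "GT40", "CHR", "CVD",
                          "CVD_AND_CHR")
  gt30 <- adjusted %in% c("R30_40", "GT40", "CHR", "CVD", "CVD_AND_CHR")
  lipid_extreme <- isTRUE(chr_tc) || isTRUE(chr_ldl) || isTRUE(chr_ratio)
  bp160 <- r$sbp >= 160 || r$dbp >= 100

  out$bp_med_indicated <- cvd || bp160 ||
    ((r$sbp >= 140 || r$dbp >= 90) && gt20) ||
    ((r$sbp >= 130 || r$dbp >= 80) && gt30) ||
    lipid_extreme
  out$statin_indicated <- cvd || dm || lipid_extreme || bp160 || gt30 ||
    (r$age >= 40 && gt20 &&
       (isTRUE(!is.na(r$tc) && r$tc >= 200) ||
          isTRUE(!is.na(r$ldl) && r$ldl >= 120)))
  out$antiplatelet_indicated <- cvd || lipid_extreme || bp160 || gt30

  tight <- cvd || dm || lipid_extreme
  out$bp_target_systolic <- if (tight) 130 else 140
  out$bp_target_diastolic <- if (tight) 80 else 90
  if (cvd) {
    out$tc_target <- 160; out$ldl_target <- 80; out$hdl_target <- 45
  } else if (dm) {
    out$tc_target <- 180; out$ldl_target <- 100; out$hdl_target <- 45
  } else {
    out$tc_target <- 200; out$ldl_target <- 120; out$hdl_target <- 40
  }

  referral <- adjusted %in% c("R20_30", "R30_40", "GT40", "CHR", "CVD",
                              "CVD_AND_CHR") ||
    out$bp_med_indicated || out$statin_indicated ||
    out$antiplatelet_indicated || (dm && !isTRUE(r$hx_diabetes))
  out$referral_indicated <- referral

  diet_pa <- obesity || out$underestimation_any || referral
  out$lifestyle_advice_any <- isTRUE(r$current_smoker) || diet_pa

  out
}

#' Independently coded oracle assessment
#'
#' Recomputes the 42 calculated variables with a flat, exhaustively
#' enumerated decision table that shares no code with the rules engine:
#' thresholds are literal constants, the risk chart is read by scanning
#' its cell table, and each record is processed individually. Used by
#' [compare_cohort()] as the second implementation in dual-programming
#' validation.
#'
#' @inheritParams assess_risk
#' @return A tibble with the same columns as [calculated_variables()].
#' @export
oracle_assess <- function(records, chart) {
  records <- validate_records(records)
  rows <- purrr::map(seq_len(nrow(records)), function(i) {
    tibble::as_tibble(.oracle_one(records[i, ], chart))
  })
  dplyr::bind_rows(rows)
}

# variables compared with an absolute floating-point tolerance
.float_variables <- function() c("tc_mmol", "tc_hdl_ratio", "bmi")

#' Compare engine and oracle over a cohort
#'
#' Runs both implementations on every record and reports per-variable
#' agreement. Two values agree when both are not-evaluable (`NA`), or
#' both present and equal — exactly for categorical, flag, and target
#' variables; within an absolute tolerance of 1e-9 for the
#' floating-point derivations (BMI, TC in mmol/L, TC/HDL ratio).
#'
#' @inheritParams assess_risk
#' @param engine The engine function to validate; swap in a deliberately
#'   perturbed engine for mutation testing. Must accept
#'   `(records, chart)` and return the [calculated_variables()] schema.
#' @param tol Absolute tolerance for floating-point variables.
#' @return An object of class `cvd_agreement`: a list with `n_records`,
#'   `per_variable_agreement` (named fractions), `n_variables_fully_agreeing`,
#'   and a `discrepancies` tibble ordered by (record, variable).
#' @examples
#' chart <- synthetic_chart()
#' rep <- compare_cohort(boundary_suite(), chart)
#' rep$n_variables_fully_agreeing
#' @export
compare_cohort <- function(records, chart, engine = calculated_variables,
                           tol = 1e-9) {
  records <- validate_records(records)
  if (nrow(records) < 1) stop("cohort must contain at least one record",
                              call. = FALSE)
  eng <- engine(records, chart)
  ora <- oracle_assess(records, chart)
  vars <- calculated_variable_names()
  fmt_val <- function(x) ifelse(is.na(x), "NA", as.character(x))

  agree_frac <- stats::setNames(numeric(length(vars)), vars)
  disc <- list()
  for (v in vars) {
    e <- eng[[v]]; o <- ora[[v]]
    if (v %in% .float_variables()) {
      same <- (is.na(e) & is.na(o)) |
        (!is.na(e) & !is.na(o) & abs(e - o) <= tol)
    } else {
      same <- (is.na(e) & is.na(o)) | (!is.na(e) & !is.na(o) & e == o)
    }
    agree_frac[v] <- mean(same)
    if (any(!same)) {
      bad <- which(!same)
      disc[[v]] <- tibble::tibble(
        record_id = records$participant_id[bad],
        variable = v,
        engine_value = fmt_val(e[bad]),
        oracle_value = fmt_val(o[bad])
      )
    }
  }
  disc <- dplyr::bind_rows(disc)
  if (!nrow(disc)) {
    disc <- tibble::tibble(record_id = character(), variable = character(),
                           engine_value = character(),
                           oracle_value = character())
  }
  disc <- dplyr::arrange(disc, .data$record_id, .data$variable)
  structure(
    list(
      n_records = nrow(records),
      per_variable_agreement = agree_frac,
      n_variables_fully_agreeing = sum(agree_frac == 1),
      discrepancies = disc
    ),
    class = "cvd_agreement"
  )
}

#' @export
print.cvd_agreement <- function(x, ...) {
  nv <- length(x$per_variable_agreement)
  cat(sprintf("<cvd_agreement> %d records, %d/%d variables in full agreement (%.0f%%)\n",
              x$n_records, x$n_variables_fully_agreeing, nv,
              100 * x$n_variables_fully_agreeing / nv))
  if (nrow(x$discrepancies)) {
    cat(sprintf("  %d discrepancies across %d variable(s):\n",
                nrow(x$discrepancies),
                dplyr::n_distinct(x$discrepancies$variable)))
    worst <- sort(x$per_variable_agreement)
    worst <- worst[worst < 1]
    for (i in seq_len(min(10, length(worst)))) {
      cat(sprintf("    %-24s agreement %.3f\n", names(worst)[i], worst[i]))
    }
  }
  invisible(x)
}

#' Write an agreement report to files
#'
#' @param report A `cvd_agreement` object.
#' @param path Base path; writes `<path>.txt` (human-readable summary)
#'   and `<path>_variables.csv` / `<path>_discrepancies.csv`.
#' @return The paths written, invisibly.
#' @export
write_agreement_report <- function(report, path) {
  stopifnot(inherits(report, "cvd_agreement"))
  txt <- paste0(path, ".txt")
  nv <- length(report$per_variable_agreement)
  lines <- c(
    sprintf("records compared        : %d", report$n_records),
    sprintf("variables compared      : %d", nv),
    sprintf("variables fully agreeing: %d (%.0f%%)",
            report$n_variables_fully_agreeing,
            100 * report$n_variables_fully_agreeing / nv),
    sprintf("discrepant value pairs  : %d", nrow(report$discrepancies))
  )
  writeLines(lines, txt)
  vars_csv <- paste0(path, "_variables.csv")
  readr::write_csv(tidy(report), vars_csv)
  disc_csv <- paste0(path, "_discrepancies.csv")
  readr::write_csv(report$discrepancies, disc_csv)
  invisible(c(txt, vars_csv, disc_csv))
}

#' Export a physician review worksheet
#'
#' Draws a seeded random sample of `k` cases and writes a worksheet with
#' the raw inputs plus blank adjudication columns for a clinician to
#' complete against paper charts and guideline text, together with an
#' answer key holding the engine's outputs for the same cases.
#'
#' @inheritParams assess_risk
#' @param k Number of cases to sample (1 <= k <= number of records).
#' @param seed Integer seed controlling the sample.
#' @param path Worksheet CSV path; the answer key is written next to it
#'   with suffix `_key.csv`.
#' @return Paths of the worksheet and key, invisibly.
#' @export
export_review_worksheet <- function(records, chart, k, seed, path) {
  records <- validate_records(records)
  if (!is.numeric(k) || length(k) != 1 || k < 1 || k > nrow(records)) {
    stop("k must satisfy 1 <= k <= number of records", call. = FALSE)
  }
  idx <- withr::with_seed(as.integer(seed),
                          sample.int(nrow(records), as.integer(k)))
  cases <- records[idx, ]
  sheet <- dplyr::mutate(
    cases,
    reviewer_chart_category = "",
    reviewer_adjusted_category = "",
    reviewer_bp_med = "",
    reviewer_statin = "",
    reviewer_antiplatelet = "",
    reviewer_notes = ""
  )
  readr::write_csv(sheet, path, na = "")
  key_path <- sub("\\.csv$", "", path)
  key_path <- paste0(key_path, "_key.csv")
  key <- assess_cohort(cases, chart)
  readr::write_csv(
    key[, c("participant_id", "chart_risk_category",
            "adjusted_risk_category", "bp_med_indicated",
            "statin_indicated", "antiplatelet_indicated",
            "bp_target_systolic", "bp_target_diastolic", "tc_target")],
    key_path, na = ""
  )
  invisible(c(worksheet = path, key = key_path))
}
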