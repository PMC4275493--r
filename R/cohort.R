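# Synthetic screening cohorts and the deterministic rule-boundary suite.

#' Synthetic cohort parameters
#'
#' Marginal distributions for the synthetic cohort generator. Defaults
#' emulate the risk-factor profile of a rural Indian community screening
#' programme: roughly two-thirds female, mean age about 51 years, mean
#' SBP 129 (SD 22) mm Hg, mean DBP 80 (SD 12) mm Hg, mean BMI 24.2
#' (SD 4.6) kg/m^2, 13% current smokers, and history prevalences of 16%
#' angina/MI, 1% stroke, 10% PVD, 14% diabetes, 19% on BP-lowering
#' therapy. Lipids are generated jointly (a point-of-care lipid panel is
#' either available or not) and are right-skewed lognormal; SBP rises
#' with age at 0.4 mm Hg per year.
#'
#' @param ... Named overrides of individual parameters; unknown names
#'   error.
#' @return A named list of class `cohort_params`.
#' @export
cohort_params <- function(...) {
  p <- list(
    p_female = 0.67, p_smoker = 0.13,
    p_angina_mi = 0.16, p_stroke = 0.01, p_pvd = 0.10, p_diabetes = 0.14,
    p_bp_med = 0.19, p_lipid_med = 0.005, p_antiplatelet = 0.03,
    p_fam_hx = 0.10,
    age_mean = 51.4, age_sd = 13.1,
    sbp_mean = 129, sbp_sd = 22, sbp_age_slope = 0.4,
    dbp_mean = 80, dbp_sd = 12,
    bmi_mean = 24.2, bmi_sd = 4.6,
    height_mean_male = 165, height_mean_female = 152, height_sd = 7,
    hr_mean = 76, hr_sd = 10,
    p_cholesterol_available = 0.3, p_waist_available = 0.7,
    p_glucose_available = 0.9, p_glucose_fasting = 0.3,
    tc_meanlog = log(185), tc_sdlog = 0.20,
    hdl_meanlog_male = log(42), hdl_meanlog_female = log(48),
    hdl_sdlog = 0.22,
    ldl_meanlog = log(110), ldl_sdlog = 0.25,
    tg_meanlog = log(140), tg_sdlog = 0.45,
    fasting_glucose_meanlog = log(98), fasting_glucose_sdlog = 0.22,
    random_glucose_meanlog = log(125), random_glucose_sdlog = 0.30
  )
  dots <- list(...)
  if (length(dots)) {
    bad <- setdiff(names(dots), names(p))
    if (length(bad)) {
      stop("unknown cohort parameter(s): ", paste(bad, collapse = ", "),
           call. = FALSE)
    }
    p[names(dots)] <- dots
  }
  probs <- grepl("^p_", names(p))
  if (any(unlist(p[probs]) < 0 | unlist(p[probs]) > 1)) {
    stop("probabilities must lie in [0, 1]", call. = FALSE)
  }
  sds <- grepl("_sd$|_sdlog$", names(p))
  if (any(unlist(p[sds]) <= 0)) stop("sds must be positive", call. = FALSE)
  structure(p, class = "cohort_params")
}

# truncated normal draw on [lo, hi] via inverse-CDF
.rtruncnorm <- function(n, mean, sd, lo, hi) {
  u <- stats::runif(n, stats::pnorm(lo, mean, sd),
                    stats::pnorm(hi, mean, sd))
  stats::qnorm(u, mean, sd)
}

#' Generate a synthetic screening cohort
#'
#' Draws `n` patient records with the marginal structure of
#' [cohort_params()]. Generation is a pure function of `(n, seed,
#' params)`: the same arguments always give an identical cohort. All
#' values are clipped to the record domain invariants, and the four
#' lipid fields are jointly missing with probability
#' `1 - p_cholesterol_available`.
#'
#' @param n Number of records (>= 1).
#' @param seed Integer random seed.
#' @param params A [cohort_params()] list.
#' @param assessor_role Role recorded on each record, `"NPHW"` or
#'   `"physician"`.
#' @return A tibble of `n` validated patient records.
#' @examples
#' cohort <- generate_cohort(100, seed = 42)
#' mean(cohort$sbp)
#' @export
generate_cohort <- function(n, seed, params = cohort_params(),
                            assessor_role = c("NPHW", "physician")) {
  stopifnot(inherits(params, "cohort_params"))
  if (!is.numeric(n) || length(n) != 1 || n < 1) {
    stop("n must be a single count >= 1", call. = FALSE)
  }
  n <- as.integer(n)
  assessor_role <- match.arg(assessor_role)
  p <- params
  withr::with_seed(as.integer(seed), {
    sex <- ifelse(stats::runif(n) < p$p_female, "female", "male")
    male <- sex == "male"
    age <- round(.rtruncnorm(n, p$age_mean, p$age_sd, 18, 110))
    resid_sd <- sqrt(max(p$sbp_sd^2 - (p$sbp_age_slope * p$age_sd)^2,
                         (0.5 * p$sbp_sd)^2))
    sbp <- round(p$sbp_mean + p$sbp_age_slope * (age - p$age_mean) +
                   stats::rnorm(n, 0, resid_sd))
    sbp <- pmin(pmax(sbp, 70), 260)
    dbp <- round(stats::rnorm(n, p$dbp_mean, p$dbp_sd))
    dbp <- pmin(pmax(dbp, 40), sbp - 10)
    heart_rate <- round(.rtruncnorm(n, p$hr_mean, p$hr_sd, 40, 180))
    height <- round(.rtruncnorm(n, ifelse(male, p$height_mean_male,
                                          p$height_mean_female),
                                p$height_sd, 130, 200), 1)
    bmi <- .rtruncnorm(n, p$bmi_mean, p$bmi_sd, 13, 45)
    weight <- round(bmi * (height / 100)^2, 1)

    waist_avail <- stats::runif(n) < p$p_waist_available
    waist <- round(.rtruncnorm(n, ifelse(male, 88, 82), 10, 55, 140))
    waist[!waist_avail] <- NA_real_

    lip_avail <- stats::runif(n) < p$p_cholesterol_available
    tc <- round(stats::rlnorm(n, p$tc_meanlog, p$tc_sdlog))
    hdl <- round(stats::rlnorm(n, ifelse(male, p$hdl_meanlog_male,
                                         p$hdl_meanlog_female), p$hdl_sdlog))
    ldl <- round(pmin(stats::rlnorm(n, p$ldl_meanlog, p$ldl_sdlog),
                      0.8 * tc))
    tg <- round(stats::rlnorm(n, p$tg_meanlog, p$tg_sdlog))
    tc[!lip_avail] <- NA_real_; hdl[!lip_avail] <- NA_real_
    ldl[!lip_avail] <- NA_real_; tg[!lip_avail] <- NA_real_

    glu_avail <- stats::runif(n) < p$p_glucose_available
    fasting <- stats::runif(n) < p$p_glucose_fasting
    fasting_glucose <- round(stats::rlnorm(n, p$fasting_glucose_meanlog,
                                           p$fasting_glucose_sdlog))
    random_glucose <- round(stats::rlnorm(n, p$random_glucose_meanlog,
                                          p$random_glucose_sdlog))
    fasting_glucose[!(glu_avail & fasting)] <- NA_real_
    random_glucose[!(glu_avail & !fasting)] <- NA_real_

    records <- tibble::tibble(
      participant_id = sprintf("S%05d", seq_len(n)),
      assessment_date = "2026-01-15",
      assessor_role = assessor_role,
      village_code = sprintf("V%02d", sample.int(11, n, replace = TRUE)),
      age = age, sex = sex,
      current_smoker = stats::runif(n) < p$p_smoker,
      hx_angina_or_mi = stats::runif(n) < p$p_angina_mi,
      hx_stroke = stats::runif(n) < p$p_stroke,
      hx_pvd = stats::runif(n) < p$p_pvd,
      hx_diabetes = stats::runif(n) < p$p_diabetes,
      fam_hx_premature_chd_or_stroke = stats::runif(n) < p$p_fam_hx,
      on_bp_lowering = stats::runif(n) < p$p_bp_med,
      on_lipid_lowering = stats::runif(n) < p$p_lipid_med,
      on_antiplatelet = stats::runif(n) < p$p_antiplatelet,
      sbp = sbp, dbp = dbp, heart_rate = heart_rate,
      height = height, weight = weight, waist = waist,
      glucose_is_fasting = glu_avail & fasting,
      fasting_glucose = fasting_glucose, random_glucose = random_glucose,
      tc = tc, ldl = ldl, hdl = hdl, tg = tg
    )
    validate_records(records)
  })
}

# one base record all boundary cases are perturbations of
.boundary_base <- function() {
  tibble::tibble(
    participant_id = "B000", assessment_date = "2026-01-15",
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
}

#' Deterministic rule-boundary test suite
#'
#' An enumerated set of patient records hitting every guideline
#' threshold at offsets -1, 0, +1 (the TC/HDL ratio at 7.9/8.0/8.1),
#' every history- and medication-flag singleton, every chart band edge,
#' the missingness patterns of the optional fields, and a factorial
#' block mixing moderate BP with ages, cholesterol levels, and smoking
#' so that the risk-gated medication rules fire at varying chart bands.
#' Content is fixed: no randomness, identical across calls.
#'
#' @return A tibble of validated patient records.
#' @examples
#' suite <- boundary_suite()
#' nrow(suite)
#' @export
boundary_suite <- function() {
  base <- .boundary_base()
  vary <- function(col, values) {
    purrr::map(values, function(v) {
      r <- base
      r[[col]] <- v
      r
    })
  }
  pieces <- list()

  flags <- c("hx_angina_or_mi", "hx_stroke", "hx_pvd", "hx_diabetes",
             "fam_hx_premature_chd_or_stroke", "on_bp_lowering",
             "on_lipid_lowering", "on_antiplatelet", "current_smoker")
  pieces$flag_singletons <- purrr::map(flags, function(f) {
    r <- base; r[[f]] <- TRUE; r
  })

  pieces$sbp <- vary("sbp", c(129, 130, 131, 139, 140, 141,
                              159, 160, 161, 179, 180, 181))
  pieces$dbp <- vary("dbp", c(79, 80, 81, 89, 90, 91, 99, 100, 101))
  pieces$age <- vary("age", c(18, 25, 39, 40, 41, 49, 50, 51, 59, 60, 61,
                              69, 70, 71, 78, 79, 80, 85, 110))
  pieces$tc <- vary("tc", c(154, 155, 193, 194, 199, 200, 201, 232, 233,
                            270, 271, 319, 320, 321))
  pieces$ldl <- vary("ldl", c(119, 120, 121, 239, 240, 241))
  # TC/HDL ratio at 7.9 / 8.0 / 8.1 with hdl fixed at 40
  pieces$ratio <- purrr::map(c(316, 320, 324), function(v) {
    r <- base; r$hdl <- 40; r$tc <- v; r
  })
  pieces$hdl_male <- purrr::map(c(39, 40, 41), function(v) {
    r <- base; r$sex <- "male"; r$hdl <- v; r
  })
  pieces$hdl_female <- vary("hdl", c(49, 50, 51))
  pieces$tg <- vary("tg", c(179, 180, 181))
  pieces$heart_rate <- vary("heart_rate", c(99, 100, 101))
  pieces$fasting_glucose <- vary("fasting_glucose",
                                 c(109, 110, 111, 125, 126, 127))
  pieces$random_glucose <- purrr::map(c(199, 200, 201), function(v) {
    r <- base; r$glucose_is_fasting <- FALSE
    r$fasting_glucose <- NA_real_; r$random_glucose <- v; r
  })
  # BMI at the 27.5 kg/m^2 obesity cut (height 160 cm)
  pieces$bmi <- vary("weight", round(c(27.4, 27.5, 27.6) * 1.6^2, 2))
  pieces$waist_male <- purrr::map(c(89, 90, 91), function(v) {
    r <- base; r$sex <- "male"; r$waist <- v; r
  })
  pieces$waist_female <- vary("waist", c(79, 80, 81))

  blank <- function(r, cols) { r[cols] <- NA_real_; r }
  lipids <- c("tc", "ldl", "hdl", "tg")
  glucose <- c("fasting_glucose", "random_glucose")
  pieces$missingness <- list(
    blank(base, lipids),
    blank(base, "waist"),
    blank(base, glucose),
    blank(base, c(lipids, glucose, "waist")),
    blank(base, c("ldl", "hdl", "tg"))   # tc alone present
  )

  grid <- tidyr::expand_grid(sbp = c(135, 145, 165), age = c(45, 65, 75),
                             tc = c(NA_real_, 170, 271),
                             smoker = c(FALSE, TRUE))
  pieces$risk_gate_grid <- purrr::pmap(grid, function(sbp, age, tc, smoker) {
    r <- base
    r$sbp <- sbp; r$age <- age; r$current_smoker <- smoker
    if (is.na(tc)) {
      r[lipids] <- NA_real_
    } else {
      r$tc <- tc
    }
    r
  })

  suite <- dplyr::bind_rows(unlist(pieces, recursive = FALSE))
  suite$participant_id <- sprintf("B%03d", seq_len(nrow(suite)))
  validate_records(suite)
}
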