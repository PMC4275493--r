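# Care-cascade analytics: screening -> referral -> attendance ->
# treatment recommendation -> adherence, plus PHC blood-pressure
# management summaries.

#' Read follow-up records from a delimited text file
#'
#' Comma-separated with header: `participant_id`,
#' `visited_doctor_within_1_month`, `provider_type`
#' (`government`/`private`/`none`), `medication_recommended`,
#' `on_medication_at_3_months`. Flags are 0/1. The logical ordering of
#' the pathway is enforced: a medication recommendation implies a doctor
#' visit, and taking medication at 3 months implies a recommendation.
#'
#' @param path Path to the follow-up CSV file.
#' @return A validated tibble of follow-up records.
#' @export
read_followups <- function(path) {
  fu <- readr::read_csv(
    path, comment = "#", show_col_types = FALSE, progress = FALSE,
    col_types = readr::cols(
      participant_id = readr::col_character(),
      provider_type = readr::col_character(),
      .default = readr::col_double()
    )
  )
  validate_followups(fu)
}

#' Validate a table of follow-up records
#'
#' @param followups Data frame of follow-up records.
#' @return The follow-ups as a tibble; errors on schema or pathway-order
#'   violations.
#' @export
validate_followups <- function(followups) {
  fu <- tibble::as_tibble(followups)
  needed <- c("participant_id", "visited_doctor_within_1_month",
              "provider_type", "medication_recommended",
              "on_medication_at_3_months")
  missing_cols <- setdiff(needed, names(fu))
  if (length(missing_cols)) {
    stop("follow-up records are missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  for (col in c("visited_doctor_within_1_month", "medication_recommended",
                "on_medication_at_3_months")) {
    fu[[col]] <- !is.na(fu[[col]]) & fu[[col]] != 0
  }
  bad_prov <- setdiff(unique(fu$provider_type),
                      c("government", "private", "none"))
  if (length(bad_prov)) {
    stop("unknown provider_type value(s): ",
         paste(bad_prov, collapse = ", "), call. = FALSE)
  }
  if (any(fu$on_medication_at_3_months & !fu$medication_recommended)) {
    stop("on_medication_at_3_months implies medication_recommended",
         call. = FALSE)
  }
  if (any(fu$medication_recommended & !fu$visited_doctor_within_1_month)) {
    stop("medication_recommended implies visited_doctor_within_1_month",
         call. = FALSE)
  }
  if (anyDuplicated(fu$participant_id)) {
    stop("duplicated participant_id in follow-ups", call. = FALSE)
  }
  fu
}

# patients whose only basis for a high-risk classification is a reported
# PVD history: no other CVD history, no CHR-level factor, chart band
# below 20%, no diabetes
.pvd_only <- function(assessments) {
  assessments$hx_pvd & !assessments$hx_angina_or_mi &
    !assessments$hx_stroke & !assessments$clinically_high_risk &
    !assessments$diabetes_status &
    match(assessments$chart_risk_category, risk_categories()) <
      match("R20_30", risk_categories())
}

#' Compute the screening-to-adherence care cascade
#'
#' Counts patients at each stage of the pathway: screened; referred
#' (engine referral indication); with a definite BP-lowering medication
#' indication among those referred; attending a doctor within 1 month of
#' referral; recommended medication by that doctor; and still on
#' medication at 3 months. Stage percentages are integer-rounded half-up
#' on consecutive-stage denominators, with adherence expressed against
#' attendance.
#'
#' @param assessments Output of [assess_cohort()].
#' @param followups Optional follow-up records (see [read_followups()]);
#'   patients without a follow-up row count as not attending. Follow-up
#'   ids that match no assessment are an error.
#' @param exclude_pvd_only Drop patients whose high-risk classification
#'   rests solely on a reported PVD history (no other CVD history, no
#'   clinically-high-risk factor, chart band below 20%, no diabetes),
#'   mirroring field exclusions where PVD self-report proved unreliable.
#' @return An object of class `cvd_cascade` with `counts` (named) and
#'   `stage_percentages` (tibble of numerator stage, denominator stage,
#'   percent).
#' @examples
#' chart <- synthetic_chart()
#' out <- assess_cohort(generate_cohort(200, seed = 7), chart)
#' compute_cascade(out)
#' @export
compute_cascade <- function(assessments, followups = NULL,
                            exclude_pvd_only = FALSE) {
  a <- tibble::as_tibble(assessments)
  if (!nrow(a)) stop("no assessments supplied", call. = FALSE)
  n_excluded <- 0L
  if (exclude_pvd_only) {
    drop <- .pvd_only(a)
    n_excluded <- sum(drop)
    a <- a[!drop, , drop = FALSE]
  }
  if (is.null(followups)) {
    followups <- tibble::tibble(
      participant_id = character(),
      visited_doctor_within_1_month = logical(),
      provider_type = character(), medication_recommended = logical(),
      on_medication_at_3_months = logical()
    )
  }
  fu <- validate_followups(followups)
  orphan <- setdiff(fu$participant_id, a$participant_id)
  if (length(orphan)) {
    stop("follow-up id(s) with no matching assessment: ",
         paste(utils::head(orphan, 10), collapse = ", "), call. = FALSE)
  }
  j <- dplyr::left_join(a, fu, by = "participant_id")
  j$visited_doctor_within_1_month <-
    !is.na(j$visited_doctor_within_1_month) & j$visited_doctor_within_1_month
  j$medication_recommended <-
    !is.na(j$medication_recommended) & j$medication_recommended
  j$on_medication_at_3_months <-
    !is.na(j$on_medication_at_3_months) & j$on_medication_at_3_months

  screened <- nrow(j)
  referred <- sum(j$referral_indicated)
  bp_ind <- sum(j$referral_indicated & j$bp_med_indicated)
  attended <- sum(j$referral_indicated & j$bp_med_indicated &
                    j$visited_doctor_within_1_month)
  recommended <- sum(j$referral_indicated & j$bp_med_indicated &
                       j$visited_doctor_within_1_month &
                       j$medication_recommended)
  adherent <- sum(j$referral_indicated & j$bp_med_indicated &
                    j$visited_doctor_within_1_month &
                    j$medication_recommended & j$on_medication_at_3_months)
  counts <- c(screened = screened, referred = referred,
              bp_med_indicated = bp_ind, attended_1_month = attended,
              recommended = recommended, adherent_3_months = adherent)
  pct <- function(num, den) {
    if (den == 0) NA_real_ else round_half_up(100 * num / den)
  }
  stage_percentages <- tibble::tibble(
    numerator = c("referred", "bp_med_indicated", "attended_1_month",
                  "adherent_3_months"),
    denominator = c("screened", "referred", "bp_med_indicated",
                    "attended_1_month"),
    n = c(referred, bp_ind, attended, adherent),
    of = c(screened, referred, bp_ind, attended),
    percent = c(pct(referred, screened), pct(bp_ind, referred),
                pct(attended, bp_ind), pct(adherent, attended))
  )
  structure(
    list(counts = counts, stage_percentages = stage_percentages,
         n_excluded_pvd_only = n_excluded),
    class = "cvd_cascade"
  )
}

#' @export
print.cvd_cascade <- function(x, ...) {
  cat("<cvd_cascade>\n")
  for (nm in names(x$counts)) {
    cat(sprintf("  %-18s %d\n", nm, x$counts[[nm]]))
  }
  sp <- x$stage_percentages
  for (i in seq_len(nrow(sp))) {
    cat(sprintf("  %s/%s: %d/%d = %s%%\n", sp$numerator[i],
                sp$denominator[i], sp$n[i], sp$of[i],
                format(sp$percent[i])))
  }
  if (x$n_excluded_pvd_only > 0) {
    cat(sprintf("  (excluded %d PVD-only high-risk patients)\n",
                x$n_excluded_pvd_only))
  }
  invisible(x)
}

#' Blood-pressure management summary
#'
#' Summarises BP management in a screened group, intended for
#' physician-screened assessments: how many patients are already on
#' BP-lowering medication, what fraction of those are at their
#' engine-assigned BP target (strictly below both the systolic and
#' diastolic target), and what fraction of the untreated have an engine
#' indication to start treatment.
#'
#' @param assessments Output of [assess_cohort()].
#' @return A one-row tibble: `n`, `n_on_bp_med`, `pct_on_bp_med`,
#'   `n_at_target`, `pct_at_target` (of those on medication),
#'   `n_untreated`, `n_untreated_indicated`, `pct_untreated_indicated`.
#' @examples
#' chart <- synthetic_chart()
#' out <- assess_cohort(generate_cohort(100, seed = 3,
#'                      assessor_role = "physician"), chart)
#' bp_management_summary(out)
#' @export
bp_management_summary <- function(assessments) {
  a <- tibble::as_tibble(assessments)
  if (!nrow(a)) stop("no assessments supplied", call. = FALSE)
  on_med <- a$on_bp_lowering
  at_target <- a$sbp < a$bp_target_systolic & a$dbp < a$bp_target_diastolic
  pct <- function(num, den) {
    if (den == 0) NA_real_ else round_half_up(100 * num / den)
  }
  n <- nrow(a)
  n_on <- sum(on_med)
  n_tgt <- sum(on_med & at_target)
  n_untreated <- sum(!on_med)
  n_ind <- sum(!on_med & a$bp_med_indicated)
  tibble::tibble(
    n = n,
    n_on_bp_med = n_on,
    pct_on_bp_med = pct(n_on, n),
    n_at_target = n_tgt,
    pct_at_target = pct(n_tgt, n_on),
    n_untreated = n_untreated,
    n_untreated_indicated = n_ind,
    pct_untreated_indicated = pct(n_ind, n_untreated)
  )
}
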