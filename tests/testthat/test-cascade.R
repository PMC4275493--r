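# Minimal assessed-cohort fixture with the stage structure of a village
# screening round: counts are chosen in the test, analytics must recover
# the percentages.
cascade_fixture <- function(n = 227, n_referred = 88, n_bp_ind = 69,
                            n_attend = 24, n_adherent = 10) {
  ids <- sprintf("P%03d", seq_len(n))
  a <- tibble::tibble(
    participant_id = ids,
    referral_indicated = seq_len(n) <= n_referred,
    bp_med_indicated = seq_len(n) <= n_bp_ind
  )
  fu <- tibble::tibble(
    participant_id = ids[seq_len(n_attend)],
    visited_doctor_within_1_month = TRUE,
    provider_type = rep_len(c("government", "private"), n_attend),
    medication_recommended = TRUE,
    on_medication_at_3_months = seq_len(n_attend) <= n_adherent
  )
  list(assessments = a, followups = fu)
}

test_that("cascade reproduces stage counts and half-up integer percentages", {
  fx <- cascade_fixture()
  cas <- compute_cascade(fx$assessments, fx$followups)
  expect_equal(unname(cas$counts),
               c(227, 88, 69, 24, 24, 10))
  expect_equal(cas$stage_percentages$percent, c(39, 78, 35, 42))

  # independent integer recomputation of every percentage
  sp <- cas$stage_percentages
  expect_equal(sp$percent, floor(100 * sp$n / sp$of + 0.5))

  # denominators chain: each equals the previous numerator stage count
  expect_equal(sp$of[-1], sp$n[1:3])
})

test_that("cascade stages never increase and empty follow-up zeroes the tail", {
  fx <- cascade_fixture()
  cas <- compute_cascade(fx$assessments, fx$followups)
  expect_true(all(diff(unname(cas$counts)) <= 0))

  neg <- fx$followups
  neg$visited_doctor_within_1_month <- FALSE
  neg$medication_recommended <- FALSE
  neg$on_medication_at_3_months <- FALSE
  cas0 <- compute_cascade(fx$assessments, neg)
  expect_equal(unname(cas0$counts[c("attended_1_month", "recommended",
                                    "adherent_3_months")]), c(0, 0, 0))
})

test_that("cascade counts are invariant to input row order", {
  fx <- cascade_fixture()
  shuffled <- fx$assessments[rev(seq_len(nrow(fx$assessments))), ]
  cas1 <- compute_cascade(fx$assessments, fx$followups)
  cas2 <- compute_cascade(shuffled, fx$followups)
  expect_equal(cas1$counts, cas2$counts)
})

test_that("orphan follow-ups and inconsistent pathways are rejected", {
  fx <- cascade_fixture(n = 20, n_referred = 10, n_bp_ind = 8,
                        n_attend = 5, n_adherent = 2)
  orphan <- fx$followups
  orphan$participant_id[1] <- "GHOST"
  expect_error(compute_cascade(fx$assessments, orphan), "GHOST")

  bad <- fx$followups
  bad$medication_recommended[1] <- FALSE  # but still on medication
  expect_error(validate_followups(bad), "implies medication_recommended")
  bad2 <- fx$followups
  bad2$visited_doctor_within_1_month[3] <- FALSE
  expect_error(validate_followups(bad2), "implies visited_doctor")
})

test_that("PVD-only high-risk patients can be excluded from the cascade", {
  chart <- fixture_chart()
  recs <- make_records(
    list(hx_pvd = TRUE),                       # PVD alone, low chart risk
    list(hx_pvd = TRUE, sbp = 170),            # PVD plus CHR factor: kept
    list(hx_angina_or_mi = TRUE),              # other CVD: kept
    list()
  )
  out <- assess_cohort(recs, chart)
  keep_all <- compute_cascade(out)
  dropped <- compute_cascade(out, exclude_pvd_only = TRUE)
  expect_equal(dropped$n_excluded_pvd_only, 1)
  expect_equal(unname(dropped$counts["screened"]),
               unname(keep_all$counts["screened"]) - 1)
})

test_that("BP management summary reports treatment coverage and control", {
  # 65 screened: 29 on BP medication (14 at their target), 36 untreated
  # of whom 11 carry an engine indication
  mk <- function(i, on_med, at_target, indicated) {
    tibble::tibble(
      participant_id = sprintf("D%02d", i),
      on_bp_lowering = on_med,
      sbp = ifelse(at_target, 128, 152), dbp = ifelse(at_target, 78, 94),
      bp_target_systolic = 140, bp_target_diastolic = 90,
      bp_med_indicated = indicated
    )
  }
  a <- dplyr::bind_rows(
    mk(1:14, TRUE, TRUE, TRUE),
    mk(15:29, TRUE, FALSE, TRUE),
    mk(30:40, FALSE, FALSE, TRUE),
    mk(41:65, FALSE, TRUE, FALSE)
  )
  s <- bp_management_summary(a)
  expect_equal(s$n, 65)
  expect_equal(c(s$n_on_bp_med, s$pct_on_bp_med), c(29, 45))
  expect_equal(c(s$n_at_target, s$pct_at_target), c(14, 48))
  expect_equal(c(s$n_untreated_indicated, s$pct_untreated_indicated),
               c(11, 31))

  # all controlled: 100%
  all_ctl <- mk(1:10, TRUE, TRUE, FALSE)
  expect_equal(bp_management_summary(all_ctl)$pct_at_target, 100)
  expect_error(bp_management_summary(a[0, ]), "no assessments")
})

test_that("cascade tidiers and plot expose the stage table", {
  fx <- cascade_fixture()
  cas <- compute_cascade(fx$assessments, fx$followups)
  td <- tidy(cas)
  expect_equal(td$n, unname(cas$counts))
  gl <- glance(cas)
  expect_equal(gl$pct_referred, 39)
  expect_equal(gl$pct_adherent_3_months, 42)
  expect_s3_class(autoplot(cas), "ggplot")
})
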