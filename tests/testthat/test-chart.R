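test_that("bundled chart file loads complete with the standard grid shape", {
  chart <- read_chart(cvdcds_example("synthetic_whoish_chart.csv"))
  expect_s3_class(chart, "cvd_chart")
  expect_equal(sum(chart$cells$pathway == "high_info"), 2 * 2 * 2 * 4 * 4 * 5)
  expect_equal(sum(chart$cells$pathway == "low_info"), 2 * 2 * 2 * 4 * 4)
  # both grids share the sex/diabetes/smoking/age/sbp axes
  hi <- chart$cells[chart$cells$pathway == "high_info", ]
  lo <- chart$cells[chart$cells$pathway == "low_info", ]
  for (col in c("sex", "age_lo", "sbp_lo")) {
    expect_setequal(unique(hi[[col]]), unique(lo[[col]]))
  }
})

test_that("incomplete grids and unknown labels are rejected", {
  cells <- synthetic_chart()$cells
  expect_error(as_cvd_chart(cells[-1, ]), "incomplete")
  bad <- cells
  bad$category[5] <- "HIGH"
  expect_error(as_cvd_chart(bad), "unknown risk category")
  dup <- dplyr::bind_rows(cells, cells[1, ])
  expect_error(as_cvd_chart(dup), "duplicated")
})

test_that("chart age imputation clamps into [40, 79] and is idempotent", {
  expect_equal(impute_chart_age(25), 40)
  expect_equal(impute_chart_age(85), 79)
  expect_equal(impute_chart_age(55), 55)
  expect_equal(impute_chart_age(40), 40)
  ages <- 18:110
  once <- impute_chart_age(ages)
  expect_true(all(once >= 40 & once <= 79))
  expect_equal(impute_chart_age(once), once)
  expect_error(impute_chart_age(17), "age")
  expect_error(impute_chart_age(111), "age")
})

test_that("lookup pathway follows cholesterol availability", {
  chart <- fixture_chart()
  out <- lookup_risk(chart, "male", FALSE, TRUE, age = 62, sbp = 150,
                     tc = NA)
  expect_equal(out$pathway, "low_info")
  out2 <- lookup_risk(chart, "male", FALSE, TRUE, age = 62, sbp = 150,
                      tc = 220)
  expect_equal(out2$pathway, "high_info")
})

test_that("lookup reproduces every cell under direct grid enumeration", {
  chart <- fixture_chart()
  cells <- chart$cells
  # representative input inside each band, computed from the band edges
  # themselves (independent of the engine's banding arithmetic)
  mid <- function(lo, hi, fallback_lo, fallback_hi) {
    lo <- ifelse(is.infinite(lo), fallback_lo, lo)
    hi <- ifelse(is.infinite(hi), fallback_hi, hi)
    (lo + hi) / 2
  }
  age_in <- mid(cells$age_lo, cells$age_hi, 40, 80)
  sbp_in <- mid(cells$sbp_lo, cells$sbp_hi, 100, 220)
  tc_in_mmol <- mid(cells$tc_lo, cells$tc_hi, 2, 9)
  tc_in <- ifelse(cells$pathway == "low_info", NA,
                  tc_in_mmol * 38.67)
  got <- lookup_risk(chart, cells$sex, cells$diabetes, cells$smoking,
                     age_in, sbp_in, tc_in)
  expect_equal(got$category, cells$category)
  expect_equal(got$pathway, cells$pathway)
})

test_that("lookup is pure and never drops category as SBP rises", {
  chart <- fixture_chart()
  a <- lookup_risk(chart, "female", TRUE, FALSE, 58, 150, 240)
  b <- lookup_risk(chart, "female", TRUE, FALSE, 58, 150, 240)
  expect_identical(a, b)
  sbps <- c(100, 120, 139, 140, 159, 160, 179, 180, 220)
  for (sex in c("male", "female")) {
    cat_rank <- match(
      lookup_risk(chart, sex, TRUE, TRUE, 65, sbps, 250)$category,
      risk_categories()
    )
    expect_true(all(diff(cat_rank) >= 0))
  }
})

test_that("monotonicity audit is empty on the fixture and counts an injected inversion", {
  chart <- fixture_chart()
  expect_equal(nrow(audit_chart_monotonicity(chart)), 0)

  cells <- chart$cells
  # invert one interior cell downward to create detectable violations
  i <- which(cells$pathway == "high_info" & cells$sex == "male" &
               cells$diabetes & cells$smoking & cells$age_band == 3 &
               cells$sbp_band == 3 & cells$tc_band == 3)
  cells$category[i] <- "LT10"
  broken <- as_cvd_chart(cells)
  report <- audit_chart_monotonicity(broken)
  expect_gt(nrow(report), 0)

  # brute-force recount: scan every ordered cell pair differing by one
  # risk-increasing step, entirely independently of the audit code
  rank <- match(cells$category, risk_categories())
  key <- paste(cells$pathway, cells$sex, cells$diabetes, cells$smoking,
               cells$age_band, cells$sbp_band, cells$tc_band)
  n_bad <- 0L
  for (r in seq_len(nrow(cells))) {
    for (ax in c("age_band", "sbp_band", "tc_band", "smoking", "diabetes")) {
      up <- cells[r, ]
      if (ax %in% c("smoking", "diabetes")) {
        if (isTRUE(up[[ax]])) next
        up[[ax]] <- TRUE
      } else {
        if (is.na(up[[ax]])) next
        up[[ax]] <- up[[ax]] + 1L
      }
      j <- match(paste(up$pathway, up$sex, up$diabetes, up$smoking,
                       up$age_band, up$sbp_band, up$tc_band), key)
      if (!is.na(j) && rank[j] < rank[r]) n_bad <- n_bad + 1L
    }
  }
  expect_equal(nrow(report), n_bad)
})
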