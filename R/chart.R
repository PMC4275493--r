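# Categorical risk-chart representation, loading, and lookup.
#
# A chart set holds two complete grids of 10-year CVD risk categories:
# the high-information grid (indexed by sex, diabetes, smoking, age band,
# SBP band, and total-cholesterol band) and the low-information grid
# (same axes without cholesterol), used when no cholesterol measurement
# is available.

# normative default band edges; charts loaded from file may redefine them
.default_axes <- function() {
  list(
    age = c(40, 50, 60, 70, 80),              # [40,50) [50,60) [60,70) [70,80)
    sbp = c(-Inf, 140, 160, 180, Inf),        # mm Hg
    tc  = c(-Inf, 4, 5, 6, 7, Inf)            # mmol/L
  )
}

band_index <- function(x, breaks) {
  # half-open [lo, hi) bands; topmost closed above at +Inf
  idx <- findInterval(x, breaks, left.open = FALSE)
  idx[x < breaks[1] | x >= breaks[length(breaks)]] <- NA_integer_
  idx
}

chart_key <- function(pathway, sex, diabetes, smoking, age_band, sbp_band,
                      tc_band) {
  paste(pathway, sex, as.integer(diabetes), as.integer(smoking),
        age_band, sbp_band, ifelse(is.na(tc_band), 0L, tc_band), sep = "|")
}

#' Construct a risk chart set from a cell table
#'
#' Validates a long table of chart cells (one row per cell of each grid)
#' and builds the indexed chart object used by [lookup_risk()]. Users
#' transcribing a published chart provide the same table via
#' [read_chart()].
#'
#' @param cells Data frame with columns `region`, `pathway`
#'   (`"high_info"`/`"low_info"`), `sex` (`"male"`/`"female"`),
#'   `diabetes`, `smoking` (`"yes"`/`"no"` or logical), `age_lo`,
#'   `age_hi`, `sbp_lo`, `sbp_hi`, `tc_lo`, `tc_hi` (band edges; `tc`
#'   columns `NA` for low-information rows; outermost edges may be
#'   `-Inf`/`Inf`), and `category` (one of [risk_categories()]).
#' @param cholesterol_units Units the `tc` band edges are expressed in.
#'
#' @return An object of class `cvd_chart`.
#' @seealso [read_chart()], [synthetic_chart()], [lookup_risk()]
#' @export
as_cvd_chart <- function(cells, cholesterol_units = c("mmol/L", "mg/dL")) {
  cholesterol_units <- match.arg(cholesterol_units)
  cells <- tibble::as_tibble(cells)
  needed <- c("region", "pathway", "sex", "diabetes", "smoking",
              "age_lo", "age_hi", "sbp_lo", "sbp_hi", "tc_lo", "tc_hi",
              "category")
  missing_cols <- setdiff(needed, names(cells))
  if (length(missing_cols)) {
    stop("chart table is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  bad_cat <- setdiff(unique(cells$category), risk_categories())
  if (length(bad_cat)) {
    stop("unknown risk category label(s): ", paste(bad_cat, collapse = ", "),
         "; expected one of ", paste(risk_categories(), collapse = ", "),
         call. = FALSE)
  }
  bad_path <- setdiff(unique(cells$pathway), c("high_info", "low_info"))
  if (length(bad_path)) {
    stop("unknown pathway label(s): ", paste(bad_path, collapse = ", "),
         call. = FALSE)
  }
  for (col in c("diabetes", "smoking")) {
    v <- cells[[col]]
    if (!is.logical(v)) cells[[col]] <- v %in% c("yes", "TRUE", "true", "1")
  }

  # recover axes from the distinct band edges of each pathway
  axes <- list(
    age = sort(unique(c(cells$age_lo, cells$age_hi))),
    sbp = sort(unique(c(cells$sbp_lo, cells$sbp_hi))),
    tc  = sort(unique(c(cells$tc_lo[cells$pathway == "high_info"],
                        cells$tc_hi[cells$pathway == "high_info"])))
  )
  for (ax in c("age", "sbp")) {
    if (length(axes[[ax]]) < 2) {
      stop("chart ", ax, " axis is degenerate", call. = FALSE)
    }
  }

  cells$age_band <- band_index(cells$age_lo, axes$age)
  cells$sbp_band <- band_index(cells$sbp_lo, axes$sbp)
  cells$tc_band  <- ifelse(cells$pathway == "high_info",
                           band_index(cells$tc_lo, axes$tc), NA_integer_)

  n_age <- length(axes$age) - 1L
  n_sbp <- length(axes$sbp) - 1L
  n_tc  <- length(axes$tc) - 1L

  # completeness: every combination present exactly once in each grid
  want <- dplyr::bind_rows(
    tidyr::expand_grid(pathway = "high_info",
                       sex = c("female", "male"), diabetes = c(FALSE, TRUE),
                       smoking = c(FALSE, TRUE), age_band = seq_len(n_age),
                       sbp_band = seq_len(n_sbp), tc_band = seq_len(n_tc)),
    tidyr::expand_grid(pathway = "low_info",
                       sex = c("female", "male"), diabetes = c(FALSE, TRUE),
                       smoking = c(FALSE, TRUE), age_band = seq_len(n_age),
                       sbp_band = seq_len(n_sbp), tc_band = NA_integer_)
  )
  want_keys <- chart_key(want$pathway, want$sex, want$diabetes, want$smoking,
                         want$age_band, want$sbp_band, want$tc_band)
  have_keys <- chart_key(cells$pathway, cells$sex, cells$diabetes,
                         cells$smoking, cells$age_band, cells$sbp_band,
                         cells$tc_band)
  absent <- setdiff(want_keys, have_keys)
  if (length(absent)) {
    stop("chart grid is incomplete; missing cell(s): ",
         paste(utils::head(absent, 5), collapse = "; "),
         if (length(absent) > 5) sprintf(" (and %d more)", length(absent) - 5),
         call. = FALSE)
  }
  if (anyDuplicated(have_keys)) {
    stop("chart grid has duplicated cell(s): ",
         paste(utils::head(have_keys[duplicated(have_keys)], 5),
               collapse = "; "), call. = FALSE)
  }

  index <- stats::setNames(cells$category, have_keys)
  structure(
    list(region = cells$region[1], cells = cells, axes = axes,
         cholesterol_units = cholesterol_units, index = index),
    class = "cvd_chart"
  )
}

#' @export
print.cvd_chart <- function(x, ...) {
  cat(sprintf("<cvd_chart> region: %s\n", x$region))
  cat(sprintf("  high-information cells: %d | low-information cells: %d\n",
              sum(x$cells$pathway == "high_info"),
              sum(x$cells$pathway == "low_info")))
  cat(sprintf("  cholesterol units: %s\n", x$cholesterol_units))
  invisible(x)
}

#' Read a risk chart set from a delimited text file
#'
#' The file is comma-separated with a header row and one row per chart
#' cell; see [as_cvd_chart()] for the column contract. Chart files are
#' validated strictly: an incomplete grid or an unknown category label is
#' fatal.
#'
#' @param path Path to the chart CSV file.
#' @inheritParams as_cvd_chart
#' @return A `cvd_chart` object.
#' @examples
#' chart <- read_chart(cvdcds_example("synthetic_whoish_chart.csv"))
#' chart
#' @export
read_chart <- function(path, cholesterol_units = c("mmol/L", "mg/dL")) {
  cells <- readr::read_csv(
    path, comment = "#", show_col_types = FALSE, progress = FALSE,
    col_types = readr::cols(
      region = readr::col_character(), pathway = readr::col_character(),
      sex = readr::col_character(), diabetes = readr::col_character(),
      smoking = readr::col_character(),
      age_lo = readr::col_double(), age_hi = readr::col_double(),
      sbp_lo = readr::col_double(), sbp_hi = readr::col_double(),
      tc_lo = readr::col_double(), tc_hi = readr::col_double(),
      category = readr::col_character()
    )
  )
  as_cvd_chart(cells, cholesterol_units = match.arg(cholesterol_units))
}

#' Write a risk chart set to a delimited text file
#'
#' @param chart A `cvd_chart` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_chart <- function(chart, path) {
  stopifnot(inherits(chart, "cvd_chart"))
  out <- dplyr::mutate(
    chart$cells,
    diabetes = ifelse(.data$diabetes, "yes", "no"),
    smoking  = ifelse(.data$smoking, "yes", "no")
  )
  out <- dplyr::select(out, "region", "pathway", "sex", "diabetes",
                       "smoking", "age_lo", "age_hi", "sbp_lo", "sbp_hi",
                       "tc_lo", "tc_hi", "category")
  readr::write_csv(out, path)
  invisible(path)
}

#' Path to a bundled example data file
#'
#' @param file File name under the package's `extdata` directory; with no
#'   argument, lists the available files.
#' @return A file path (or a vector of file names).
#' @export
cvdcds_example <- function(file = NULL) {
  if (is.null(file)) {
    dir(system.file("extdata", package = "cvdcds"))
  } else {
    system.file("extdata", file, package = "cvdcds", mustWork = TRUE)
  }
}

#' Synthetic monotone risk chart set
#'
#' Builds a complete, deliberately monotone chart set with the standard
#' WHO/ISH grid shape (2 sexes x 2 diabetes x 2 smoking x 4 age bands x
#' 4 SBP bands, and 5 cholesterol bands on the high-information grid).
#' Cell categories are synthetic: they come from a monotone score over
#' the band indices, not from any published chart, so the set is suitable
#' for testing and demonstration only. Published chart values can be
#' transcribed into the same file format and loaded with [read_chart()].
#'
#' @return A `cvd_chart` object with 320 high-information and 64
#'   low-information cells.
#' @examples
#' chart <- synthetic_chart()
#' nrow(chart$cells)
#' @export
synthetic_chart <- function() {
  axes <- .default_axes()
  score_to_cat <- function(score, breaks) {
    # breaks: upper score bound (inclusive) of the first four categories
    risk_categories()[findInterval(score, breaks + 1L) + 1L]
  }
  grid_hi <- tidyr::expand_grid(
    sex = c("female", "male"), diabetes = c(FALSE, TRUE),
    smoking = c(FALSE, TRUE), age_band = 1:4, sbp_band = 1:4, tc_band = 1:5
  )
  grid_hi <- dplyr::mutate(
    grid_hi,
    pathway = "high_info",
    score = (.data$age_band - 1L) + (.data$sbp_band - 1L) +
      (.data$tc_band - 1L) + .data$smoking + .data$diabetes +
      (.data$sex == "male"),
    category = score_to_cat(.data$score, c(3, 5, 7, 9))
  )
  grid_lo <- tidyr::expand_grid(
    sex = c("female", "male"), diabetes = c(FALSE, TRUE),
    smoking = c(FALSE, TRUE), age_band = 1:4, sbp_band = 1:4
  )
  grid_lo <- dplyr::mutate(
    grid_lo,
    pathway = "low_info", tc_band = NA_integer_,
    score = (.data$age_band - 1L) + (.data$sbp_band - 1L) +
      .data$smoking + .data$diabetes + (.data$sex == "male"),
    category = score_to_cat(.data$score, c(2, 4, 6, 7))
  )
  cells <- dplyr::bind_rows(grid_hi, grid_lo)
  cells <- dplyr::mutate(
    cells,
    region = "synthetic-monotone",
    age_lo = axes$age[.data$age_band], age_hi = axes$age[.data$age_band + 1L],
    sbp_lo = axes$sbp[.data$sbp_band], sbp_hi = axes$sbp[.data$sbp_band + 1L],
    tc_lo = ifelse(is.na(.data$tc_band), NA_real_, axes$tc[.data$tc_band]),
    tc_hi = ifelse(is.na(.data$tc_band), NA_real_,
                   axes$tc[.data$tc_band + 1L])
  )
  cells <- dplyr::select(cells, "region", "pathway", "sex", "diabetes",
                         "smoking", "age_lo", "age_hi", "sbp_lo", "sbp_hi",
                         "tc_lo", "tc_hi", "category")
  as_cvd_chart(cells, cholesterol_units = "mmol/L")
}

#' Impute the chart age used for risk lookup
#'
#' Risk charts tabulate ages 40-79 only; younger adults are assessed at
#' an imputed age of 40 and those aged 79 or more at 79. Idempotent, and
#' its image is always within \[40, 79\].
#'
#' @param age Age(s) in years; each must lie in \[18, 110\].
#' @return Imputed chart age(s), `pmax(40, pmin(79, age))`.
#' @examples
#' impute_chart_age(c(25, 55, 85))
#' @export
impute_chart_age <- function(age) {
  if (any(is.na(age)) || any(age < 18 | age > 110)) {
    stop("age must be within [18, 110] years", call. = FALSE)
  }
  pmax(40, pmin(79, age))
}

#' Look up categorical 10-year CVD risk
#'
#' Vectorised chart lookup. The high-information grid is used for every
#' element with a cholesterol value; elements without one automatically
#' fall back to the low-information grid. Age is imputed internally via
#' [impute_chart_age()]; cholesterol given in mg/dL is converted to
#' mmol/L before banding when the chart declares mmol/L units.
#'
#' @param chart A `cvd_chart` object.
#' @param sex `"male"`/`"female"`.
#' @param diabetes,smoking Logical.
#' @param age Age in years, \[18, 110\].
#' @param sbp Systolic blood pressure, mm Hg.
#' @param tc Total cholesterol in `tc_units`, or `NA` when unmeasured.
#' @param tc_units Units `tc` is supplied in.
#' @return A tibble with columns `category` (one of [risk_categories()])
#'   and `pathway` (`"high_info"` or `"low_info"`).
#' @examples
#' chart <- synthetic_chart()
#' lookup_risk(chart, "male", FALSE, TRUE, age = 62, sbp = 165, tc = 230)
#' lookup_risk(chart, "male", FALSE, TRUE, age = 62, sbp = 165, tc = NA)
#' @export
lookup_risk <- function(chart, sex, diabetes, smoking, age, sbp, tc = NA,
                        tc_units = c("mg/dL", "mmol/L")) {
  stopifnot(inherits(chart, "cvd_chart"))
  tc_units <- match.arg(tc_units)
  n <- max(lengths(list(sex, diabetes, smoking, age, sbp, tc)))
  sex <- rep_len(sex, n); diabetes <- rep_len(diabetes, n)
  smoking <- rep_len(smoking, n); age <- rep_len(age, n)
  sbp <- rep_len(sbp, n); tc <- rep_len(tc, n)

  chart_age <- impute_chart_age(age)
  pathway <- ifelse(is.na(tc), "low_info", "high_info")
  tc_chart <- tc
  if (tc_units == "mg/dL" && chart$cholesterol_units == "mmol/L") {
    tc_chart <- tc / cvd_thresholds()$mgdl_per_mmol_tc
  }
  age_band <- band_index(chart_age, chart$axes$age)
  sbp_band <- band_index(pmax(chart$axes$sbp[1], sbp), chart$axes$sbp)
  tc_band <- ifelse(pathway == "high_info",
                    band_index(tc_chart, chart$axes$tc), NA_integer_)
  keys <- chart_key(pathway, sex, diabetes, smoking, age_band, sbp_band,
                    tc_band)
  category <- unname(chart$index[keys])
  if (anyNA(category)) {
    stop("risk lookup failed for input combination(s): ",
         paste(utils::head(keys[is.na(category)], 3), collapse = "; "),
         call. = FALSE)
  }
  tibble::tibble(category = category, pathway = pathway)
}

#' Audit a chart set for risk-ordering inversions
#'
#' Scans every pair of adjacent cells and reports each place where the
#' tabulated risk *decreases* as an axis moves in its risk-increasing
#' direction (higher SBP band, higher age band, higher cholesterol band,
#' non-smoker to smoker, non-diabetic to diabetic) with all other axes
#' fixed. Advisory only: violations are reported, never fatal, since a
#' user-supplied transcription of a published chart may legitimately
#' contain local inversions.
#'
#' @param chart A `cvd_chart` object.
#' @return A tibble of violations with one row per inverted adjacent
#'   pair (`pathway`, `axis`, the fixed coordinates, `from_category`,
#'   `to_category`); zero rows for a monotone chart.
#' @examples
#' nrow(audit_chart_monotonicity(synthetic_chart()))
#' @export
audit_chart_monotonicity <- function(chart) {
  stopifnot(inherits(chart, "cvd_chart"))
  cells <- chart$cells
  cells$rank <- match(cells$category, risk_categories())
  idx <- chart_key(cells$pathway, cells$sex, cells$diabetes, cells$smoking,
                   cells$age_band, cells$sbp_band, cells$tc_band)
  rank_by_key <- stats::setNames(cells$rank, idx)
  step <- function(axis) {
    nxt <- cells
    if (axis == "smoking") {
      keep <- !cells$smoking; nxt$smoking <- TRUE
    } else if (axis == "diabetes") {
      keep <- !cells$diabetes; nxt$diabetes <- TRUE
    } else {
      nxt[[axis]] <- cells[[axis]] + 1L
      keep <- !is.na(cells[[axis]])
    }
    up_keys <- chart_key(nxt$pathway, nxt$sex, nxt$diabetes, nxt$smoking,
                         nxt$age_band, nxt$sbp_band, nxt$tc_band)
    up_rank <- rank_by_key[up_keys]
    bad <- which(keep & !is.na(up_rank) & up_rank < cells$rank)
    if (!length(bad)) return(NULL)
    tibble::tibble(
      pathway = cells$pathway[bad], axis = axis,
      sex = cells$sex[bad], diabetes = cells$diabetes[bad],
      smoking = cells$smoking[bad], age_band = cells$age_band[bad],
      sbp_band = cells$sbp_band[bad], tc_band = cells$tc_band[bad],
      from_category = cells$category[bad],
      to_category = risk_categories()[up_rank[bad]]
    )
  }
  res <- purrr::map(c("sbp_band", "age_band", "tc_band", "smoking",
                      "diabetes"), step)
  res <- dplyr::bind_rows(res)
  if (!nrow(res)) {
    res <- tibble::tibble(
      pathway = character(), axis = character(), sex = character(),
      diabetes = logical(), smoking = logical(), age_band = integer(),
      sbp_band = integer(), tc_band = integer(),
      from_category = character(), to_category = character()
    )
  }
  res
}
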