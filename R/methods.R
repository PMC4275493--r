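# Tidiers and plot methods for result objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy an agreement report
#'
#' @param x A `cvd_agreement` object from [compare_cohort()].
#' @param ... Unused.
#' @return A tibble with one row per calculated variable: `variable`,
#'   `agreement` (fraction of records agreeing), `n_discrepant`.
#' @method tidy cvd_agreement
#' @export
tidy.cvd_agreement <- function(x, ...) {
  tibble::tibble(
    variable = names(x$per_variable_agreement),
    agreement = unname(x$per_variable_agreement),
    n_discrepant = round((1 - unname(x$per_variable_agreement)) *
                           x$n_records)
  )
}

#' Glance at an agreement report
#'
#' @inheritParams tidy.cvd_agreement
#' @return A one-row tibble: `n_records`, `n_variables`,
#'   `n_variables_fully_agreeing`, `pct_variables_agreeing`,
#'   `n_discrepancies`.
#' @method glance cvd_agreement
#' @export
glance.cvd_agreement <- function(x, ...) {
  nv <- length(x$per_variable_agreement)
  tibble::tibble(
    n_records = x$n_records,
    n_variables = nv,
    n_variables_fully_agreeing = x$n_variables_fully_agreeing,
    pct_variables_agreeing = 100 * x$n_variables_fully_agreeing / nv,
    n_discrepancies = nrow(x$discrepancies)
  )
}

#' Plot per-variable agreement
#'
#' Horizontal bars of per-variable agreement fractions, lowest first, so
#' any variable short of full agreement is immediately visible.
#'
#' @param object A `cvd_agreement` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot cvd_agreement
#' @export
autoplot.cvd_agreement <- function(object, ...) {
  d <- tidy(object)
  d$variable <- stats::reorder(d$variable, d$agreement)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$agreement, y = .data$variable)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_vline(xintercept = 1, linetype = 2, colour = "grey40") +
    ggplot2::scale_x_continuous(limits = c(0, 1.02),
                                expand = c(0, 0)) +
    ggplot2::labs(x = "agreement (fraction of records)", y = NULL,
                  title = sprintf("Engine vs oracle: %d/%d variables fully agree",
                                  object$n_variables_fully_agreeing,
                                  length(object$per_variable_agreement))) +
    ggplot2::theme_minimal()
}

#' Tidy a care cascade
#'
#' @param x A `cvd_cascade` object from [compute_cascade()].
#' @param ... Unused.
#' @return A tibble with one row per cascade stage: `stage`, `n`, and
#'   (where defined) `percent_of_previous`.
#' @method tidy cvd_cascade
#' @export
tidy.cvd_cascade <- function(x, ...) {
  sp <- x$stage_percentages
  tibble::tibble(
    stage = names(x$counts),
    n = unname(x$counts),
    percent_of_previous = vapply(names(x$counts), function(s) {
      i <- match(s, sp$numerator)
      if (is.na(i)) NA_real_ else sp$percent[i]
    }, numeric(1))
  )
}

#' Glance at a care cascade
#'
#' @inheritParams tidy.cvd_cascade
#' @return A one-row tibble with all stage counts and percentages.
#' @method glance cvd_cascade
#' @export
glance.cvd_cascade <- function(x, ...) {
  out <- tibble::as_tibble(as.list(x$counts))
  sp <- x$stage_percentages
  pcts <- stats::setNames(as.list(sp$percent),
                          paste0("pct_", sp$numerator))
  dplyr::bind_cols(out, tibble::as_tibble(pcts),
                   tibble::tibble(n_excluded_pvd_only =
                                    x$n_excluded_pvd_only))
}

#' Plot a care cascade
#'
#' Funnel-style bar chart of the pathway stages with counts and
#' consecutive-stage percentages annotated.
#'
#' @param object A `cvd_cascade` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot cvd_cascade
#' @export
autoplot.cvd_cascade <- function(object, ...) {
  d <- tidy(object)
  d$stage <- factor(d$stage, levels = rev(d$stage))
  d$label <- ifelse(is.na(d$percent_of_previous), as.character(d$n),
                    sprintf("%d (%d%%)", d$n, d$percent_of_previous))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$n, y = .data$stage)) +
    ggplot2::geom_col(fill = "firebrick4", alpha = 0.85) +
    ggplot2::geom_text(ggplot2::aes(label = .data$label), hjust = -0.1,
                       size = 3.3) +
    ggplot2::scale_x_continuous(expand = ggplot2::expansion(mult = c(0, 0.18))) +
    ggplot2::labs(x = "patients", y = NULL,
                  title = "Screening-to-adherence care cascade") +
    ggplot2::theme_minimal()
}

#' Plot the risk-category mix of an assessed cohort
#'
#' @param assessments Output of [assess_cohort()].
#' @return A ggplot bar chart of adjusted risk categories in risk order.
#' @export
plot_risk_mix <- function(assessments) {
  d <- dplyr::count(tibble::as_tibble(assessments),
                    .data$adjusted_risk_category)
  d$adjusted_risk_category <- factor(d$adjusted_risk_category,
                                     levels = adjusted_categories())
  ggplot2::ggplot(d, ggplot2::aes(x = .data$adjusted_risk_category,
                                  y = .data$n)) +
    ggplot2::geom_col(fill = "darkorange3") +
    ggplot2::labs(x = "adjusted 10-year CVD risk category", y = "patients") +
    ggplot2::theme_minimal()
}
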