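#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a calibration fit
#'
#' @param x a `pm_calibration`.
#' @param ... unused.
#' @return a tibble of fixed-effect terms and estimates.
#' @export
tidy.pm_calibration <- function(x, ...) {
  tibble::tibble(term = names(x$coef), estimate = unname(x$coef))
}

#' @rdname tidy.pm_calibration
#' @export
glance.pm_calibration <- function(x, ...) {
  tibble::tibble(r2 = x$r2, rmse = x$rmse, n_pairs = x$n_pairs,
                 cutoff_km = x$cutoff_km,
                 var_participant = x$var_participant,
                 var_residual = x$var_residual, singular = x$singular)
}

#' Tidy the spatiotemporal mixed model
#'
#' @param x a `pm_exposure_model`.
#' @param ... unused.
#' @return the coefficient tibble (term, estimate, se, ci_lo, ci_hi, p,
#'   p_bh).
#' @export
tidy.pm_exposure_model <- function(x, ...) x$coefficients

#' @rdname tidy.pm_exposure_model
#' @export
glance.pm_exposure_model <- function(x, ...) {
  tibble::tibble(n = nrow(x$data),
                 n_participants = length(unique(x$data$studyid)),
                 var_participant = x$var_participant,
                 var_residual = x$var_residual, icc = x$icc,
                 adjustment = x$adjustment)
}

#' Dose-apportionment bar chart
#'
#' @param object a `pm_dose`.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.pm_dose <- function(object, ...) {
  d <- object$microenv
  ggplot2::ggplot(d, ggplot2::aes(
    x = stats::reorder(.data$microenv, -.data$dose_prop),
    y = .data$dose_prop)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::scale_y_continuous(labels = function(v) sprintf("%.0f%%", 100 * v)) +
    ggplot2::labs(x = NULL, y = "share of inhaled dose",
                  title = "PM2.5 dose apportionment by microenvironment") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}

#' Calibration fitted-vs-reference plot
#'
#' @param object a `pm_calibration`.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.pm_calibration <- function(object, ...) {
  stopifnot(!is.null(object$diag))
  ggplot2::ggplot(object$diag, ggplot2::aes(.data$fitted, .data$ref)) +
    ggplot2::geom_point(alpha = 0.3, size = 0.8) +
    ggplot2::geom_abline(slope = 1, intercept = 0, colour = "firebrick") +
    ggplot2::labs(x = "calibrated hourly mean (ug/m3)",
                  y = "reference station (ug/m3)",
                  title = sprintf("In-situ calibration: R2 = %.2f, RMSE = %.2f",
                                  object$r2, object$rmse)) +
    ggplot2::theme_minimal()
}

#' Coefficient forest plot for the exposure model
#'
#' @param object a `pm_exposure_model`.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.pm_exposure_model <- function(object, ...) {
  d <- object$coefficients[object$coefficients$term != "(Intercept)", ]
  ggplot2::ggplot(d, ggplot2::aes(.data$estimate,
                                  stats::reorder(.data$term, .data$estimate))) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$ci_lo,
                                         xmax = .data$ci_hi), height = 0.2) +
    ggplot2::geom_point() +
    ggplot2::labs(x = "coefficient (ug/m3)", y = NULL,
                  title = "Spatiotemporal mixed-model coefficients") +
    ggplot2::theme_minimal()
}

#' Cut-off scan diagnostic plot
#'
#' @param scan the scan tibble from [scan_cutoffs()].
#' @return a ggplot.
#' @export
plot_cutoff_scan <- function(scan) {
  ggplot2::ggplot(scan, ggplot2::aes(.data$cutoff_km, .data$r2)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = "pairing cut-off (km)", y = expression(R^2),
                  title = "Calibration goodness of fit by cut-off distance") +
    ggplot2::theme_minimal()
}
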