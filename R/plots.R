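#' Bland-Altman plot
#'
#' Difference-versus-mean scatter with the bias line (dashed) and the 1.96 SD
#' limits of agreement (dotted).
#'
#' @param object A [bland_altman()] fit.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.bland_altman <- function(object, ...) {
  ggplot2::ggplot(object$data, ggplot2::aes(x = .data$mean, y = .data$diff)) +
    ggplot2::geom_hline(yintercept = object$mean_diff, linetype = "dashed") +
    ggplot2::geom_hline(yintercept = c(object$loa_low, object$loa_high),
                        linetype = "dotted") +
    ggplot2::geom_point() +
    ggplot2::labs(
      x = "Mean of methods (deg)",
      y = "Difference, test - reference (deg)",
      title = sprintf("Bland-Altman: bias %.2f deg, LoA [%.2f, %.2f]",
                      object$mean_diff, object$loa_low, object$loa_high)
    ) +
    ggplot2::theme_minimal()
}

#' Passing-Bablok regression plot
#'
#' Paired scatter with the fitted Passing-Bablok line (solid) and the
#' identity line (dotted).
#'
#' @param object A [passing_bablok()] fit.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.passing_bablok <- function(object, ...) {
  ggplot2::ggplot(object$data, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dotted") +
    ggplot2::geom_abline(slope = object$slope, intercept = object$intercept) +
    ggplot2::geom_point() +
    ggplot2::labs(
      x = "Reference method (deg)", y = "Test method (deg)",
      title = sprintf(
        "Passing-Bablok: slope %.3f (angle %.1f deg), intercept %.2f",
        object$slope, object$slope_angle_deg, object$intercept)
    ) +
    ggplot2::theme_minimal()
}

#' Per-angle precision plot
#'
#' Dot plot of intra- and interobserver coefficients of variation per angle
#' variant and side from a precision experiment summary.
#'
#' @param object A `precision_experiment`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.precision_experiment <- function(object, ...) {
  long <- object$summary |>
    tidyr::pivot_longer(c("cv_intra", "cv_inter"), names_to = "pairing",
                        names_prefix = "cv_", values_to = "cv_percent")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$angle, y = .data$cv_percent,
                                     shape = .data$side,
                                     colour = .data$pairing)) +
    ggplot2::geom_point(position = ggplot2::position_dodge(width = 0.5),
                        size = 2) +
    ggplot2::geom_hline(yintercept = c(3, 10, 15), linetype = "dotted") +
    ggplot2::labs(x = NULL, y = "CV for repeated measurements (%)") +
    ggplot2::theme_minimal()
}
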