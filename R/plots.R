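#' Plot a phase-difference histogram
#'
#' @param object a `psi_histogram` from [phase_histogram()].
#' @param ... unused.
#' @return A ggplot object.
#' @method autoplot psi_histogram
#' @export
autoplot.psi_histogram <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$mid, y = .data$density)) +
    ggplot2::geom_col(width = object$bin_right[1] - object$bin_left[1],
                      fill = "grey70", colour = "grey30") +
    ggplot2::geom_hline(yintercept = 1 / (2 * pi), linetype = "dashed") +
    ggplot2::scale_x_continuous(
      breaks = c(0, pi / 2, pi, 3 * pi / 2, 2 * pi),
      labels = c("0", "π/2", "π", "3π/2", "2π")) +
    ggplot2::labs(x = expression(psi), y = "density") +
    ggplot2::theme_minimal()
}

#' Plot fitted coupling functions with posterior bands
#'
#' One panel per directed edge showing the posterior-mean coupling function,
#' a pointwise two-posterior-sd band, and (when `truth` is supplied) the
#' generating function as a dashed line.
#'
#' @param object a `phase_fit` from [estimate_model()].
#' @param truth optional generating [phase_model()].
#' @param ... forwarded to [coupling_curves()].
#' @return A ggplot object.
#' @method autoplot phase_fit
#' @export
autoplot.phase_fit <- function(object, truth = NULL, ...) {
  cc <- coupling_curves(object, truth = truth, ...)
  p <- ggplot2::ggplot(cc, ggplot2::aes(x = .data$psi)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lower, ymax = .data$upper),
                         fill = "indianred", alpha = 0.3) +
    ggplot2::geom_line(ggplot2::aes(y = .data$estimate), colour = "indianred")
  if ("truth" %in% names(cc)) {
    p <- p + ggplot2::geom_line(ggplot2::aes(y = .data$truth),
                                linetype = "dashed", colour = "black")
  }
  p + ggplot2::facet_wrap(~edge, scales = "free_y") +
    ggplot2::labs(x = expression(psi),
                  y = expression(Gamma(psi) ~ "(rad / unit time)")) +
    ggplot2::theme_minimal()
}

#' Plot a surrogate ensemble
#'
#' Histogram of surrogate coupling powers with the original (unshifted)
#' power marked; the subtitle reports the empirical p-value and the selected
#' Fourier orders.
#'
#' @param object a `surrogate_ensemble` from [surrogate_scan()].
#' @param ... unused.
#' @return A ggplot object.
#' @method autoplot surrogate_ensemble
#' @export
autoplot.surrogate_ensemble <- function(object, ...) {
  o <- attr(object, "original")
  ggplot2::ggplot(object, ggplot2::aes(x = .data$power)) +
    ggplot2::geom_histogram(bins = 20, fill = "steelblue", colour = "grey20") +
    ggplot2::geom_vline(xintercept = o$power, colour = "red") +
    ggplot2::labs(
      x = "coupling power", y = "surrogates",
      subtitle = sprintf("original M = %d, power = %.3g, p = %.3g",
                         o$M, o$power, attr(object, "p_value"))) +
    ggplot2::theme_minimal()
}

#' Plot a phase sensitivity function
#'
#' @param object a `phase_sensitivity` from [adjoint_sensitivity()].
#' @param ... unused.
#' @return A ggplot object showing both components of `Z` over one cycle.
#' @method autoplot phase_sensitivity
#' @export
autoplot.phase_sensitivity <- function(object, ...) {
  df <- tibble(phi = rep(object$phi, 2L),
               component = rep(c("Z_x", "Z_y"), each = length(object$phi)),
               value = c(object$Z[, 1], object$Z[, 2]))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$phi, y = .data$value,
                                   colour = .data$component)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = expression(phi), y = "phase sensitivity") +
    ggplot2::theme_minimal()
}

#' Plot a theoretical coupling table
#'
#' @param object a `coupling_table` from [theoretical_coupling()].
#' @param ... unused.
#' @return A ggplot object.
#' @method autoplot coupling_table
#' @export
autoplot.coupling_table <- function(object, ...) {
  ggplot2::ggplot(object$table, ggplot2::aes(x = .data$psi, y = .data$gamma)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = expression(psi), y = expression(Gamma(psi))) +
    ggplot2::theme_minimal()
}
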