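# ggplot2 visualisations

#' @exportS3Method ggplot2::autoplot
autoplot.standard_curve <- function(object, ...) {
  d <- object$fit$model
  ggplot2::ggplot(tibble(log10_quantity = d$x, ct = d$y),
                  ggplot2::aes(x = .data$log10_quantity, y = .data$ct)) +
    ggplot2::geom_point() +
    ggplot2::geom_abline(slope = object$slope, intercept = object$intercept,
                         colour = "steelblue") +
    ggplot2::labs(
      x = "log10 input quantity", y = "Ct",
      title = sprintf("Standard curve: slope %.3f, E = %.2f, r² = %.4f",
                      object$slope, object$efficiency, object$r2)) +
    ggplot2::theme_minimal()
}

#' Plot a melt curve and its derivative
#'
#' Two stacked panels: the raw fluorescence trace and the `-dF/dT`
#' derivative with detected peaks marked.
#'
#' @param curve a melt-curve data frame (`temperature`, `fluorescence`).
#' @param smoothing_window,min_prominence passed to [melt_peaks()].
#' @return a ggplot object.
#' @export
plot_melt_curve <- function(curve, smoothing_window = 3, min_prominence = NULL) {
  pk <- melt_peaks(curve, smoothing_window, min_prominence)
  fs <- moving_average(curve$fluorescence, smoothing_window)
  n <- length(fs)
  inner <- 2:(n - 1L)
  deriv <- tibble(
    temperature = curve$temperature[inner],
    value = -(fs[inner + 1L] - fs[inner - 1L]) /
      (curve$temperature[inner + 1L] - curve$temperature[inner - 1L]),
    panel = "-dF/dT")
  raw <- tibble(temperature = curve$temperature, value = curve$fluorescence,
                panel = "fluorescence")
  ggplot2::ggplot(bind_rows(raw, deriv),
                  ggplot2::aes(x = .data$temperature, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(data = pk, ggplot2::aes(xintercept = .data$temperature),
                        linetype = "dashed", colour = "firebrick") +
    ggplot2::facet_wrap(~panel, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "temperature (°C)", y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot normalized expression with SEM error bars
#'
#' Bar chart of A.U. per assay, filled by cultivar and faceted by tissue --
#' the standard presentation of a multi-gene expression profile.
#'
#' @param expr output of [quantify_expression()].
#' @return a ggplot object.
#' @export
plot_expression <- function(expr) {
  ggplot2::ggplot(expr, ggplot2::aes(x = .data$assay_id, y = .data$au_mean,
                                     fill = .data$cultivar)) +
    ggplot2::geom_col(position = ggplot2::position_dodge(width = 0.9)) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$au_mean - .data$au_sem,
                   ymax = .data$au_mean + .data$au_sem),
      position = ggplot2::position_dodge(width = 0.9), width = 0.3) +
    ggplot2::facet_wrap(~tissue) +
    ggplot2::labs(x = NULL, y = "normalized expression (A.U.)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 60, hjust = 1))
}
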