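#' Dispersion plot of RT against a predictor with fitted curves
#'
#' Scatter of (optionally subsampled) single trials with the fitted linear
#' and sigmoid curves overlaid. Subsampling affects the display only; the
#' fits always use all points.
#'
#' @param trials Trial tibble carrying the predictor column.
#' @param predictor Column name, e.g. `"jp_1"`.
#' @param orientation Sigmoid orientation for the fit.
#' @param display_frac Fraction of points drawn.
#' @param window Analysis trial window.
#' @return A ggplot object.
#' @export
plot_dispersion <- function(trials, predictor = "jp_1",
                            orientation = "decreasing",
                            display_frac = 0.025, window = c(442, 1078)) {
  dat <- trials |>
    dplyr::filter(.data$correct, .data$trial >= window[1],
                  .data$trial <= window[2],
                  is.finite(.data[[predictor]]))
  lin <- fit_linear(dat[[predictor]], dat$rt_ms)
  sig <- fit_sigmoid(dat[[predictor]], dat$rt_ms, orientation = orientation)
  xs <- seq(min(dat[[predictor]]), max(dat[[predictor]]), length.out = 200)
  curves <- dplyr::bind_rows(
    tibble::tibble(x = xs, fn = "linear",
                   y = lin$params$intercept + lin$params$slope * xs),
    if (sig$converged) tibble::tibble(
      x = xs, fn = "sigmoid",
      y = sigmoid_rt(xs, do.call(sigmoid_params, sig$params), orientation)))
  shown <- dat[unique(round(seq(1, nrow(dat),
                                length.out = max(2, round(nrow(dat) * display_frac))))), ]
  ggplot2::ggplot(shown, ggplot2::aes(.data[[predictor]], .data$rt_ms)) +
    ggplot2::geom_point(alpha = 0.3, size = 0.8) +
    ggplot2::geom_line(data = curves,
                       ggplot2::aes(.data$x, .data$y, colour = .data$fn),
                       linewidth = 0.9) +
    ggplot2::labs(x = predictor, y = "RT (ms)", colour = "fit") +
    ggplot2::theme_minimal()
}

#' Bar grid of explained variance
#'
#' @param grid A comparison grid from [compare_predictors_trialwise()] or
#'   [compare_predictors_sessionwise()].
#' @return A ggplot object: R-squared per predictor and function, faceted
#'   over history length.
#' @export
plot_comparison_grid <- function(grid) {
  ggplot2::ggplot(grid,
                  ggplot2::aes(.data$predictor, .data$r_squared,
                               fill = .data$fn)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::facet_wrap(~n_prev, nrow = 1,
                        labeller = ggplot2::label_both) +
    ggplot2::labs(y = expression(R^2), x = NULL, fill = NULL) +
    ggplot2::theme_minimal()
}

#' Block-wise sigmoid parameter trajectories
#'
#' @param trajectory Output of [blockwise_sigmoid()].
#' @return A ggplot object: `Xhalf`, `Ymax`, `Ymin` (with standard-error
#'   ribbons) across training blocks.
#' @export
plot_trajectory <- function(trajectory) {
  long <- trajectory |>
    dplyr::filter(.data$converged) |>
    tidyr::pivot_longer(cols = c("xhalf", "ymax", "ymin"),
                        names_to = "parameter", values_to = "estimate") |>
    dplyr::mutate(se = dplyr::case_when(
      .data$parameter == "xhalf" ~ .data$xhalf_se,
      .data$parameter == "ymax" ~ .data$ymax_se,
      TRUE ~ .data$ymin_se))
  ggplot2::ggplot(long, ggplot2::aes(.data$block, .data$estimate)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$estimate - .data$se,
                                      ymax = .data$estimate + .data$se),
                         alpha = 0.2) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::facet_wrap(~parameter, scales = "free_y") +
    ggplot2::labs(x = "training block", y = "estimate") +
    ggplot2::theme_minimal()
}
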