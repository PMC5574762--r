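# Diagnostic figures: divergent-genome growth per replicate, the F_ST
# landscape of one pair, and scenario coefficient means with bootstrap
# intervals.

#' Plot divergent-genome-size growth
#'
#' One line per replicate of outlier-window count versus divergence time
#' (in units of N generations), optionally faceted by scenario.
#'
#' @param series A series tibble (`run_scenario()$series` or
#'   `run_experiment()$series`; minimally `t_scaled`, `n_outlier`, and
#'   optionally `replicate`, `scenario`).
#' @return A ggplot object.
#' @export
plot_growth_series <- function(series) {
  stopifnot(all(c("t_scaled", "n_outlier") %in% names(series)))
  grp <- if ("replicate" %in% names(series))
    ggplot2::aes(x = .data$t_scaled, y = .data$n_outlier,
                 group = .data$replicate)
  else ggplot2::aes(x = .data$t_scaled, y = .data$n_outlier)
  p <- ggplot2::ggplot(series, grp) +
    ggplot2::geom_line(alpha = 0.4) +
    ggplot2::labs(x = "divergence time (N generations)",
                  y = "outlier windows") +
    ggplot2::theme_minimal()
  if ("scenario" %in% names(series))
    p <- p + ggplot2::facet_wrap(~scenario, scales = "free_y")
  p
}

#' Plot the windowed F_ST landscape of one pair
#'
#' @param windows A [window_table()] (optionally with an `outlier` column,
#'   highlighted in red).
#' @return A ggplot object.
#' @export
plot_fst_landscape <- function(windows) {
  p <- ggplot2::ggplot(windows,
                       ggplot2::aes(x = (.data$start_bp + .data$end_bp) / 2,
                                    y = .data$fst)) +
    ggplot2::geom_step(na.rm = TRUE) +
    ggplot2::labs(x = "position (bp)", y = expression(F[ST])) +
    ggplot2::theme_minimal()
  if ("outlier" %in% names(windows))
    p <- p + ggplot2::geom_point(
      data = dplyr::filter(windows, .data$outlier),
      colour = "red", size = 0.8, na.rm = TRUE)
  p
}

#' Plot scenario coefficient means with bootstrap intervals
#'
#' Replicate coefficients as open points, scenario means as filled points
#' with BCa intervals.
#'
#' @param summary A [scenario_summary()] tibble.
#' @param fits Optional per-replicate fits for the underlying points.
#' @return A ggplot object.
#' @export
plot_coefficients <- function(summary, fits = NULL) {
  p <- ggplot2::ggplot(summary, ggplot2::aes(x = .data$scenario,
                                             y = .data$mean_b))
  if (!is.null(fits))
    p <- p + ggplot2::geom_jitter(
      data = dplyr::filter(fits, .data$converged),
      ggplot2::aes(y = .data$b), width = 0.08, shape = 1, alpha = 0.6)
  p +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$ci_lower,
                                          ymax = .data$ci_upper),
                             colour = "black") +
    ggplot2::labs(x = NULL, y = "exponential coefficient b") +
    ggplot2::theme_minimal()
}

#' @describeIn fit_linear_origin Plot a fitted growth curve over the data.
#' @param object A `growth_fit`.
#' @param ... Unused.
#' @export
autoplot.growth_fit <- function(object, ...) {
  d <- object$data
  xs <- seq(0, max(d$x), length.out = 200)
  ys <- if (object$model == "linear_origin") object$params[["c"]] * xs
        else object$params[["a"]] * (1 - exp(object$params[["b"]] * xs))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(data = data.frame(x = xs, y = ys), colour = "blue") +
    ggplot2::labs(x = "divergence time (N generations)",
                  y = "outlier windows") +
    ggplot2::theme_minimal()
}
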