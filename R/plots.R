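#' Plot an ROI fluctuation curve
#'
#' Relative error (sd/mean) of the metric versus ROI volume on log-log
#' axes, optionally with a fitted power law overlaid.
#'
#' @param curve a `roi_scale_curve`.
#' @param fit optional `scaling_fit` to overlay.
#' @return A ggplot object.
#' @export
plot_roi_curve <- function(curve, fit = NULL) {
  stopifnot(inherits(curve, "roi_scale_curve"))
  p <- ggplot2::ggplot(curve[is.finite(curve$rel_err), ],
                       ggplot2::aes(x = .data$v_roi_um3, y = .data$rel_err)) +
    ggplot2::geom_point() +
    ggplot2::geom_line() +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = expression(V[ROI] ~ (mu * m^3)),
                  y = expression(sigma / mu),
                  title = "Scale-dependence of morphometric fluctuations")
  if (!is.null(fit)) {
    pts <- fit$points
    pred <- exp(stats::predict(fit$fit))
    p <- p + ggplot2::geom_line(
      data = tibble::tibble(v_roi_um3 = pts$v_roi_um3, rel_err = pred),
      color = "red", linetype = 2)
  }
  p
}

#' Plot a radial autocorrelation curve
#'
#' @param curve a `correlation_curve`.
#' @param threshold decay threshold drawn as a horizontal line.
#' @return A ggplot object.
#' @export
plot_correlation_curve <- function(curve, threshold = 0.01) {
  stopifnot(inherits(curve, "correlation_curve"))
  ggplot2::ggplot(curve, ggplot2::aes(x = .data$r_um, y = .data$C_mean)) +
    ggplot2::geom_ribbon(ggplot2::aes(
      ymin = .data$C_mean - .data$C_sd, ymax = .data$C_mean + .data$C_sd),
      alpha = 0.2, fill = "steelblue") +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = threshold, linetype = 2) +
    ggplot2::labs(x = expression(r ~ (mu * m)), y = expression(hat(C)(r)),
                  title = "Radial two-point autocorrelation")
}

#' Plot a flow speed distribution
#'
#' Normalized frequency on a log scale versus speed, the conventional
#' rendering for porous-medium velocity distributions.
#'
#' @param vd a tibble from [velocity_distribution()].
#' @return A ggplot object.
#' @export
plot_velocity_distribution <- function(vd) {
  ggplot2::ggplot(vd[vd$frequency > 0, ],
                  ggplot2::aes(x = .data$speed_um_s, y = .data$frequency)) +
    ggplot2::geom_line() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = expression(speed ~ (mu * m / s)),
                  y = "normalized frequency",
                  title = "Flow speed distribution")
}

#' Plot branch metric distributions of a skeleton graph
#'
#' @param graph a `skeleton_graph` with metrics filled.
#' @return A ggplot object (histograms per metric).
#' @export
plot_branch_metrics <- function(graph) {
  stopifnot(inherits(graph, "skeleton_graph"))
  tb <- tidy(graph)
  long <- tidyr::pivot_longer(
    tb[, c("diameter_um", "length_um", "tortuosity")],
    cols = dplyr::everything(), names_to = "metric", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$value)) +
    ggplot2::geom_histogram(bins = 30) +
    ggplot2::facet_wrap(~metric, scales = "free") +
    ggplot2::labs(x = NULL, y = "branches",
                  title = "Branch morphometrics")
}
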