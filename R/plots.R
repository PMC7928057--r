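#' @export
#' @exportS3Method ggplot2::autoplot
autoplot.force_trace <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$time, y = .data$force)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Time (s)", y = "Force (N)")
}

#' @export
#' @exportS3Method ggplot2::autoplot
autoplot.trial_recording <- function(object, ...) {
  df <- dplyr::bind_rows(
    dplyr::mutate(as_tibble(object$target_v), channel = "vertical",
                  kind = "target"),
    dplyr::mutate(as_tibble(object$target_h), channel = "horizontal",
                  kind = "target"),
    dplyr::mutate(as_tibble(object$measured_v), channel = "vertical",
                  kind = "measured"),
    dplyr::mutate(as_tibble(object$measured_h), channel = "horizontal",
                  kind = "measured"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$force,
                                   colour = .data$channel,
                                   linetype = .data$kind)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Time (s)", y = "Force (N)",
                  title = sprintf("Commanded lag %s ms",
                                  format(object$commanded_lag)))
}

#' Spatial-trajectory plot of a trial
#'
#' Horizontal vs vertical force for the target and measured stages — the
#' loop traced in the force plane by the combined action of the two motors
#' (diagonal for small lags, an L-shaped near-right-triangle around the
#' half-cycle lag).
#'
#' @param rec A `trial_recording`.
#' @return A ggplot object.
#' @export
plot_spatial_trajectory <- function(rec) {
  df <- dplyr::bind_rows(
    dplyr::mutate(spatial_trajectory(rec, "target"), kind = "target"),
    dplyr::mutate(spatial_trajectory(rec, "measured"), kind = "measured"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$horizontal, y = .data$vertical,
                                   linetype = .data$kind)) +
    ggplot2::geom_path() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "Horizontal force (N)", y = "Vertical force (N)",
                  title = sprintf("Commanded lag %s ms",
                                  format(rec$commanded_lag)))
}

#' @export
#' @exportS3Method ggplot2::autoplot
autoplot.lag_correlation <- function(object, ...) {
  ggplot2::ggplot(object$data,
                  ggplot2::aes(x = .data$target_lag_ms,
                               y = .data$actual_lag_ms)) +
    ggplot2::geom_abline(slope = object$slope, intercept = object$intercept,
                         colour = "grey50") +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$actual_lag_ms - .data$actual_se_ms,
                   ymax = .data$actual_lag_ms + .data$actual_se_ms),
      width = 0, na.rm = TRUE) +
    ggplot2::geom_point() +
    ggplot2::labs(x = "Commanded lag (ms)", y = "Delivered lag (ms)",
                  subtitle = sprintf("r = %.4f", object$r))
}

#' @export
#' @exportS3Method ggplot2::autoplot
autoplot.psychometric_fit <- function(object, ...) {
  grid <- tibble(
    lag_ms = seq(min(object$proportions$lag_ms),
                 max(object$proportions$lag_ms), length.out = 200))
  grid$p <- logistic_p(grid$lag_ms, object$mu, object$s)
  ggplot2::ggplot(object$proportions,
                  ggplot2::aes(x = .data$lag_ms, y = .data$proportion)) +
    ggplot2::geom_hline(yintercept = 0.5, linetype = "dotted") +
    ggplot2::geom_line(data = grid, ggplot2::aes(y = .data$p)) +
    ggplot2::geom_point() +
    ggplot2::labs(x = "Lag (ms, positive = vertical first)",
                  y = "P(vertical judged first)",
                  subtitle = sprintf("PSE = %.1f ms, JND = %.1f ms",
                                     object$pse, object$jnd))
}

#' @export
#' @exportS3Method ggplot2::autoplot
autoplot.pooled_curve <- function(object, ...) {
  grid <- tibble(
    lag_ms = seq(min(object$pooled$lag_ms), max(object$pooled$lag_ms),
                 length.out = 200))
  grid$p <- logistic_p(grid$lag_ms, object$fit$mu, object$fit$s)
  ggplot2::ggplot(object$pooled,
                  ggplot2::aes(x = .data$lag_ms,
                               y = .data$mean_proportion)) +
    ggplot2::geom_hline(yintercept = 0.5, linetype = "dotted") +
    ggplot2::geom_line(data = grid, ggplot2::aes(y = .data$p)) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$mean_proportion - .data$se_proportion,
                   ymax = .data$mean_proportion + .data$se_proportion),
      width = 0, na.rm = TRUE) +
    ggplot2::geom_point() +
    ggplot2::labs(x = "Lag (ms, positive = vertical first)",
                  y = "Mean P(vertical judged first)")
}
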