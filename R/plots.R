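#' Predicted-versus-observed PS scatter
#'
#' Log-log scatter of predicted against observed PS with the identity
#' line (perfect prediction) and dashed 0.5x / 2x guide lines marking the
#' fold-success band.
#'
#' @param results tibble from [run_ivivc()].
#' @param fold_bounds bounds to draw (default `c(0.5, 2)`).
#' @return A ggplot object.
#' @export
plot_ivivc <- function(results, fold_bounds = c(0.5, 2)) {
  ggplot2::ggplot(results,
                  ggplot2::aes(x = .data$ps_obs, y = .data$ps_pre,
                               colour = .data$within_fold)) +
    ggplot2::geom_abline(slope = 1, intercept = 0) +
    ggplot2::geom_abline(slope = 1, intercept = log10(fold_bounds[1]),
                         linetype = "dashed") +
    ggplot2::geom_abline(slope = 1, intercept = log10(fold_bounds[2]),
                         linetype = "dashed") +
    ggplot2::geom_point(size = 2) +
    ggplot2::scale_x_log10() + ggplot2::scale_y_log10() +
    ggplot2::facet_wrap(~model_id) +
    ggplot2::labs(x = "observed PS (µL/min/g)",
                  y = "predicted PS (µL/min/g)",
                  colour = "within fold") +
    ggplot2::theme_bw()
}

#' TEER time-course plot
#'
#' Mean +/- SEM corrected TEER per model over culture days.
#'
#' @param timecourse tibble from [summarize_teer()].
#' @return A ggplot object.
#' @export
plot_teer <- function(timecourse) {
  ggplot2::ggplot(timecourse,
                  ggplot2::aes(x = .data$day, y = .data$teer_mean,
                               colour = .data$model_id)) +
    ggplot2::geom_line() +
    ggplot2::geom_pointrange(
      ggplot2::aes(ymin = .data$teer_mean - .data$teer_sem,
                   ymax = .data$teer_mean + .data$teer_sem)) +
    ggplot2::labs(x = "culture day",
                  y = "TEER (Ω·cm²)",
                  colour = "model") +
    ggplot2::theme_bw()
}
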