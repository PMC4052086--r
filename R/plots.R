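# ggplot2 views of result tables. Each experiment tibble carries a class
# so autoplot() picks the right layout.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot cross-validation results
#'
#' One point per fold and coordinate, with per-coordinate means.
#'
#' @param object A `cv_result` tibble from [cross_validate()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.cv_result <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$dim, y = .data$r)) +
    ggplot2::geom_jitter(width = 0.08, height = 0, alpha = 0.7) +
    ggplot2::stat_summary(fun = mean, geom = "crossbar", width = 0.4,
                          linewidth = 0.3, colour = "red") +
    ggplot2::labs(x = "coordinate", y = "Pearson r",
                  title = paste0("Cross-validated decoding accuracy (",
                                 object$decoder[1], ")")) +
    ggplot2::ylim(-1, 1) +
    ggplot2::theme_minimal()
}

#' Plot a training-size curve
#'
#' @param object A `training_curve` tibble from [training_size_curve()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.training_curve <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$n_train, y = .data$mean_r)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean_r - .data$sd_r,
                                      ymax = .data$mean_r + .data$sd_r),
                         alpha = 0.2) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "training trials", y = "mean test r",
                  title = "Decoding accuracy vs training-set size") +
    ggplot2::theme_minimal()
}

#' Plot an electrode contribution map
#'
#' Bars of single-electrode decoding correlation, sorted.
#'
#' @param object A `contribution_map` tibble from
#'   [electrode_contribution()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.contribution_map <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = stats::reorder(.data$channel, .data$r),
                               y = .data$r)) +
    ggplot2::geom_col() +
    ggplot2::coord_flip() +
    ggplot2::labs(x = "electrode", y = "single-electrode r",
                  title = "Electrode contribution to decoding") +
    ggplot2::theme_minimal()
}

#' Plot measured vs reconstructed trajectories
#'
#' Overlays the measured and decoded coordinates over time.
#'
#' @param predicted,measured Kinematics tibbles of equal length.
#' @return A ggplot object.
#' @export
plot_reconstruction <- function(predicted, measured) {
  dims <- channel_names(measured)
  long <- dplyr::bind_rows(
    tidyr::pivot_longer(dplyr::mutate(measured, series = "measured"),
                        dplyr::all_of(dims), names_to = "dim"),
    tidyr::pivot_longer(dplyr::mutate(predicted[c("time", dims)],
                                      series = "reconstructed"),
                        dplyr::all_of(dims), names_to = "dim"))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$time, y = .data$value,
                                     colour = .data$series)) +
    ggplot2::geom_line(linewidth = 0.4) +
    ggplot2::facet_wrap(~dim, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "time (s)", y = "position (standardized)") +
    ggplot2::theme_minimal()
}
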