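#' Plot a depth-binned efficiency profile
#'
#' Line-and-ribbon plot of (normalised) transduction efficiency against
#' imaging depth, one colour per condition; the ribbon is mean ± SEM over
#' organoids. An optional vertical line marks a layer boundary (e.g. the
#' outer/inner nuclear layer border).
#'
#' @param profile Either a [depth_profile()] (aggregated internally via
#'   [aggregate_profile()]) or an already aggregated tibble.
#' @param layer_boundary_um Optional depth of a layer boundary to mark.
#' @return A ggplot object.
#' @export
plot_depth_profile <- function(profile, layer_boundary_um = NULL) {
  agg <- if (inherits(profile, "depth_profile")) aggregate_profile(profile)
         else tibble::as_tibble(profile)
  has_cond <- "condition" %in% names(agg)
  p <- ggplot2::ggplot(agg, ggplot2::aes(
    x = .data$bin_center_um, y = .data$E,
    colour = if (has_cond) .data$condition else NULL,
    fill = if (has_cond) .data$condition else NULL
  ))
  if (all(c("SEM") %in% names(agg)) && any(!is.na(agg$SEM))) {
    p <- p + ggplot2::geom_ribbon(
      ggplot2::aes(ymin = .data$E - .data$SEM, ymax = .data$E + .data$SEM),
      alpha = 0.2, colour = NA
    )
  }
  p <- p + ggplot2::geom_line() + ggplot2::geom_point()
  if (!is.null(layer_boundary_um)) {
    p <- p + ggplot2::geom_vline(xintercept = layer_boundary_um,
                                 linetype = "dashed")
  }
  p + ggplot2::labs(x = "imaging depth (µm)",
                    y = "transduction efficiency",
                    colour = "condition", fill = "condition") +
    ggplot2::theme_minimal()
}

#' @rdname plot_depth_profile
#' @param object A [depth_profile()].
#' @param ... Passed to [plot_depth_profile()].
#' @export
autoplot.depth_profile <- function(object, ...) {
  plot_depth_profile(object, ...)
}

#' Plot a threshold calibration sweep
#'
#' Software plane efficiencies as a function of the shell overlap threshold,
#' with the manual per-plane reference as horizontal lines and the chosen
#' threshold marked.
#'
#' @param calibration A `threshold_calibration` from [calibrate_threshold()].
#' @return A ggplot object.
#' @export
plot_threshold_sweep <- function(calibration) {
  stopifnot(inherits(calibration, "threshold_calibration"))
  sw <- dplyr::mutate(calibration$full_sweep,
                      plane = factor(.data$plane_depth_um))
  ref <- dplyr::mutate(calibration$manual_reference,
                       plane = factor(.data$plane_depth_um))
  ggplot2::ggplot(sw, ggplot2::aes(x = .data$threshold, y = .data$E,
                                   colour = .data$plane)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::geom_hline(data = ref,
                        ggplot2::aes(yintercept = .data$manual_E,
                                     colour = .data$plane),
                        linetype = "dotted") +
    ggplot2::geom_vline(xintercept = calibration$threshold,
                        linetype = "dashed") +
    ggplot2::labs(x = "shell overlap threshold", y = "transduction efficiency",
                  colour = "plane depth (µm)") +
    ggplot2::theme_minimal()
}

#' @rdname plot_threshold_sweep
#' @param object A `threshold_calibration`.
#' @param ... Unused.
#' @export
autoplot.threshold_calibration <- function(object, ...) {
  plot_threshold_sweep(object)
}

#' Condition-level efficiency over time
#'
#' Point-and-errorbar (mean ± SEM over organoids) plot of condition-level
#' efficiency per timepoint.
#'
#' @param condition_tbl The `condition` tibble from [aggregate_efficiency()].
#' @return A ggplot object.
#' @export
plot_efficiency_timecourse <- function(condition_tbl) {
  ggplot2::ggplot(condition_tbl, ggplot2::aes(
    x = .data$timepoint, y = .data$E, colour = .data$condition,
    group = .data$condition
  )) +
    ggplot2::geom_point(position = ggplot2::position_dodge(width = 0.3)) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$E - .data$SEM, ymax = .data$E + .data$SEM),
      width = 0.2, position = ggplot2::position_dodge(width = 0.3)
    ) +
    ggplot2::geom_line(position = ggplot2::position_dodge(width = 0.3),
                       alpha = 0.5) +
    ggplot2::labs(x = "timepoint", y = "transduction efficiency",
                  colour = "condition") +
    ggplot2::theme_minimal()
}
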