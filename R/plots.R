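#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a staircase trial log
#'
#' Contrast track over trials with reversals highlighted and the
#' estimated threshold as a horizontal line.
#'
#' @param object A `staircase_run`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.staircase_run <- function(object, ...) {
  log <- tidy(object)
  p <- ggplot2::ggplot(log, ggplot2::aes(x = .data$trial, y = .data$contrast)) +
    ggplot2::geom_step() +
    ggplot2::geom_point(
      data = log[log$reversal, ],
      colour = "firebrick", size = 2
    ) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(
      x = "Trial", y = "Contrast",
      title = sprintf(
        "3-down-1-up staircase, %g cpd (%s meridian)",
        object$sf, object$meridian
      )
    )
  if (object$converged) {
    p <- p + ggplot2::geom_hline(
      yintercept = object$threshold_estimate, linetype = "dashed"
    )
  }
  p
}

#' Plot a sweep-VEP response function
#'
#' Second-harmonic amplitude against swept spatial frequency with
#' vector-SE error bars and the noise amplitude as a reference line.
#'
#' @param object A `sweep_response`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.sweep_response <- function(object, ...) {
  d <- as_tibble(object)
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$swept_sf, y = .data$amplitude)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_line(
      ggplot2::aes(y = .data$noise_amplitude),
      linetype = "dotted"
    ) +
    ggplot2::labs(
      x = "Spatial frequency (cpd)",
      y = expression("Amplitude (" * mu * "V)"),
      title = "Sweep-VEP response at the second harmonic"
    )
  if ("vector_se" %in% names(d)) {
    p <- p + ggplot2::geom_errorbar(
      ggplot2::aes(
        ymin = .data$amplitude - .data$vector_se,
        ymax = .data$amplitude + .data$vector_se
      ),
      width = 0.2
    )
  }
  p
}

#' Plot log CSF points
#'
#' @param points A CSF points tibble from [thresholds_to_csf()].
#' @return A ggplot object (log10 sensitivity vs log10 spatial
#'   frequency).
#' @export
plot_csf <- function(points) {
  pts <- check_points(points)
  ggplot2::ggplot(
    pts, ggplot2::aes(x = .data$log10_sf, y = .data$log10_sensitivity)
  ) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed") +
    ggplot2::labs(
      x = "log10 spatial frequency (cpd)",
      y = "log10 contrast sensitivity",
      title = "Contrast sensitivity function"
    )
}

#' Plot a meridional disparity report
#'
#' Strong/weak means with SE bars, one panel per group.
#'
#' @param object A `disparity_report`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.disparity_report <- function(object, ...) {
  d <- as_tibble(object) |>
    tidyr::pivot_longer(
      cols = c("strong_mean", "weak_mean"),
      names_to = "meridian", values_to = "mean"
    ) |>
    dplyr::mutate(
      se = ifelse(
        .data$meridian == "strong_mean", .data$strong_se, .data$weak_se
      ),
      meridian = ifelse(
        .data$meridian == "strong_mean", "strong", "weak"
      )
    )
  ggplot2::ggplot(
    d,
    ggplot2::aes(x = .data$metric, y = .data$mean, fill = .data$meridian)
  ) +
    ggplot2::geom_col(position = ggplot2::position_dodge(width = 0.8), width = 0.7) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$mean - .data$se, ymax = .data$mean + .data$se),
      position = ggplot2::position_dodge(width = 0.8), width = 0.2
    ) +
    ggplot2::facet_wrap(~group) +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "Mean ± SE", fill = "Meridian")
}
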