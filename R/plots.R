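#' Diagnostic plots for a study run
#'
#' Lightweight ggplot2 mirrors of the study's figures: per-crowd box plots
#' of image scores, the per-photo error spread ordered by descending median
#' error, and the variability-versus-error scatter with its fitted line.
#' ggplot2 is only suggested; these functions error if it is unavailable.
#'
#' @param results a [run_study()] result list.
#' @param metric which score to plot, `"dice"` or `"surface_area_error"`.
#' @return a ggplot object.
#' @export
plot_crowd_performance <- function(results, metric = c("surface_area_error", "dice")) {
  metric <- match.arg(metric)
  need_ggplot2()
  ggplot2::ggplot(
    results$scores,
    ggplot2::aes(x = .data$label, y = .data[[metric]])
  ) +
    ggplot2::geom_boxplot(outlier.size = 0.6) +
    ggplot2::labs(x = "crowd", y = metric)
}

#' @rdname plot_crowd_performance
#' @param crowd_name crowd to plot (defaults to the first in the results).
#' @export
plot_photo_spread <- function(results, crowd_name = NULL) {
  need_ggplot2()
  sp <- results$photo_spread
  crowd_name <- crowd_name %||% sp$crowd_name[1]
  sp <- sp[sp$crowd_name == crowd_name, , drop = FALSE]
  sp$photo_id <- factor(sp$photo_id, levels = sp$photo_id)
  ggplot2::ggplot(sp, ggplot2::aes(x = .data$photo_id)) +
    ggplot2::geom_ribbon(
      ggplot2::aes(ymin = .data$min_error, ymax = .data$max_error, group = 1),
      fill = "grey80"
    ) +
    ggplot2::geom_line(ggplot2::aes(y = .data$median_error, group = 1)) +
    ggplot2::labs(
      x = "photo (descending median error)",
      y = "surface area error (% of skin)", title = crowd_name
    ) +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, size = 6))
}

#' @rdname plot_crowd_performance
#' @export
plot_variability_vs_error <- function(results, crowd_name = NULL) {
  need_ggplot2()
  pts <- results$regression_points
  crowd_name <- crowd_name %||% pts$crowd_name[1]
  pts <- pts[pts$crowd_name == crowd_name, , drop = FALSE]
  ggplot2::ggplot(pts, ggplot2::aes(x = .data$sd_fraction, y = .data$consensus_error)) +
    ggplot2::geom_point() +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         linetype = "dashed", colour = "red") +
    ggplot2::labs(
      x = "SD of raters' surface-area estimates (%)",
      y = "consensus surface area error (%)", title = crowd_name
    )
}

need_ggplot2 <- function() {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop_cm("plotting requires the ggplot2 package")
  }
}
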