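#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a ROC curve
#'
#' @param object A `pelvi_roc`.
#' @param ... Unused.
#' @return A ggplot: the ROC curve, the chance diagonal and the optimal
#'   operating point.
#' @method autoplot pelvi_roc
#' @export
autoplot.pelvi_roc <- function(object, ...) {
  p <- object$points
  opt <- p[which.min(p$fpr^2 + (1 - p$tpr)^2), ]
  ggplot2::ggplot(p, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, colour = "grey70") +
    ggplot2::geom_path() +
    ggplot2::geom_point(data = opt, shape = 4, size = 3) +
    ggplot2::coord_equal() +
    ggplot2::labs(
      x = "False positive rate", y = "True positive rate",
      title = sprintf("%s: AUC %.2f, cut-off %.3g",
                      object$feature_name %||% "feature",
                      object$auc, object$cutoff_opt)
    )
}

#' Plot a cohort summary as per-location mean +/- sd
#'
#' @param object A `cohort_summary`.
#' @param ... Unused.
#' @return A ggplot faceted by metric, comparing all versus selected
#'   sessions per probe location, with the acceptability thresholds.
#' @method autoplot cohort_summary
#' @export
autoplot.cohort_summary <- function(object, ...) {
  thr <- tibble::tibble(metric = c("accuracy", "precision", "bias", "bias"),
                        y = c(1, 1, 0.5, -0.5))
  ggplot2::ggplot(object$by_location,
                  ggplot2::aes(x = .data$location, y = .data$mean,
                               colour = .data$dataset)) +
    ggplot2::geom_pointrange(
      ggplot2::aes(ymin = .data$mean - .data$sd,
                   ymax = .data$mean + .data$sd),
      position = ggplot2::position_dodge(width = 0.4)) +
    ggplot2::geom_hline(data = thr, ggplot2::aes(yintercept = .data$y),
                        linetype = "dashed", colour = "red") +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = NULL, y = "degC", colour = NULL)
}

#' Plot one slice of a temperature map
#'
#' @param series A `thermo_series`.
#' @param scan Scan index within the series.
#' @param slice Slice index.
#' @param limits Colour scale limits in degC.
#' @return A ggplot raster of the temperature-change slice; invalid
#'   voxels are blanked.
#' @export
plot_temperature_slice <- function(series, scan = 1, slice = 1,
                                   limits = c(-8, 8)) {
  m <- series$maps[[scan]][, , slice]
  m[!series$valid[[scan]][, , slice]] <- NA
  df <- tidyr::expand_grid(x = seq_len(nrow(m)), y = seq_len(ncol(m)))
  df$dT <- as.vector(m)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                   fill = .data$dT)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient2(low = "blue", mid = "white",
                                  high = "red", limits = limits,
                                  oob = scales_squish) +
    ggplot2::coord_equal() +
    ggplot2::labs(fill = "dT (degC)",
                  title = sprintf("scan %d, slice %d (stage %s)",
                                  scan, slice, series$stage))
}

# Clamp out-of-bounds values into the limits (avoids a scales dependency
# in Imports for one helper).
scales_squish <- function(x, range = c(0, 1)) {
  pmin(pmax(x, range[1]), range[2])
}
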