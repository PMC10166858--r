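#' Plot a corrected arc curve
#'
#' @param cac An `lss_cac` (or numeric vector).
#' @param changepoints Optional detected change-points (vertical lines).
#' @param truth Optional ground-truth change-points (dashed lines).
#' @return A ggplot.
#' @export
plot_cac <- function(cac, changepoints = NULL, truth = NULL) {
  df <- tibble(position = seq_along(cac), cac = as.numeric(cac))
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$position, y = .data$cac)) +
    ggplot2::geom_line(color = "steelblue") +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "subsequence position", y = "corrected arc curve")
  if (!is.null(truth) && length(truth) > 0) {
    p <- p + ggplot2::geom_vline(xintercept = truth, linetype = "dashed",
                                 color = "grey40")
  }
  if (!is.null(changepoints) && length(changepoints) > 0) {
    p <- p + ggplot2::geom_vline(xintercept = changepoints, color = "firebrick")
  }
  p
}

#' @describeIn segment_ts Corrected arc curve with the detected
#'   change-points; pass `truth =` to overlay ground truth.
#' @param object Result object.
#' @param truth Optional ground-truth change-points.
#' @export
autoplot.lss_segmentation <- function(object, truth = NULL, ...) {
  if (is.null(object$cac)) {
    abort("this run produced no corrected arc curve (lfmd baseline); nothing to plot")
  }
  plot_cac(object$cac, changepoints = object$changepoints, truth = truth)
}

#' @describeIn generate_regime_series Channel traces with the true
#'   change-points overlaid.
#' @param object Simulated dataset.
#' @param channels Which channels to show (default first 4).
#' @export
autoplot.lss_sim <- function(object, channels = 1:min(4, ncol(object$ts)), ...) {
  long <- tidy(object)
  keep <- colnames(object$ts)[channels]
  long <- dplyr::filter(long, .data$channel %in% keep)
  p <- ggplot2::ggplot(long, ggplot2::aes(x = .data$time, y = .data$value)) +
    ggplot2::geom_line(linewidth = 0.2) +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$channel)) +
    ggplot2::labs(x = "time step", y = NULL)
  if (length(object$changepoints) > 0) {
    p <- p + ggplot2::geom_vline(xintercept = object$changepoints,
                                 color = "firebrick", linetype = "dashed")
  }
  p
}
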