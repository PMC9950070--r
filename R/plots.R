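# ggplot2 views of the result types: reliability diagrams, confusion
# matrices, per-class diameter histograms and the effect-size matrix.

#' Reliability diagram
#'
#' Bars show per-bin accuracy over mean confidence with the calibration
#' curve; the diagonal is perfect calibration. The subtitle reports ECE and
#' MCE.
#'
#' @param bins Tibble from [reliability_bins()].
#' @return A ggplot.
#' @export
plot_reliability <- function(bins) {
  b <- bins[!bins$empty, ]
  ggplot2::ggplot(b, ggplot2::aes(x = (.data$lo + .data$hi) / 2, y = .data$accuracy)) +
    ggplot2::geom_col(width = (b$hi - b$lo) * 0.92, fill = "steelblue",
                      colour = "grey30") +
    ggplot2::geom_text(ggplot2::aes(label = .data$count), vjust = -0.4, size = 3) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2) +
    ggplot2::geom_line(ggplot2::aes(x = .data$mean_confidence), colour = "firebrick") +
    ggplot2::geom_point(ggplot2::aes(x = .data$mean_confidence), colour = "firebrick") +
    ggplot2::coord_cartesian(xlim = c(0, 1), ylim = c(0, 1.05)) +
    ggplot2::labs(x = "confidence", y = "accuracy",
                  subtitle = sprintf("ECE %.2f%%  MCE %.2f%%", ece(bins), mce(bins))) +
    ggplot2::theme_minimal()
}

#' @describeIn confusion_matrix Heat-map of the confusion matrix with
#'   per-class recall/precision in the margins.
#' @param object An `rbc_confusion`.
#' @param ... Unused.
#' @method autoplot rbc_confusion
#' @export
autoplot.rbc_confusion <- function(object, ...) {
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$predicted, y = .data$truth,
                                  fill = .data$count)) +
    ggplot2::geom_tile(colour = "white") +
    ggplot2::geom_text(ggplot2::aes(label = .data$count), size = 3) +
    ggplot2::scale_y_discrete(limits = rev(rbc_classes())) +
    ggplot2::scale_fill_gradient(low = "white", high = "steelblue") +
    ggplot2::labs(title = sprintf("overall accuracy %.1f%%", 100 * object$accuracy)) +
    ggplot2::theme_minimal()
}

#' Per-class diameter histograms
#'
#' @param data Tibble with `class` and `diameter` columns.
#' @param lo,hi,width Binning as in [diameter_histogram()].
#' @return A faceted ggplot of normalised frequencies.
#' @export
plot_diameter_histograms <- function(data, lo = 4, hi = 10, width = 0.1) {
  d <- data |>
    dplyr::group_by(class = as_rbc_factor(.data$class)) |>
    dplyr::group_modify(~ diameter_histogram(.x$diameter, lo, hi, width)) |>
    dplyr::ungroup()
  ggplot2::ggplot(d, ggplot2::aes(x = .data$center, y = .data$frequency)) +
    ggplot2::geom_col(width = width, fill = "indianred") +
    ggplot2::facet_wrap(~class, ncol = 1, strip.position = "right") +
    ggplot2::labs(x = "effective diameter (µm)", y = "frequency") +
    ggplot2::theme_minimal()
}

#' Common-language effect-size matrix heat map
#'
#' @param M Matrix from [cl_matrix()].
#' @return A ggplot.
#' @export
plot_cl_matrix <- function(M) {
  d <- tibble::as_tibble(as.data.frame.table(M, responseName = "p")) |>
    dplyr::rename(row = "Var1", col = "Var2")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$col, y = .data$row, fill = .data$p)) +
    ggplot2::geom_tile(colour = "white") +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.2f", .data$p)), size = 3) +
    ggplot2::scale_y_discrete(limits = rev(rbc_classes())) +
    ggplot2::scale_fill_gradient2(low = "steelblue", mid = "white",
                                  high = "indianred", midpoint = 0.5,
                                  limits = c(0, 1)) +
    ggplot2::labs(x = "group B", y = "group A",
                  fill = "P(A > B)") +
    ggplot2::theme_minimal()
}

#' Track trajectories over the frame
#'
#' @param tracks Tidy track tibble from [tidy.rbc_tracks()].
#' @return A ggplot of per-track paths (y axis flipped to image convention).
#' @export
plot_tracks <- function(tracks) {
  ggplot2::ggplot(dplyr::filter(tracks, .data$visible),
                  ggplot2::aes(x = .data$x, y = .data$y,
                               group = .data$track_id,
                               colour = factor(.data$track_id))) +
    ggplot2::geom_path() +
    ggplot2::scale_y_reverse() +
    ggplot2::labs(colour = "track") +
    ggplot2::theme_minimal()
}
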