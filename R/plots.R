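#' Plot an undercounting bias curve
#'
#' Detection ratio (mean detected clusters / mean true molecules) versus the
#' Poisson mean copy number, with the tolerated-bias level drawn as a
#' reference line.
#'
#' @param object An `undercount_result` from [simulate_undercount()].
#' @param max_relative_bias Reference bias level to draw.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.undercount_result <- function(object, max_relative_bias = 0.05, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$lambda,
                                       y = .data$detection_ratio)) +
    ggplot2::geom_hline(yintercept = 1 - max_relative_bias,
                        linetype = "dashed", colour = "grey50") +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "mean molecules per cell (Poisson λ)",
                  y = "detection ratio (detected / true)",
                  title = "Diffraction-limited undercounting") +
    ggplot2::theme_minimal()
}

#' Plot a photobleaching trace and its fitted steps
#'
#' @param object A `bleach_fit` from [count_steps()] or a `bleach_trace`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.bleach_fit <- function(object, ...) {
  n <- length(object$values)
  df <- tibble(frame = seq_len(n), intensity = object$values)
  b <- c(1L, object$step_frames, n + 1L)
  fit <- tibble(
    frame = unlist(lapply(seq_len(length(b) - 1L),
                          function(s) b[s]:(b[s + 1L] - 1L))),
    level = rep(object$levels, diff(b)))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$frame, y = .data$intensity)) +
    ggplot2::geom_line(colour = "grey60") +
    ggplot2::geom_step(data = fit,
                       ggplot2::aes(y = .data$level), colour = "red") +
    ggplot2::labs(x = "frame", y = "background-subtracted intensity",
                  title = sprintf("%d photobleaching step(s)", object$n_steps)) +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.bleach_fit
#' @export
autoplot.bleach_trace <- function(object, ...) {
  df <- tibble(frame = seq_along(object$values), intensity = object$values)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$frame,
                                        y = .data$intensity)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "frame", y = "background-subtracted intensity") +
    ggplot2::theme_minimal()
  if (length(object$true_step_frames))
    p <- p + ggplot2::geom_vline(xintercept = object$true_step_frames,
                                 linetype = "dotted", colour = "red")
  p
}

#' Plot aggregated per-cell count distributions
#'
#' Bar chart of the mean proportion of cells per molecule count across
#' replicates, with spread error bars — the standard presentation of
#' replicate count histograms.
#'
#' @param object A `count_aggregate` from [aggregate_replicates()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.count_aggregate <- function(object, ...) {
  ggplot2::ggplot(object$proportions,
                  ggplot2::aes(x = .data$count, y = .data$mean_proportion)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_errorbar(ggplot2::aes(
      ymin = pmax(.data$mean_proportion - .data$spread, 0),
      ymax = .data$mean_proportion + .data$spread), width = 0.3) +
    ggplot2::labs(x = "molecules per cell", y = "proportion of cells",
                  title = sprintf("mean %.2f ± %.2f molecules/cell (%s)",
                                  object$mean_count,
                                  object$mean_count_spread,
                                  object$spread_type)) +
    ggplot2::theme_minimal()
}

#' Display a field with segmented cells and detected spots
#'
#' @param image Background image (e.g. the maximum projection), matrix.
#' @param regions Optional cell-region tibble; centroids and ids are drawn.
#' @param spots Optional spot tibble (columns row, col).
#' @return A ggplot object.
#' @export
plot_field <- function(image, regions = NULL, spots = NULL) {
  df <- expand.grid(row = seq_len(nrow(image)), col = seq_len(ncol(image)))
  df$intensity <- image[as.matrix(df[, c("row", "col")])]
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$intensity)) +
    ggplot2::scale_fill_gradient(low = "black", high = "white") +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::theme_void()
  if (!is.null(regions) && nrow(regions))
    p <- p + ggplot2::geom_text(
      data = regions,
      ggplot2::aes(x = .data$centroid_col, y = .data$centroid_row,
                   label = .data$cell_id),
      colour = "yellow", size = 3)
  if (!is.null(spots) && nrow(spots))
    p <- p + ggplot2::geom_point(
      data = spots, ggplot2::aes(x = .data$col, y = .data$row),
      colour = "red", shape = 1, size = 3)
  p
}
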