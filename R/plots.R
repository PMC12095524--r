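#' Plot single-cell activity traces
#'
#' @param traces Long trace table.
#' @param cells Optional cell table supplying `condition` for faceting.
#' @param n Maximum number of cells to draw (sampled deterministically).
#' @return A ggplot object.
#' @export
plot_traces <- function(traces, cells = NULL, n = 30) {
  ids <- unique(traces$cell_id)
  if (length(ids) > n) ids <- ids[seq(1, length(ids), length.out = n)]
  d <- traces[traces$cell_id %in% ids, ]
  if (!is.null(cells)) {
    d <- dplyr::left_join(d, cells[, c("cell_id", "condition")],
                          by = "cell_id")
  }
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$t_min / 60,
                                       y = .data$activity,
                                       group = .data$cell_id)) +
    ggplot2::geom_line(alpha = 0.5, linewidth = 0.3) +
    ggplot2::labs(x = "time (h)", y = "ERK activity") +
    ggplot2::theme_minimal()
  if (!is.null(cells)) p <- p + ggplot2::facet_wrap(~condition)
  p
}

#' Plot history prototype centroids
#'
#' @param x An `erk_prototypes` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.erk_prototypes <- function(x, ...) {
  d <- purrr::map_dfr(seq_len(x$k), function(k) {
    tibble::tibble(class = factor(k), t_min = x$t_min,
                   activity = x$centroids[k, ])
  })
  ggplot2::ggplot(d, ggplot2::aes(x = .data$t_min / 60, y = .data$activity,
                                  color = .data$class)) +
    ggplot2::geom_line(linewidth = 0.8) +
    ggplot2::labs(x = "time (h)", y = "mean ERK activity",
                  color = "prototype") +
    ggplot2::theme_minimal()
}

#' Plot a per-timepoint correlation profile
#'
#' @param tc Output of [timepoint_correlation()] or
#'   [survey_timepoint_profile()].
#' @return A ggplot object.
#' @export
plot_timepoint_correlation <- function(tc) {
  key <- if ("target" %in% names(tc)) "target" else "gene_id"
  ggplot2::ggplot(tc, ggplot2::aes(x = .data$t_min / 60, y = .data$r,
                                   color = .data[[key]])) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (h)", y = "Pearson r") +
    ggplot2::theme_minimal()
}

#' Plot an integrated-gradients attribution map
#'
#' @param x An `erk_attribution` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.erk_attribution <- function(x, ...) {
  ggplot2::ggplot(x$map, ggplot2::aes(x = .data$t_min / 60,
                                      y = .data$importance)) +
    ggplot2::geom_col(width = 0.08) +
    ggplot2::labs(x = "time (h)", y = "mean attribution") +
    ggplot2::theme_minimal()
}

#' Spatial overlay of inferred signaling histories
#'
#' @param overlay Output of [annotate_histories()].
#' @return A ggplot object.
#' @export
plot_overlay <- function(overlay) {
  ggplot2::ggplot(overlay, ggplot2::aes(x = .data$x_um, y = .data$y_um,
                                        color = .data$pred_class)) +
    ggplot2::geom_point(size = 1.2) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (µm)", y = "y (µm)",
                  color = "inferred class") +
    ggplot2::theme_minimal()
}
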