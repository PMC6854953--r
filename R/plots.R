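stack_to_df <- function(stack, channels = NULL) {
  channels <- channels %||% names(stack$channels)
  purrr::map_dfr(channels, function(ch) {
    m <- get_channel(stack, ch)
    tibble::tibble(
      row = rep(seq_len(nrow(m)) - 1L, times = ncol(m)),
      col = rep(seq_len(ncol(m)) - 1L, each = nrow(m)),
      intensity = as.vector(m),
      channel = ch)
  })
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Display the channels of a synthetic scene
#'
#' @param object A `pnn_scene`.
#' @param channels Channels to show (default: all).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.pnn_scene <- function(object, channels = NULL, ...) {
  df <- stack_to_df(object$stack, channels)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row,
                                   fill = .data$intensity)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_gradient(low = "black", high = "white") +
    ggplot2::coord_fixed() +
    ggplot2::facet_wrap(~channel) +
    ggplot2::labs(x = NULL, y = NULL, fill = "I") +
    ggplot2::theme_minimal()
}

circle_df <- function(row, col, radius, id) {
  th <- seq(0, 2 * pi, length.out = 90)
  purrr::map_dfr(seq_along(row), function(i) {
    tibble::tibble(id = id[i], row = row[i] + radius[i] * sin(th),
                   col = col[i] + radius[i] * cos(th))
  })
}

#' Overlay detected PNN rings (and nuclei) on one channel
#'
#' @param stack An [image_stack()].
#' @param pnns Validated PNN objects.
#' @param nuclei Optional nuclei table, drawn as points.
#' @param channel Channel to display.
#' @return A ggplot.
#' @export
plot_detections <- function(stack, pnns, nuclei = NULL, channel = "wfa") {
  df <- stack_to_df(stack, channel)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$intensity)) +
    ggplot2::scale_fill_gradient(low = "black", high = "white") +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::theme_minimal() +
    ggplot2::labs(x = NULL, y = NULL, fill = "I")
  if (nrow(pnns)) {
    circ <- circle_df(pnns$row, pnns$col, pnns$radius, pnns$pnn_id)
    p <- p + ggplot2::geom_path(data = circ,
                                ggplot2::aes(group = .data$id),
                                colour = "red", linewidth = 0.3)
  }
  if (!is.null(nuclei) && nrow(nuclei)) {
    p <- p + ggplot2::geom_point(data = nuclei, colour = "cyan", size = 0.6)
  }
  p
}

#' Phenotype census bar chart
#'
#' @param object A `pnn_census`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.pnn_census <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$phenotype, y = .data$percent)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::ylim(0, 100) +
    ggplot2::labs(y = "% of PNN-positive cells", x = NULL,
                  subtitle = sprintf("n = %d PNN cells", df$n_pnn_cells[1L])) +
    ggplot2::theme_minimal()
}

#' Per-PNN intensity scatter behind a colocalization coefficient
#'
#' @param records Measurement tibble.
#' @param channel_a,channel_b Channels on the axes.
#' @return A ggplot with the Spearman coefficient in the subtitle.
#' @export
plot_coloc <- function(records, channel_a = "wfa",
                       channel_b = "comparison") {
  res <- colocalize(records, channel_a, channel_b)
  ggplot2::ggplot(records,
                  ggplot2::aes(x = .data[[paste0("mean_", channel_a)]],
                               y = .data[[paste0("mean_", channel_b)]])) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::labs(
      x = sprintf("mean %s intensity", channel_a),
      y = sprintf("mean %s intensity", channel_b),
      subtitle = sprintf("Spearman rho = %.3f (n = %d)", res$rho, res$n)) +
    ggplot2::theme_minimal()
}

#' @importFrom rlang .data
NULL
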