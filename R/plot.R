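# Optional scalp-map visualization (requires ggplot2).

#' Plot an ERD/ERS scalp map
#'
#' Simple topographic scatter of per-electrode relative power change on the
#' projected head layout: desynchronization in blue, synchronization in
#' red, removed electrodes hollow.
#'
#' @param map An `erd_map` from [erd_scalp_map()].
#' @param layout An `electrode_layout`.
#' @return A ggplot object.
#' @export
plot_scalp_map <- function(map, layout = standard_layout()) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("ggplot2 is required for plotting", call. = FALSE)
  }
  df <- as.data.frame(map)
  pos <- layout$positions[df$electrode, , drop = FALSE]
  df$x <- pos[, "x"]; df$y <- pos[, "y"]
  circ <- data.frame(x = 1.1 * cos(seq(0, 2 * pi, length.out = 200)),
                     y = 1.1 * sin(seq(0, 2 * pi, length.out = 200)))
  ggplot2::ggplot(df, ggplot2::aes(x = x, y = y)) +
    ggplot2::geom_path(data = circ, inherit.aes = FALSE,
                       ggplot2::aes(x = x, y = y),
                       colour = "grey40") +
    ggplot2::geom_point(ggplot2::aes(fill = percent,
                                     shape = removed), size = 6) +
    ggplot2::geom_text(ggplot2::aes(label = electrode), size = 2,
                       vjust = -1.6) +
    ggplot2::scale_shape_manual(values = c(`FALSE` = 21, `TRUE` = 1),
                                guide = "none") +
    ggplot2::scale_fill_gradient2(low = "blue", mid = "white", high = "red",
                                  midpoint = 0, name = "%Power") +
    ggplot2::coord_equal() +
    ggplot2::theme_void() +
    ggplot2::ggtitle(sprintf("%s, %s band", df$condition[1], df$band[1]))
}
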