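#' Plot the pairwise gene structure of a marker design
#'
#' Draws the two species' exon blocks along alignment columns, mismatch and
#' gap columns, exon-intron junctions, and the footprint of the top-ranked
#' primer pairs.
#'
#' @param object A `marker_design` object.
#' @param top How many top-ranked pairs to draw.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.marker_design <- function(object, top = 5L, ...) {
  ps <- object$structure
  L <- length(ps$col_state)
  cols <- tibble(column = seq_len(L) - 1L, state = ps$col_state)
  marks <- cols[cols$state != "match", , drop = FALSE]
  blocks <- object$blocks
  juncs <- bind_rows(
    tibble(column = ps$junctions_a, species = "A"),
    tibble(column = ps$junctions_b, species = "B"))
  p <- ggplot2::ggplot() +
    ggplot2::geom_rect(
      data = blocks,
      ggplot2::aes(xmin = .data$col_start, xmax = .data$col_end,
                   ymin = 0.45, ymax = 0.55),
      fill = "grey70") +
    ggplot2::geom_segment(
      data = marks,
      ggplot2::aes(x = .data$column, xend = .data$column, y = 0.42, yend = 0.58,
                   colour = .data$state)) +
    ggplot2::labs(x = "alignment column", y = NULL,
                  title = sprintf("%s vs %s", object$gene_a, object$gene_b),
                  colour = "column") +
    ggplot2::scale_y_continuous(limits = c(0, 1), breaks = NULL)
  if (nrow(juncs) > 0L)
    p <- p + ggplot2::geom_vline(
      data = juncs, ggplot2::aes(xintercept = .data$column),
      linetype = "dashed", colour = "grey40")
  pairs <- object$pairs
  if (nrow(pairs) > 0L) {
    sel <- pairs[pairs$rank <= top, , drop = FALSE]
    seg <- bind_rows(
      tibble(x = sel$fw_col_start, xend = sel$fw_col_end,
             y = 0.65 + 0.05 * (sel$rank - 1L), role = "forward"),
      tibble(x = sel$rv_col_start, xend = sel$rv_col_end,
             y = 0.65 + 0.05 * (sel$rank - 1L), role = "reverse"))
    p <- p + ggplot2::geom_segment(
      data = seg,
      ggplot2::aes(x = .data$x, xend = .data$xend, y = .data$y,
                   yend = .data$y, linetype = .data$role),
      linewidth = 1.2, colour = "black") +
      ggplot2::labs(linetype = "primer")
  }
  p
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
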