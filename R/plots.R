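#' Oxford-grid dotplot of a species pair
#'
#' One panel per scaffold pair (facet grid), one point per homologous gene
#' pair at its rank coordinates — the classic visualization of
#' macrosynteny. With `cells` supplied, panels can be restricted to
#' syntenic cells.
#'
#' @param dots Dot table from [synteny_dots()].
#' @param cells Optional classified cell table; when given, only cells not
#'   labelled `not_syntenic` are shown.
#' @return A ggplot object.
#' @export
plot_oxford_grid <- function(dots, cells = NULL) {
  if (!is.null(cells) && "label" %in% names(cells)) {
    keep <- filter(cells, .data$label != "not_syntenic")
    dots <- semi_join(dots, keep, by = c("scaffold_a", "scaffold_b"))
  }
  ggplot2::ggplot(dots, ggplot2::aes(x = .data$rank_a, y = .data$rank_b)) +
    ggplot2::geom_point(size = 0.4, colour = "darkgreen") +
    ggplot2::facet_grid(scaffold_b ~ scaffold_a, scales = "free", space = "free") +
    ggplot2::labs(x = "gene rank, species A", y = "gene rank, species B") +
    ggplot2::theme_bw() +
    ggplot2::theme(panel.grid = ggplot2::element_blank())
}

#' Self-similarity dotplot of one scaffold
#'
#' Forward-orientation hits in green, reverse in purple, mirroring the
#' conventional rendering of segmental-duplication dotplots.
#'
#' @param points Point table from [self_dotplot()].
#' @return A ggplot object.
#' @export
plot_self_dotplot <- function(points) {
  ggplot2::ggplot(points, ggplot2::aes(
    x = .data$rank_q, y = .data$rank_s, colour = .data$orientation
  )) +
    ggplot2::geom_point(size = 0.6) +
    ggplot2::scale_colour_manual(
      values = c(forward = "darkgreen", reverse = "purple")
    ) +
    ggplot2::labs(x = "gene rank (query)", y = "gene rank (subject)") +
    ggplot2::theme_bw()
}

#' @rdname plot_gain_loss
#' @method autoplot gain_loss
#' @export
autoplot.gain_loss <- function(object, ...) plot_gain_loss(object, ...)

#' Gains and losses per tree node
#'
#' Horizontal bars of orthogroup origins (gains) and Dollo losses per
#' node, tips on top, mirroring the histogram-plus-circled-numbers style
#' used for gain/loss maps on phylogenies.
#'
#' @param object A `gain_loss` from [summarize_gain_loss()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
plot_gain_loss <- function(object, ...) {
  long <- object$nodes |>
    select("label", "is_tip", gains = "n_origins", losses = "n_losses") |>
    tidyr::pivot_longer(c("gains", "losses"), names_to = "event", values_to = "n")
  ggplot2::ggplot(long, ggplot2::aes(
    x = .data$n, y = .data$label, fill = .data$event
  )) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::scale_fill_manual(values = c(gains = "steelblue", losses = "firebrick")) +
    ggplot2::labs(x = "orthogroups", y = NULL) +
    ggplot2::theme_bw()
}
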