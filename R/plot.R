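#' Heatmaps of metric and risk maps
#'
#' Draws the angular maps as gantry-by-couch heatmaps, one tile per
#' orientation; for risk maps, constrained (inadmissible) cells are drawn in
#' grey. Selections can be overlaid with [autoplot.beam_selection()].
#'
#' @param object a `metric_map` tibble.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.metric_map <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$gantry_deg, y = .data$couch_deg,
                               fill = .data$value)) +
    ggplot2::geom_tile() +
    ggplot2::facet_wrap(~ voi) +
    ggplot2::scale_fill_viridis_c(option = "inferno") +
    ggplot2::labs(x = "gantry angle (deg)", y = "couch angle (deg)",
                  fill = "value") +
    ggplot2::theme_minimal()
}

#' @param object a `risk_map` tibble.
#' @rdname autoplot.metric_map
#' @export
autoplot.risk_map <- function(object, ...) {
  p <- ggplot2::ggplot(object,
                       ggplot2::aes(x = .data$gantry_deg,
                                    y = .data$couch_deg)) +
    ggplot2::geom_tile(data = object[object$admissible, ],
                       ggplot2::aes(fill = .data$score)) +
    ggplot2::scale_fill_viridis_c(option = "inferno") +
    ggplot2::labs(x = "gantry angle (deg)", y = "couch angle (deg)",
                  fill = "risk score") +
    ggplot2::theme_minimal()
  if (any(!object$admissible))
    p <- p + ggplot2::geom_tile(data = object[!object$admissible, ],
                                fill = "grey60")
  p
}

#' @param object a `beam_selection` tibble.
#' @rdname autoplot.metric_map
#' @export
autoplot.beam_selection <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$gantry_deg, y = .data$couch_deg,
                               label = .data$rank)) +
    ggplot2::geom_point(shape = 4, size = 3, stroke = 1.5) +
    ggplot2::geom_text(nudge_y = 4) +
    ggplot2::labs(x = "gantry angle (deg)", y = "couch angle (deg)") +
    ggplot2::theme_minimal()
}

#' Plot a risk map with its selected beams
#'
#' @param risk a `risk_map`.
#' @param selection a `beam_selection` on the same grid.
#' @return a ggplot object.
#' @export
plot_selection <- function(risk, selection) {
  autoplot.risk_map(risk) +
    ggplot2::geom_point(data = selection, shape = 4, size = 3, stroke = 1.5,
                        colour = "white") +
    ggplot2::geom_text(data = selection,
                       ggplot2::aes(label = .data$rank),
                       nudge_y = 5, colour = "white")
}
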