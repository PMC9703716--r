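# ggplot2 displays for the result objects.

#' Plot metric-versus-density curves
#'
#' @param curves Long tibble from [global_metric_curves()] (or the
#'   `$curves` element of an `scn_comparison`).
#' @return A ggplot: one panel per metric, one line per group.
#' @export
plot_metric_curves <- function(curves) {
  ggplot2::ggplot(curves, ggplot2::aes(.data$density, .data$value,
                                       colour = .data$group)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = "network density", y = "metric value",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' @describeIn plot_metric_curves Association-matrix heatmaps per group.
#' @param object,x Result object.
#' @param ... Unused.
#' @method autoplot scn_networks
#' @export
autoplot.scn_networks <- function(object, ...) {
  tidy(object) |>
    ggplot2::ggplot(ggplot2::aes(.data$region_a, .data$region_b,
                                 fill = .data$r)) +
    ggplot2::geom_tile() +
    ggplot2::facet_wrap(~group) +
    ggplot2::scale_fill_gradient2(limits = c(-1, 1)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "r") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text = ggplot2::element_blank())
}

#' @describeIn plot_metric_curves Observed group differences against the
#'   95% permutation interval, one panel per metric; significant densities
#'   are starred.
#' @method autoplot scn_comparison
#' @export
autoplot.scn_comparison <- function(object, ...) {
  ggplot2::ggplot(object$global, ggplot2::aes(.data$density, .data$diff)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$ci_low,
                                      ymax = .data$ci_high),
                         fill = "grey80") +
    ggplot2::geom_line() +
    ggplot2::geom_point(data = ~dplyr::filter(.x, .data$significant),
                        shape = 8, colour = "red", size = 2) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2) +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(
      x = "network density",
      y = sprintf("difference (%s - %s)", object$groups[1],
                  object$groups[2])
    ) +
    ggplot2::theme_minimal()
}

#' @describeIn plot_metric_curves Nodal betweenness against the hub
#'   threshold, one panel per group.
#' @method autoplot scn_hubs
#' @export
autoplot.scn_hubs <- function(object, ...) {
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(.data$region, .data$betweenness,
                               fill = .data$is_hub)) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(ggplot2::aes(yintercept = .data$threshold),
                        linetype = 2) +
    ggplot2::facet_wrap(~group, ncol = 1) +
    ggplot2::scale_fill_manual(values = c(`FALSE` = "grey70",
                                          `TRUE` = "firebrick")) +
    ggplot2::labs(x = NULL, y = "betweenness (density AUC)",
                  fill = "hub") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank())
}
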