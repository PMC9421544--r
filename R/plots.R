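#' Hub-role quadrant plot
#'
#' Scatter of WMZ against PC_norm with the classification boundaries
#' (WMZ = 1, PC_norm = 0.5), colored by role -- the standard view of connector
#' versus provincial hub structure.
#'
#' @param hub_tbl A [hub_table()] tibble.
#' @return A ggplot object.
#' @export
plot_hub_roles <- function(hub_tbl) {
  ggplot2::ggplot(hub_tbl,
                  ggplot2::aes(x = .data$pc_norm, y = .data$wmz,
                               color = .data$role)) +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed", color = "grey40") +
    ggplot2::geom_vline(xintercept = 0.5, linetype = "dashed", color = "grey40") +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::labs(x = "Normalized participation coefficient",
                  y = "Within-module degree z-score", color = "Role") +
    ggplot2::theme_minimal()
}

#' Metric-versus-density curves
#'
#' Line plot of nodal or global metric curves across the density sweep,
#' optionally grouped/colored (e.g. by group or node).
#'
#' @param curves Tibble with `density`, `value` and optionally a grouping
#'   column.
#' @param color Optional name of the column mapped to color.
#' @return A ggplot object.
#' @export
plot_metric_curves <- function(curves, color = NULL) {
  mapping <- if (is.null(color)) {
    ggplot2::aes(x = .data$density, y = .data$value)
  } else {
    ggplot2::aes(x = .data$density, y = .data$value,
                 color = .data[[color]], group = .data[[color]])
  }
  ggplot2::ggplot(curves, mapping) +
    ggplot2::stat_summary(fun = mean, geom = "line") +
    ggplot2::labs(x = "Network density", y = "Metric value") +
    ggplot2::theme_minimal()
}

#' Plot an NBS result
#'
#' Null maximal-component-size distribution with the observed component sizes
#' overlaid.
#'
#' @param object An `fcnet_nbs` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @importFrom ggplot2 autoplot
#' @export
autoplot.fcnet_nbs <- function(object, ...) {
  null_df <- tibble::tibble(max_size = object$null_max)
  p <- ggplot2::ggplot(null_df, ggplot2::aes(x = .data$max_size)) +
    ggplot2::geom_histogram(bins = 30, fill = "grey70", color = "white") +
    ggplot2::labs(x = "Null maximal component size (edges)", y = "Count") +
    ggplot2::theme_minimal()
  if (nrow(object$components)) {
    p <- p + ggplot2::geom_vline(
      data = object$components,
      ggplot2::aes(xintercept = .data$n_edges),
      color = "firebrick", linetype = "dashed"
    )
  }
  p
}
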