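# ggplot2 visualisations of the result objects.

#' Quadrant plot of topological roles
#'
#' The classic c-z plane: among-module connectivity against within-module
#' connectivity, with the null-derived critical thresholds as dashed lines
#' carving the four role quadrants.
#'
#' @param object A `role_assignment` tibble from [assign_roles()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.role_assignment <- function(object, ...) {
  df <- tibble::as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$c, y = .data$z)) +
    ggplot2::geom_vline(xintercept = df$c_critical[1], linetype = "dashed",
                        colour = "grey40") +
    ggplot2::geom_hline(yintercept = df$z_critical[1], linetype = "dashed",
                        colour = "grey40") +
    ggplot2::geom_point(ggplot2::aes(colour = .data$role), size = 2.5) +
    ggplot2::scale_colour_manual(
      values = c(peripheral = "grey55", connector = "#1b9e77",
                 module_hub = "#7570b3", network_hub = "#d95f02"),
      drop = FALSE
    ) +
    ggplot2::labs(
      x = "among-module connectivity (c)",
      y = "within-module connectivity (z)",
      colour = "role"
    ) +
    ggplot2::theme_minimal()
}

#' Rarefaction (accumulation) curve plot
#'
#' Expected richness against the number of individuals subsampled.
#'
#' @param object A `rarefaction_curve` tibble from [rarefaction_curve()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.rarefaction_curve <- function(object, ...) {
  ggplot2::ggplot(
    tibble::as_tibble(object),
    ggplot2::aes(x = .data$n, y = .data$expected_richness)
  ) +
    ggplot2::geom_line(linewidth = 0.8, colour = "#1b6ca8") +
    ggplot2::labs(x = "individuals sampled", y = "expected richness") +
    ggplot2::theme_minimal()
}

#' Module-sorted interaction heatmap
#'
#' Tile plot of the weighted matrix with rows and columns grouped by
#' module, making the block structure behind a modularity result visible.
#'
#' @param matrix An [interaction_matrix()].
#' @param result A `modularity_result` for that matrix.
#' @return A ggplot.
#' @export
plot_module_matrix <- function(matrix, result) {
  stopifnot(inherits(matrix, "interaction_matrix"),
            inherits(result, "modularity_result"))
  part <- result$partition
  row_ord <- order(part$row_module)
  col_ord <- order(part$col_module)
  edges <- tidy.interaction_matrix(matrix) |>
    dplyr::mutate(
      pollinator = factor(.data$pollinator,
                          levels = matrix$row_labels[row_ord]),
      plant = factor(.data$plant, levels = matrix$col_labels[col_ord])
    )
  ggplot2::ggplot(
    edges,
    ggplot2::aes(x = .data$plant, y = .data$pollinator,
                 fill = .data$weight)
  ) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(trans = "log1p") +
    ggplot2::labs(x = "plants (module-sorted)",
                  y = "pollinators (module-sorted)", fill = "visits") +
    ggplot2::theme_minimal() +
    ggplot2::theme(
      axis.text.x = ggplot2::element_text(angle = 90, vjust = 0.5,
                                          hjust = 1, size = 6),
      axis.text.y = ggplot2::element_text(size = 5)
    )
}
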