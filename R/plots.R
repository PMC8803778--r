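#' Plot a density surface
#'
#' @param object An `scr_density_surface`.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.scr_density_surface <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$x, .data$y, fill = .data$density)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = expression(foxes / km^2)) +
    ggplot2::coord_equal() +
    ggplot2::labs(
      title = sprintf("%s density, session %s",
                      attr(object, "kind") %||% "",
                      attr(object, "session") %||% ""),
      x = "x (km)", y = "y (km)"
    ) +
    ggplot2::theme_minimal()
}

#' Plot an AIC model-comparison table
#'
#' @param object An `scr_model_table`.
#' @param ... Unused.
#' @return A ggplot of delta-AIC per model.
#' @exportS3Method ggplot2::autoplot
autoplot.scr_model_table <- function(object, ...) {
  df <- dplyr::mutate(tibble::as_tibble(object),
                      model = factor(.data$model, levels = rev(.data$model)))
  ggplot2::ggplot(df, ggplot2::aes(.data$dAIC, .data$model)) +
    ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = 2, linetype = "dashed", colour = "grey50") +
    ggplot2::labs(x = expression(Delta * AIC), y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot link-scale coefficients of a fit
#'
#' @param object An `scr_fit`.
#' @param ... Passed to [tidy.scr_fit()].
#' @return A ggplot of estimates with Wald intervals.
#' @exportS3Method ggplot2::autoplot
autoplot.scr_fit <- function(object, ...) {
  df <- tidy(object, ...)
  ggplot2::ggplot(df, ggplot2::aes(.data$estimate, .data$term)) +
    ggplot2::geom_point() +
    ggplot2::geom_errorbarh(
      ggplot2::aes(xmin = .data$conf.low, xmax = .data$conf.high), height = 0.2
    ) +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed", colour = "grey50") +
    ggplot2::facet_grid(.data$submodel ~ ., scales = "free_y", space = "free_y") +
    ggplot2::labs(x = "estimate (link scale)", y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a synthetic landscape
#'
#' Forest cover with roads and search tracks overlaid.
#'
#' @param landscape An [make_landscape()] result.
#' @return A ggplot.
#' @export
plot_landscape <- function(landscape) {
  cells <- raster_cells(landscape$forest)
  ggplot2::ggplot(cells, ggplot2::aes(.data$x, .data$y)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$value)) +
    ggplot2::scale_fill_gradient(name = "forest", low = "grey95",
                                 high = "darkgreen", limits = c(0, 1)) +
    ggplot2::geom_path(
      data = landscape$tracks,
      ggplot2::aes(group = .data$line_id), colour = "steelblue",
      linewidth = 0.3
    ) +
    ggplot2::geom_path(
      data = landscape$roads,
      ggplot2::aes(group = .data$line_id), colour = "grey20", linewidth = 0.5
    ) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (km)", y = "y (km)") +
    ggplot2::theme_minimal()
}
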