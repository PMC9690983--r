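# ggplot2 views of grids and result objects.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a grid as a raster map
#'
#' @param object A `land_grid`.
#' @param ... Unused.
#' @return A ggplot: categorical grids get a discrete class fill, continuous
#'   grids a viridis gradient.
#' @export
autoplot.land_grid <- function(object, ...) {
  df <- as_tibble(object)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal()
  if (inherits(object, "categorical_grid")) {
    df$class <- factor(df$value, levels = object$class_table$code,
                       labels = object$class_table$name)
    p + ggplot2::geom_raster(data = df, ggplot2::aes(fill = .data$class)) +
      ggplot2::scale_fill_brewer(palette = "Set1", na.value = "grey90",
                                 name = NULL)
  } else {
    p + ggplot2::geom_raster(ggplot2::aes(fill = .data$value)) +
      ggplot2::scale_fill_viridis_c(na.value = "grey90", name = NULL)
  }
}

#' Plot the residual trace of a simulation
#'
#' @param object A `luc_simulation`.
#' @param ... Unused.
#' @return A ggplot of per-class residual cells against iteration.
#' @export
autoplot.luc_simulation <- function(object, ...) {
  ggplot2::ggplot(object$residuals,
                  ggplot2::aes(x = .data$iteration, y = .data$residual_cells,
                               colour = .data$class)) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = 0, linetype = 2) +
    ggplot2::labs(x = "iteration", y = "cells above (+) / below (-) demand",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot driver importance per class
#'
#' @param object A `development_probability`.
#' @param ... Unused.
#' @return A ggplot bar chart of normalised driver importance, one facet per
#'   class.
#' @export
autoplot.development_probability <- function(object, ...) {
  ggplot2::ggplot(object$importance,
                  ggplot2::aes(x = .data$driver, y = .data$importance)) +
    ggplot2::geom_col() +
    ggplot2::facet_wrap(~class) +
    ggplot2::labs(x = NULL, y = "normalised importance") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Plot the zonal risk map
#'
#' @param object A `risk_assessment`.
#' @param ... Unused.
#' @return A ggplot of the five-level risk classification at zone resolution.
#' @export
autoplot.risk_assessment <- function(object, ...) {
  autoplot.land_grid(object$map) +
    ggplot2::scale_fill_brewer(palette = "YlOrRd", na.value = "grey90",
                               name = "risk")
}
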