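# Tabular reporting figures: unit x band t-value grids with significance
# overlay, and heat maps of association matrices.

#' Unit-by-band t-value grid for a statistical suite
#'
#' Mirrors the tabular t-map style of reporting: one tile per (unit, band),
#' faceted by metric, fill mapped to the t statistic and cells surviving
#' the corrected threshold outlined in white.
#'
#' @param stat_tbl A StatResult tibble from one of the suites.
#' @param alpha Corrected significance level for the overlay (default 0.01).
#' @return A ggplot object.
#' @export
plot_stat_grid <- function(stat_tbl, alpha = 0.01) {
  if (nrow(stat_tbl) == 0) stop("empty results")
  band_order <- c("delta", "theta", "alpha", "beta", "gamma")
  df <- stat_tbl |>
    dplyr::mutate(
      band = factor(.data$band, levels = intersect(band_order, unique(.data$band))),
      significant = .data$p_corrected < alpha
    )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$band, y = .data$unit, fill = .data$t)) +
    ggplot2::geom_tile(color = "grey30") +
    ggplot2::geom_tile(
      data = dplyr::filter(df, .data$significant),
      color = "white", linewidth = 1.2, fill = NA
    ) +
    ggplot2::scale_fill_gradient2(low = "#2166ac", mid = "white", high = "#b2182b",
                                  midpoint = 0, name = "t") +
    ggplot2::facet_wrap(~metric) +
    ggplot2::labs(x = "frequency band", y = NULL,
                  subtitle = sprintf("white outline: p < %g (corrected)", alpha)) +
    ggplot2::theme_minimal()
}

#' @rdname plot_stat_grid
#' @param object A StatResult tibble (for `autoplot`).
#' @param ... Passed on.
#' @export
autoplot.taugraph_stats <- function(object, ...) plot_stat_grid(object, ...)

#' Heat map of an association matrix
#'
#' @param object An [aec()] association matrix.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.association_matrix <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$parcel_i, y = .data$parcel_j,
                                   fill = .data$r)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "#2166ac", mid = "white",
                                  high = "#b2182b", midpoint = 0) +
    ggplot2::labs(x = NULL, y = NULL,
                  title = if (!is.null(object$band)) object$band$name else NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text = ggplot2::element_blank())
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
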