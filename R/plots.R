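#' Scree plot with the selected shoulder
#'
#' @param object An [pca_decompose()] result.
#' @param ... Ignored.
#' @return A ggplot.
#' @export
autoplot.r2star_pca <- function(object, ...) {
  d <- tidy(object)
  sh <- find_shoulder(object$eigenvalues)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$component, y = .data$variance_fraction)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.6) +
    ggplot2::geom_vline(xintercept = as.integer(sh), linetype = "dashed") +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "Eigenvector rank", y = "Variance fraction",
                  title = "Eigenvalue curve",
                  subtitle = sprintf("shoulder at rank %d", as.integer(sh))) +
    ggplot2::theme_minimal()
}

#' Slice montage of a summary map
#'
#' @param object A [summary_map()].
#' @param ... Ignored.
#' @return A ggplot faceted by slice.
#' @export
autoplot.summary_map <- function(object, ...) {
  d <- dim(object$values)
  df <- tidyr::expand_grid(z = seq_len(d[3]), y = seq_len(d[2]), x = seq_len(d[1]))
  df$value <- as.vector(object$values)[with(df, x + (y - 1) * d[1] + (z - 1) * d[1] * d[2])]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y, fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::facet_wrap(~z, labeller = ggplot2::label_both) +
    ggplot2::scale_fill_viridis_c(na.value = "grey90") +
    ggplot2::coord_fixed() +
    ggplot2::labs(title = object$label, fill = NULL) +
    ggplot2::theme_minimal()
}

#' Component time-courses plot
#'
#' @param object A [run_spatial_ica()] result.
#' @param components Which components to draw (default all).
#' @param ... Ignored.
#' @return A ggplot faceted by component.
#' @export
autoplot.spatial_ica <- function(object, components = NULL, ...) {
  d <- tidy(object)
  if (!is.null(components)) d <- dplyr::filter(d, .data$component %in% components)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$time_s, y = .data$value)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_wrap(~component, scales = "free_y",
                        labeller = ggplot2::label_both) +
    ggplot2::labs(x = "Time (s)", y = "Component time-course") +
    ggplot2::theme_minimal()
}
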