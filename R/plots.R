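# ggplot2 views of the result objects.

#' Plot a field of view or rendered image
#'
#' @param image A numeric matrix.
#' @param pixel_size_nm Pixel size for physical axes (`NULL`: pixel axes).
#' @return A ggplot object (raster heat map, y pointing down as in images).
#' @export
plot_image <- function(image, pixel_size_nm = NULL) {
  df <- tidyr::expand_grid(y = seq_len(nrow(image)) - 1,
                           x = seq_len(ncol(image)) - 1)
  df$value <- as.vector(t(image))
  unit <- "px"
  if (!is.null(pixel_size_nm)) {
    df$x <- df$x * pixel_size_nm / 1000
    df$y <- df$y * pixel_size_nm / 1000
    unit <- "µm"
  }
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y, fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c(name = "intensity") +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = paste0("x (", unit, ")"), y = paste0("y (", unit, ")"))
}

#' @export
autoplot.state_diagram <- function(object, ...) {
  axes <- attr(object, "axes")
  df <- as_tibble(object)
  if (length(axes) == 1) {
    ggplot2::ggplot(df, ggplot2::aes(.data[[axes[1]]], .data$value)) +
      ggplot2::geom_hline(yintercept = 1, linetype = "dashed") +
      ggplot2::geom_pointrange(ggplot2::aes(
        ymin = .data$value - .data$error, ymax = .data$value + .data$error)) +
      ggplot2::geom_line() +
      ggplot2::labs(y = "normalized edge fractional area")
  } else {
    ggplot2::ggplot(df, ggplot2::aes(.data[[axes[1]]], .data[[axes[2]]],
                                     fill = .data$value)) +
      ggplot2::geom_tile() +
      ggplot2::scale_fill_viridis_c(name = "normalized\nedge fraction")
  }
}

#' @export
autoplot.partition_summary <- function(object, ...) {
  df <- object$per_condensate
  ggplot2::ggplot(df, ggplot2::aes(x = "sample", y = .data$pc)) +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed") +
    ggplot2::geom_jitter(width = 0.08, alpha = 0.6) +
    ggplot2::stat_summary(fun = mean, geom = "crossbar", width = 0.3) +
    ggplot2::labs(x = NULL, y = "partition coefficient")
}

#' @export
autoplot.filament_traces <- function(object, ...) {
  df <- purrr::map2(object$points_nm, object$trace_id, function(p, id) {
    tibble(trace_id = id, x_um = p[, 1] / 1000, y_um = p[, 2] / 1000)
  })
  df <- bind_rows(df)
  ggplot2::ggplot(df, ggplot2::aes(.data$x_um, .data$y_um,
                                   group = .data$trace_id,
                                   color = factor(.data$trace_id))) +
    ggplot2::geom_path(show.legend = FALSE) +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "x (µm)", y = "y (µm)")
}

#' @export
autoplot.population_stats <- function(object, ...) {
  df <- tibble(length_um = object$lengths_um)
  ggplot2::ggplot(df, ggplot2::aes(.data$length_um)) +
    ggplot2::geom_histogram(bins = 20) +
    ggplot2::geom_vline(xintercept = object$threshold_um,
                        linetype = "dashed") +
    ggplot2::labs(x = "filament length (µm)", y = "count")
}

#' @export
autoplot.puncta_spacing_report <- function(object, ...) {
  df <- tibble(spacing_nm = object$spacings_nm)
  ggplot2::ggplot(df, ggplot2::aes(y = .data$spacing_nm, x = "spacings")) +
    ggplot2::geom_boxplot(width = 0.3) +
    ggplot2::geom_jitter(width = 0.05) +
    ggplot2::labs(x = NULL, y = "inter-puncta spacing (nm)")
}
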