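# ggplot2 visualisations for the main result types.

#' @importFrom ggplot2 ggplot aes geom_point geom_path geom_raster geom_line
#'   scale_fill_gradient coord_equal labs theme_minimal facet_wrap scale_y_log10
NULL

#' Plot a cone mosaic
#'
#' Cone centres scaled by reflectance.
#'
#' @param object A `cone_mosaic`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.cone_mosaic <- function(object, ...) {
  ggplot(as_tibble(object), aes(x = .data$mu_x, y = .data$mu_y)) +
    geom_point(aes(size = .data$A), alpha = 0.7, show.legend = FALSE) +
    ggplot2::scale_size_continuous(range = c(0.3, 2)) +
    ggplot2::scale_y_reverse() +
    coord_equal() +
    labs(x = "x (arcmin)", y = "y (arcmin)",
         title = "Cone mosaic ground truth") +
    theme_minimal()
}

#' Plot an eye-movement trace
#'
#' Horizontal and vertical gaze displacement against time, with
#' microsaccade intervals marked.
#'
#' @param object An `eye_trace`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.eye_trace <- function(object, ...) {
  long <- tidyr::pivot_longer(as_tibble(object), c("x", "y"),
                              names_to = "axis", values_to = "arcmin")
  ms <- dplyr::filter(tidy(object), .data$kind == "microsaccade")
  p <- ggplot(long, aes(.data$t, .data$arcmin, colour = .data$axis)) +
    geom_line() +
    labs(x = "time (s)", y = "displacement (arcmin)",
         title = "Fixational eye-movement trace") +
    theme_minimal()
  if (nrow(ms) > 0) {
    p <- p + ggplot2::geom_vline(xintercept = ms$t_start,
                                 linetype = "dotted", colour = "grey40")
  }
  p
}

#' Plot a retina image or PSF
#'
#' @param object A `retina_image` or `psf`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.retina_image <- function(object, ...) {
  ps <- attr(object, "pixel_scale"); o <- attr(object, "origin")
  df <- tidyr::expand_grid(row = seq_len(nrow(object)),
                           col = seq_len(ncol(object)))
  df$x <- o[1] + (df$col - 1) * ps
  df$y <- o[2] + (df$row - 1) * ps
  df$value <- as.vector(unclass(object))[(df$col - 1) * nrow(object) + df$row]
  ggplot(df, aes(.data$x, .data$y, fill = .data$value)) +
    geom_raster() +
    scale_fill_gradient(low = "black", high = "white", guide = "none") +
    ggplot2::scale_y_reverse() +
    coord_equal() +
    labs(x = "x (arcmin)", y = "y (arcmin)") +
    theme_minimal()
}

#' @rdname autoplot.retina_image
#' @export
autoplot.psf <- function(object, ...) {
  ps <- attr(object, "pixel_scale")
  n <- nrow(object)
  autoplot.retina_image(structure(unclass(object), pixel_scale = ps,
                                  origin = -ps * c((n - 1) / 2, (n - 1) / 2),
                                  class = c("retina_image", "matrix", "array")))
}

#' Plot a radially averaged power spectrum
#'
#' @param spectrum Tibble from [radial_power_spectrum()].
#' @return A ggplot (log power against frequency in c/deg).
#' @export
plot_power_spectrum <- function(spectrum) {
  ggplot(dplyr::filter(spectrum, .data$freq_cpd > 0),
         aes(.data$freq_cpd, .data$power)) +
    geom_line() +
    scale_y_log10() +
    labs(x = "spatial frequency (c/deg)", y = "power",
         title = "Radially averaged power spectrum") +
    theme_minimal()
}
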