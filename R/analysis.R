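# Measurement helpers used for validating the simulator's own output.

#' Measure event displacement amplitudes from a trace
#'
#' For each event (typically the microsaccades), the Euclidean displacement
#' between the last sample before the event and the last sample inside it —
#' the amplitude a motion-extraction algorithm would recover from the trace.
#' Events starting at the first sample or truncated by the end of the trace
#' are dropped.
#'
#' @param trace An `eye_trace`.
#' @param events Subset of `tidy(trace)` rows to measure.
#' @return Numeric vector of displacement amplitudes (arcmin).
#' @export
measure_event_amplitudes <- function(trace, events) {
  rate <- attr(trace, "sample_rate")
  n <- nrow(trace)
  out <- rep(NA_real_, nrow(events))
  for (i in seq_len(nrow(events))) {
    i0 <- round(events$t_start[i] * rate) + 1L
    i1 <- round(events$t_end[i] * rate)
    if (i0 <= 1L || i1 >= n || i1 < i0) next
    out[i] <- sqrt((trace$x[i1] - trace$x[i0 - 1L])^2 +
                     (trace$y[i1] - trace$y[i0 - 1L])^2)
  }
  out[!is.na(out)]
}

#' Render a diffraction-limited, motion-free synthetic cone image
#'
#' Convenience pipeline for spectral validation: scales raw cone centres to
#' the requested eccentricity, assigns Marcuse widths and modulated
#' reflectances, renders the analytic retina on the oversampled fine grid,
#' applies the confocal effective kernel, and samples a uniform (scan-free)
#' output grid.
#'
#' @param centres Raw cone centres (e.g. from [rd_cone_positions()]).
#' @param eccentricity_deg Eccentricity to scale to (degrees).
#' @param fov_deg Output field of view (degrees, square).
#' @param out_px Output frame side (pixels).
#' @param pupil_diameter_mm Pupil for the diffraction-limited capture.
#' @param oversample Fine-grid oversampling factor.
#' @param seed Optional RNG seed for the reflectance draw.
#' @return A `retina_image` of the captured frame (pixel scale in arcmin).
#' @export
render_eccentricity_image <- function(centres, eccentricity_deg,
                                      fov_deg = 0.8, out_px = 192,
                                      pupil_diameter_mm = 5, oversample = 4,
                                      seed = NULL) {
  m <- scale_mosaic_to_eccentricity(centres, eccentricity_deg)
  sig_um <- cone_width_marcuse(cone_radius_histology_um(eccentricity_deg))
  sig_arcmin <- sig_um / (mm_per_deg() * 1000 / 60)
  a <- assign_reflectances(m, seed = seed)
  mos <- cone_mosaic(m[, c("mu_x", "mu_y")], sigma_x = sig_arcmin, A = a,
                     eccentricity_deg = eccentricity_deg)
  out_scale <- fov_deg * 60 / out_px
  fine <- out_scale / oversample
  model <- optical_model(pupil_diameter_mm = pupil_diameter_mm,
                         oversample = oversample)
  ksize <- 2 * floor(model$psf_extent_arcmin / fine / 2) + 1
  half <- fov_deg * 60 / 2
  guard <- (ksize - 1) / 2 * fine + 2 * fine
  ret <- render_retina(mos, fine, c(-half - guard, half + guard,
                                    -half - guard, half + guard))
  ax <- seq(-half + out_scale / 2, half - out_scale / 2, length.out = out_px)
  grid <- tidyr::expand_grid(y = ax, x = ax)
  vals <- capture_frame_fast(ret, model, grid, kernel_size = ksize)
  new_retina_image(matrix(vals, out_px, out_px, byrow = TRUE), out_scale,
                   origin = c(ax[1], ax[1]))
}
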