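#' Optical model of the double-pass confocal system
#'
#' Describes the pupil, wavelength, residual aberrations, optional
#' Stiles-Crawford pupil apodization and the confocal pinhole. Input and
#' output PSFs are assumed identical unless `zernike_out` is supplied.
#'
#' @param pupil_diameter_mm Pupil diameter (mm).
#' @param wavelength_nm Imaging wavelength (nm).
#' @param zernike Residual-aberration coefficients: data frame with columns
#'   `index` (ANSI single index, 0-based) and `value_um` (coefficient, um
#'   RMS), or `NULL` for diffraction-limited.
#' @param zernike_out Optional distinct coefficients for the output pass.
#' @param apodization_sigma_mm Gaussian amplitude-transmission sigma at the
#'   pupil (mm); `NULL` disables apodization.
#' @param pinhole_airy Pinhole diameter in Airy-disc diameters (1 Airy unit
#'   = 2.44 lambda/D).
#' @param oversample Sampling factor of the internal fine grid relative to
#'   the output frame (>= 2 required to respect the sampling rule; default 4,
#'   beyond which outputs are nearly identical).
#' @param psf_extent_arcmin Side length of the PSF/kernel support (arcmin).
#' @return An `optical_model` list.
#' @export
optical_model <- function(pupil_diameter_mm = 7.2, wavelength_nm = 840,
                          zernike = NULL, zernike_out = NULL,
                          apodization_sigma_mm = NULL, pinhole_airy = 1,
                          oversample = 4, psf_extent_arcmin = 8) {
  stopifnot(pupil_diameter_mm > 0, wavelength_nm > 0, pinhole_airy >= 0,
            psf_extent_arcmin > 0)
  if (oversample < 2) {
    abort("oversample must be >= 2: the fine grid must sample at least twice as finely as the output frame")
  }
  for (z in list(zernike, zernike_out)) {
    if (!is.null(z)) stopifnot(all(c("index", "value_um") %in% names(z)))
  }
  structure(as.list(environment()), class = "optical_model")
}

# --- Zernike polynomials, ANSI Z80.28 single-index ordering -----------------

zernike_nm <- function(j) {
  n <- ceiling((-3 + sqrt(9 + 8 * j)) / 2)
  m <- 2 * j - n * (n + 2)
  list(n = n, m = m)
}

# Normalised Zernike polynomial j (ANSI) on unit-disc polar coordinates.
zernike_eval <- function(j, rho, theta) {
  nm <- zernike_nm(j)
  n <- nm$n; m <- nm$m; am <- abs(m)
  r <- 0
  for (k in 0:((n - am) / 2)) {
    r <- r + (-1)^k * factorial(n - k) /
      (factorial(k) * factorial((n + am) / 2 - k) * factorial((n - am) / 2 - k)) *
      rho^(n - 2 * k)
  }
  norm <- sqrt(2 * (n + 1) / (1 + (m == 0)))
  ang <- if (m >= 0) cos(am * theta) else sin(am * theta)
  norm * r * ang
}

# Aberration phase (radians) over pupil grid; rho > 1 masked later.
zernike_wavefront_um <- function(zernike, rho, theta) {
  w <- 0
  if (!is.null(zernike) && nrow(zernike) > 0) {
    for (i in seq_len(nrow(zernike))) {
      w <- w + zernike$value_um[i] * zernike_eval(zernike$index[i], rho, theta)
    }
  }
  w
}

airy_radius_arcmin <- function(model) {
  1.22 * model$wavelength_nm * 1e-9 / (model$pupil_diameter_mm * 1e-3) *
    ARCMIN_PER_RAD
}

#' Point spread function from the pupil function
#'
#' `PSF = |FT(pupil amplitude x apodization x exp(i 2 pi W / lambda))|^2`,
#' computed by discrete Fourier transform on a grid whose pixel scale is the
#' output frame scale divided by `oversample`. The PSF is normalised to unit
#' sum.
#'
#' @param model An [optical_model()].
#' @param which `"in"` or `"out"` pass.
#' @param pixel_scale_arcmin Fine-grid pixel scale; default
#'   `airy radius / (2 * oversample)`.
#' @param size Grid side (pixels, forced odd); default covers
#'   `psf_extent_arcmin`.
#' @return A `psf` object: matrix with attribute `pixel_scale` (arcmin/px).
#' @export
psf_from_pupil <- function(model, which = c("in", "out"),
                           pixel_scale_arcmin = NULL, size = NULL) {
  which <- match.arg(which)
  ps <- pixel_scale_arcmin %||% (airy_radius_arcmin(model) / (2 * model$oversample))
  n <- size %||% (2 * floor(model$psf_extent_arcmin / ps / 2) + 1)
  if (n %% 2 == 0) n <- n + 1
  lambda_m <- model$wavelength_nm * 1e-9
  d_m <- model$pupil_diameter_mm * 1e-3
  ps_rad <- ps / ARCMIN_PER_RAD
  # pupil-plane sample spacing set by FFT reciprocity: dx = lambda / (n * ps)
  dx <- lambda_m / (n * ps_rad)
  r_px <- (d_m / 2) / dx
  if (r_px > (n - 1) / 2) {
    abort("PSF grid too small for this pupil: enlarge psf_extent_arcmin or coarsen the pixel scale")
  }
  ax <- seq_len(n) - (n + 1) / 2
  xx <- outer(rep(1, n), ax); yy <- outer(ax, rep(1, n))
  rho <- sqrt(xx^2 + yy^2) / r_px
  inside <- rho <= 1
  amp <- matrix(0, n, n)
  amp[inside] <- 1
  if (!is.null(model$apodization_sigma_mm)) {
    r_mm <- rho * model$pupil_diameter_mm / 2
    amp <- amp * exp(-r_mm^2 / (2 * model$apodization_sigma_mm^2))
  }
  zern <- if (which == "in") model$zernike else (model$zernike_out %||% model$zernike)
  theta <- atan2(yy, xx)
  w_um <- zernike_wavefront_um(zern, pmin(rho, 1), theta)
  phase <- 2 * pi * w_um * 1e-6 / lambda_m
  pupil <- amp * exp(1i * phase)
  field <- fftshift2(fft(ifftshift2(pupil)))
  psf <- Mod(field)^2
  psf <- psf / sum(psf)
  structure(psf, pixel_scale = ps, class = c("psf", "matrix", "array"))
}

#' Strehl ratio of the modelled PSF
#'
#' Peak of the aberrated PSF divided by the peak of the corresponding
#' diffraction-limited PSF (same pupil, no Zernike terms).
#'
#' @inheritParams psf_from_pupil
#' @return Numeric scalar in (0, 1].
#' @export
strehl_ratio <- function(model, pixel_scale_arcmin = NULL, size = NULL) {
  p_ab <- psf_from_pupil(model, "in", pixel_scale_arcmin, size)
  model0 <- model
  model0$zernike <- NULL
  p_dl <- psf_from_pupil(model0, "in", pixel_scale_arcmin, size)
  max(p_ab) / max(p_dl)
}

# Anti-aliased disc mask for the pinhole, same grid as the PSFs.
pinhole_mask <- function(model, pixel_scale_arcmin, size) {
  n <- size
  # pinhole diameter of p Airy units = p * 2.44 lambda/D, so radius = p * 1.22 lambda/D
  radius <- model$pinhole_airy * airy_radius_arcmin(model)
  ax <- (seq_len(n) - (n + 1) / 2) * pixel_scale_arcmin
  rr <- sqrt(outer(ax^2, rep(1, n)) + outer(rep(1, n), ax^2))
  # coverage ramp one pixel wide at the rim
  pmin(pmax((radius - rr) / pixel_scale_arcmin + 0.5, 0), 1)
}

#' Effective confocal collection kernel
#'
#' For PSFs that are constant over a frame, the Fig.-style per-sample
#' capture (illuminate, reimage, pinhole, integrate) collapses to a single
#' correlation of the retina with the effective kernel
#' `K(u) = PSF_in(u) * (PSF_out (x) pinhole)(u)`, where `(x)` denotes
#' correlation of the output PSF with the pinhole transmission centred on
#' the beam. As the pinhole shrinks to a point `K -> PSF_in . PSF_out`
#' (whose transfer function is the autocorrelation of the single-pass OTF);
#' as the pinhole opens fully `K -> PSF_in` (confocality lost).
#'
#' @inheritParams psf_from_pupil
#' @param pixel_scale_arcmin Grid scale for the kernel (arcmin/px).
#' @param size Kernel side (odd); defaults from the model extent.
#' @return A `psf`-classed matrix (not normalised: its sum is the fraction
#'   of light collected through the pinhole for a uniform unit retina).
#' @export
effective_kernel <- function(model, pixel_scale_arcmin = NULL, size = NULL) {
  p_in <- psf_from_pupil(model, "in", pixel_scale_arcmin, size)
  ps <- attr(p_in, "pixel_scale")
  n <- nrow(p_in)
  p_out <- psf_from_pupil(model, "out", ps, n)
  mask <- pinhole_mask(model, ps, n)
  cc <- xcorr2(mask, p_out)   # (PSF_out corr pinhole)(u) on the same grid
  k <- unclass(p_in) * cc
  structure(k, pixel_scale = ps, class = c("psf", "matrix", "array"))
}

#' Capture a single confocal sample (explicit pipeline)
#'
#' The detector signal for one beam position, computed by the explicit
#' sequence: multiply the retina by the beam-centred input PSF, convolve the
#' illuminated patch with the output PSF, mask by the pinhole transmission
#' (unit disc centred on the beam), and sum. The beam must sit on the retina
#' grid to within a pixel interpolation: off-grid positions are evaluated by
#' bilinear interpolation between the four neighbouring grid evaluations.
#'
#' @param retina A `retina_image` (see [render_retina()]); its pixel scale
#'   defines the computation grid.
#' @param model An [optical_model()].
#' @param beam_position `c(x, y)` in arcmin.
#' @param kernel_size Optional PSF support (pixels, odd).
#' @return Detector intensity (non-negative scalar).
#' @export
capture_sample <- function(retina, model, beam_position, kernel_size = NULL) {
  ps <- attr(retina, "pixel_scale"); o <- attr(retina, "origin")
  n <- kernel_size %||% (2 * floor(model$psf_extent_arcmin / ps / 2) + 1)
  p_in <- psf_from_pupil(model, "in", ps, n)
  p_out <- psf_from_pupil(model, "out", ps, n)
  mask <- pinhole_mask(model, ps, n)
  col <- (beam_position[1] - o[1]) / ps + 1
  row <- (beam_position[2] - o[2]) / ps + 1
  eval_at <- function(r0, c0) {
    h <- (n - 1) / 2
    if (r0 - h < 1 || r0 + h > nrow(retina) || c0 - h < 1 || c0 + h > ncol(retina)) {
      abort("beam too close to the retina edge: render the retina with a guard band at least the PSF half-width")
    }
    patch <- unclass(retina)[(r0 - h):(r0 + h), (c0 - h):(c0 + h)]
    illuminated <- patch * unclass(p_in)
    at_pinhole <- xcorr2(illuminated, unclass(p_out)[n:1, n:1, drop = FALSE]) # convolution
    sum(at_pinhole * mask)
  }
  r0 <- floor(row); c0 <- floor(col)
  fr <- row - r0; fc <- col - c0
  if (abs(fr) < 1e-9 && abs(fc) < 1e-9) return(eval_at(r0, c0))
  v00 <- eval_at(r0, c0)
  v10 <- if (fr > 1e-9) eval_at(r0 + 1, c0) else v00
  v01 <- if (fc > 1e-9) eval_at(r0, c0 + 1) else v00
  v11 <- if (fr > 1e-9 && fc > 1e-9) eval_at(r0 + 1, c0 + 1) else v00
  (1 - fr) * (1 - fc) * v00 + fr * (1 - fc) * v10 +
    (1 - fr) * fc * v01 + fr * fc * v11
}

#' Capture a full sample stream via the effective-kernel fast path
#'
#' Mathematically equivalent to applying [capture_sample()] at every beam
#' position (to ~1e-6 relative, the FFT round-off), but computed as one
#' correlation of the retina with the effective kernel followed by bilinear
#' interpolation at the beam positions. Valid while the PSFs are constant
#' within the frame.
#'
#' @param retina A `retina_image` with a guard band at least the kernel
#'   half-width around the sampled region.
#' @param model An [optical_model()].
#' @param pattern A `scan_pattern` (with or without eye motion).
#' @param kernel_size Optional kernel support (pixels, odd).
#' @return Numeric vector of detector intensities, one per pattern row.
#' @export
capture_frame_fast <- function(retina, model, pattern, kernel_size = NULL) {
  ps <- attr(retina, "pixel_scale"); o <- attr(retina, "origin")
  n <- kernel_size %||% (2 * floor(model$psf_extent_arcmin / ps / 2) + 1)
  k <- effective_kernel(model, ps, n)
  field <- xcorr2(unclass(retina), unclass(k))
  h <- (n - 1) / 2
  row <- (pattern$y - o[2]) / ps + 1
  col <- (pattern$x - o[1]) / ps + 1
  if (any(row < h + 1) || any(row > nrow(retina) - h) ||
      any(col < h + 1) || any(col > ncol(retina) - h)) {
    abort("beam leaves the retina guard band: render a larger retina or reduce motion")
  }
  interp2_bilinear(field, row, col)
}

#' Add detector noise to a sample stream
#'
#' Additive Gaussian noise. By default noise is applied in raw-sample space
#' (before desinusoiding). With `stage = "post_with_warp"` the noise stream
#' itself is desinusoided and must then be added to the desinusoided frame
#' by the caller: adding unwarped noise to a desinusoided frame would give
#' the noise the wrong column statistics near the line edges.
#'
#' @param stream Numeric vector (raw samples).
#' @param noise_mean,noise_sd Noise distribution; `sd = 0` is the identity.
#' @param stage `"pre_desinusoid"` (default) or `"post_with_warp"`.
#' @param cfg [scan_config()]; required for `"post_with_warp"`.
#' @param seed Optional RNG seed.
#' @return For `"pre_desinusoid"`: the noisy stream. For
#'   `"post_with_warp"`: the desinusoided noise frame (matrix) to add to a
#'   desinusoided image.
#' @export
add_noise <- function(stream, noise_mean = 0, noise_sd = 0.02,
                      stage = c("pre_desinusoid", "post_with_warp"),
                      cfg = NULL, seed = NULL) {
  stage <- match.arg(stage)
  if (noise_sd < 0) abort("noise_sd must be >= 0")
  with_seed_if(seed, {
    if (stage == "pre_desinusoid") {
      if (noise_sd == 0 && noise_mean == 0) return(stream)
      stream + rnorm(length(stream), noise_mean, noise_sd)
    } else {
      if (is.null(cfg)) abort("cfg is required to warp post-desinusoid noise")
      noise <- rnorm(length(stream), noise_mean, noise_sd)
      desinusoid(noise, cfg)
    }
  })
}
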