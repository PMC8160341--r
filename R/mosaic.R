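#' Hexagonal-packing spacing from cone density
#'
#' Converts a cone density `rho` (cones per unit area) to a spacing
#' `s = (2 rho / sqrt(3))^(-1/2)`. For a hexagonal lattice this `s` is the
#' row spacing (`sqrt(3)/2` times the centre-to-centre distance), so the
#' relation inverts as `rho = sqrt(3) / (2 s^2)`.
#'
#' @param rho Cone density, cones per unit area (> 0). Vectorised.
#' @return Spacing in the length unit implied by `rho`.
#' @export
#' @examples
#' spacing_from_density(2 / sqrt(3))   # 0.866
spacing_from_density <- function(rho) {
  if (any(!is.finite(rho)) || any(rho <= 0)) {
    abort("rho must be a positive, finite density")
  }
  (2 * rho / sqrt(3))^(-1 / 2)
}

# Approximate in-vivo human cone density vs eccentricity (cones/mm^2).
# Piecewise log-linear lookup; user-overridable wherever it is consumed.
# Values are on the lower side of histological counts, consistent with
# adult densities measured from AOSLO images outside the foveal centre.
.default_density_table <- function() {
  tibble(
    eccentricity_deg = c(0.5, 1, 1.5, 2, 3, 4, 5, 6, 8, 10),
    density_mm2      = 1000 * c(45, 30, 22, 18, 14, 11.5, 10, 8.5, 7, 6)
  )
}

#' Cone density at a retinal eccentricity
#'
#' Log-linear interpolation of an embedded approximate density model
#' (cones/mm^2 against eccentricity in degrees). Supply `table` to use your
#' own histology.
#'
#' @param eccentricity_deg Eccentricity in degrees, within the table domain.
#' @param table Optional replacement table with columns `eccentricity_deg`
#'   and `density_mm2`.
#' @return Density in cones/mm^2.
#' @export
cone_density <- function(eccentricity_deg, table = NULL) {
  tab <- table %||% .default_density_table()
  stopifnot(all(c("eccentricity_deg", "density_mm2") %in% names(tab)))
  rng <- range(tab$eccentricity_deg)
  if (any(eccentricity_deg < rng[1]) || any(eccentricity_deg > rng[2])) {
    abort(sprintf("eccentricity outside the density model domain [%g, %g] deg",
                  rng[1], rng[2]))
  }
  exp(approx(tab$eccentricity_deg, log(tab$density_mm2),
             xout = eccentricity_deg)$y)
}

#' Target cone spacing at an eccentricity
#'
#' Converts the density model to an angular nearest-neighbour spacing in
#' arcmin, optionally rescaled for axial length (a longer eye compresses the
#' same retinal spacing into a smaller visual angle).
#'
#' @inheritParams cone_density
#' @param axial_length_mm Axial length (mm); default 24 (schematic eye).
#' @return Spacing in arcmin of visual angle.
#' @export
cone_spacing_arcmin <- function(eccentricity_deg, axial_length_mm = 24,
                                table = NULL) {
  rho_mm2 <- cone_density(eccentricity_deg, table)
  rho_deg2 <- rho_mm2 * mm_per_deg(24)^2  # density on the schematic retina, per deg^2
  s_deg <- spacing_from_density(rho_deg2)
  s_deg * 60 * 24 / axial_length_mm
}

#' Construct a cone mosaic table
#'
#' A cone mosaic is a tibble with one row per cone and columns `mu_x`,
#' `mu_y` (centre, arcmin), `sigma_x`, `sigma_y` (Gaussian widths, arcmin),
#' `theta` (orientation, radians in `[0, pi)`) and `A` (reflectance, >= 0);
#' this table is the ground truth of the synthetic retina.
#'
#' @param positions Two-column matrix or data frame of centres (arcmin).
#' @param sigma_x,sigma_y Gaussian widths (arcmin), recycled.
#' @param theta Orientation (radians), recycled.
#' @param A Reflectance, recycled.
#' @param eccentricity_deg Optional eccentricity annotation.
#' @return A `cone_mosaic` tibble.
#' @export
cone_mosaic <- function(positions, sigma_x = 0.25, sigma_y = sigma_x,
                        theta = 0, A = 1, eccentricity_deg = NA_real_) {
  xy <- as_positions(positions)
  n <- nrow(xy)
  m <- tibble(
    mu_x = xy[, 1], mu_y = xy[, 2],
    sigma_x = rep_len(sigma_x, n), sigma_y = rep_len(sigma_y, n),
    theta = rep_len(theta, n) %% pi, A = rep_len(A, n)
  )
  if (any(m$sigma_x <= 0) || any(m$sigma_y <= 0)) abort("sigma must be > 0")
  if (any(m$A < 0)) abort("reflectance A must be >= 0")
  if (n >= 2 && min(nearest_neighbour_distances(m)) <= 0) {
    abort("cone centres must be distinct")
  }
  new_cone_mosaic(m, eccentricity_deg = eccentricity_deg,
                  mean_spacing_arcmin = if (n >= 2) mean(nearest_neighbour_distances(m)) else NA_real_)
}

new_cone_mosaic <- function(df, eccentricity_deg = NA_real_,
                            mean_spacing_arcmin = NA_real_) {
  structure(as_tibble(df),
            eccentricity_deg = eccentricity_deg,
            mean_spacing_arcmin = mean_spacing_arcmin,
            class = c("cone_mosaic", class(as_tibble(df))))
}

#' Scale cone positions to match human cone spacing at an eccentricity
#'
#' Uniformly rescales a set of cone centres (for example the output of
#' [rd_cone_positions()], in grid pixels) so that the mean nearest-neighbour
#' distance equals the target spacing from the embedded density model at the
#' given eccentricity. The transform is a pure similarity: relative geometry
#' is unchanged. The result is recentred on the origin.
#'
#' @param centres Positions (matrix or data frame; any length unit).
#' @param eccentricity_deg Retinal eccentricity (degrees).
#' @param axial_length_mm Axial length (mm) for angular rescaling.
#' @param table Optional density table (see [cone_density()]).
#' @return A `cone_mosaic` tibble (positions only: `mu_x`, `mu_y` in arcmin;
#'   width/orientation/reflectance columns filled with defaults of
#'   [cone_mosaic()]).
#' @export
scale_mosaic_to_eccentricity <- function(centres, eccentricity_deg,
                                         axial_length_mm = 24, table = NULL) {
  xy <- as_positions(centres)
  if (nrow(xy) < 7) abort("at least 7 centres required for nearest-neighbour scaling")
  target <- cone_spacing_arcmin(eccentricity_deg, axial_length_mm, table)
  nn <- nearest_neighbour_distances(xy)
  factor <- target / mean(nn)
  xy <- sweep(xy, 2, colMeans(xy))
  xy <- xy * factor
  m <- cone_mosaic(xy, eccentricity_deg = eccentricity_deg)
  attr(m, "mean_spacing_arcmin") <- target
  m
}

#' Fundamental-mode field radius of a cone by the Marcuse equation
#'
#' Treats a cone inner segment as a step-index fibre of core radius `a` and
#' returns the Marcuse estimate of the fundamental (LP01) mode-field radius
#' `w = a (0.65 + 1.619 V^-1.5 + 2.879 V^-6)` with
#' `V = (2 pi a / lambda) NA`, `NA = sqrt(n_core^2 - n_clad^2)`.
#'
#' @param cone_radius_um Core radius `a` (microns). Vectorised.
#' @param wavelength_um Wavelength (microns).
#' @param n_core,n_clad Refractive indices (core > cladding).
#' @return Mode-field radius `w` in microns.
#' @export
marcuse_mode_radius <- function(cone_radius_um, wavelength_um = 0.84,
                                n_core = 1.39, n_clad = 1.34) {
  if (n_core <= n_clad) abort("n_core must exceed n_clad")
  stopifnot(all(cone_radius_um > 0), wavelength_um > 0)
  na <- sqrt(n_core^2 - n_clad^2)
  v <- 2 * pi * cone_radius_um / wavelength_um * na
  cone_radius_um * (0.65 + 1.619 * v^(-3 / 2) + 2.879 * v^(-6))
}

#' Gaussian sigma of a cone reflectance profile
#'
#' Converts the Marcuse mode-field radius `w` (1/e field radius) to the
#' sigma of the Gaussian used to render the cone, `sigma = w / sqrt(2)`,
#' i.e. the rendered profile is the field-amplitude Gaussian
#' `exp(-r^2 / w^2)`. The methods vignette discusses this convention (the
#' strict intensity profile would use `w / 2`).
#'
#' @inheritParams marcuse_mode_radius
#' @return Gaussian sigma in microns.
#' @export
cone_width_marcuse <- function(cone_radius_um, wavelength_um = 0.84,
                               n_core = 1.39, n_clad = 1.34) {
  marcuse_mode_radius(cone_radius_um, wavelength_um, n_core, n_clad) / sqrt(2)
}

# Approximate cone inner-segment diameter (um) vs eccentricity (deg).
cone_radius_histology_um <- function(eccentricity_deg) {
  (2.2 + 0.55 * eccentricity_deg) / 2
}

#' Assign cone reflectances
#'
#' Reflectances are drawn from a normal distribution (clipped at zero) and
#' multiplied by a smooth low-spatial-frequency modulation field evaluated at
#' each cone centre, emulating the patchy brightness of real cone images.
#' The modulation field is normalised to unit mean over the cones, so the
#' configured mean is preserved.
#'
#' @param centres Cone centres (matrix or data frame, arcmin).
#' @param mean,sd Parameters of the base normal draw (`mean > 0`, `sd >= 0`).
#' @param modulation Apply the low-frequency modulation field?
#' @param mod_length_arcmin Correlation length of the modulation (arcmin).
#' @param mod_depth Relative sd of the modulation field.
#' @param seed Optional RNG seed.
#' @return Numeric vector of reflectances `A >= 0`, one per centre.
#' @export
assign_reflectances <- function(centres, mean = 1, sd = 0.2,
                                modulation = TRUE, mod_length_arcmin = 15,
                                mod_depth = 0.3, seed = NULL) {
  if (mean < 0 || sd < 0) abort("reflectance mean and sd must be non-negative")
  xy <- as_positions(centres)
  n <- nrow(xy)
  with_seed_if(seed, {
    a <- rnorm(n, mean, sd)
    if (modulation && n > 1) {
      fld <- smooth_random_field(xy[, 1], xy[, 2], mod_length_arcmin)
      fld <- 1 + mod_depth * fld
      fld <- pmax(fld, 0)
      fld <- fld / base::mean(fld)
      a <- a * fld
    }
    pmax(a, 0)
  })
}

#' Uniform-random control mosaic
#'
#' Places cones i.i.d. uniformly in a rectangle, with no minimum-spacing
#' constraint: the completely irregular control against which the packing
#' regularity of self-organised mosaics is compared.
#'
#' @param n_cones Number of cones (>= 1).
#' @param bounds Rectangle `c(xmin, xmax, ymin, ymax)` (arcmin).
#' @param seed Optional RNG seed.
#' @return A `cone_mosaic` tibble (positions only).
#' @export
random_mosaic <- function(n_cones, bounds = c(-30, 30, -30, 30), seed = NULL) {
  stopifnot(n_cones >= 1, length(bounds) == 4,
            bounds[2] > bounds[1], bounds[4] > bounds[3])
  with_seed_if(seed, {
    cone_mosaic(cbind(runif(n_cones, bounds[1], bounds[2]),
                      runif(n_cones, bounds[3], bounds[4])))
  })
}

#' Render the analytic ground-truth retina
#'
#' Evaluates the retina reflectance map as a sum of oriented Gaussians,
#' `R(x,y) = sum_i A_i exp(-(a dx^2 + 2 b dx dy + c dy^2))` with
#' `a = cos^2(t)/(2 sx^2) + sin^2(t)/(2 sy^2)`,
#' `b = sin(2t) (1/(4 sx^2) - 1/(4 sy^2))`,
#' `c = sin^2(t)/(2 sx^2) + cos^2(t)/(2 sy^2)`,
#' exactly at pixel centres. Rendering is linear in the reflectances.
#'
#' @param mosaic A `cone_mosaic`.
#' @param pixel_scale Arcmin per pixel; choose at most half the finest
#'   structure of interest (the frame generator renders at
#'   `output scale / oversample`).
#' @param bounds Rectangle `c(xmin, xmax, ymin, ymax)` in arcmin.
#' @param support_sigmas Gaussians are truncated beyond this many sigmas.
#' @return A `retina_image`: matrix of reflectance with attributes
#'   `pixel_scale` (arcmin/px) and `origin` (arcmin coordinates of pixel
#'   `[1, 1]`, i.e. (x of column 1, y of row 1)).
#' @export
render_retina <- function(mosaic, pixel_scale, bounds, support_sigmas = 5) {
  stopifnot(pixel_scale > 0, length(bounds) == 4)
  xs <- seq(bounds[1], bounds[2], by = pixel_scale)
  ys <- seq(bounds[3], bounds[4], by = pixel_scale)
  img <- matrix(0, nrow = length(ys), ncol = length(xs))
  inside <- mosaic$mu_x >= bounds[1] - support_sigmas * mosaic$sigma_x &
    mosaic$mu_x <= bounds[2] + support_sigmas * mosaic$sigma_x &
    mosaic$mu_y >= bounds[3] - support_sigmas * mosaic$sigma_y &
    mosaic$mu_y <= bounds[4] + support_sigmas * mosaic$sigma_y
  if (!any(inside)) {
    warn("bounds exclude all cones; returning a blank image")
  }
  m <- mosaic[inside, , drop = FALSE]
  for (i in seq_len(nrow(m))) {
    sx <- m$sigma_x[i]; sy <- m$sigma_y[i]; th <- m$theta[i]
    a <- cos(th)^2 / (2 * sx^2) + sin(th)^2 / (2 * sy^2)
    b <- sin(2 * th) * (1 / (4 * sx^2) - 1 / (4 * sy^2))
    cc <- sin(th)^2 / (2 * sx^2) + cos(th)^2 / (2 * sy^2)
    r <- support_sigmas * max(sx, sy)
    jx <- which(abs(xs - m$mu_x[i]) <= r)
    jy <- which(abs(ys - m$mu_y[i]) <= r)
    if (length(jx) == 0 || length(jy) == 0) next
    dx <- xs[jx] - m$mu_x[i]
    dy <- ys[jy] - m$mu_y[i]
    g <- m$A[i] * exp(-(outer(dy^2, rep(1, length(dx))) * cc +
                         2 * b * outer(dy, dx) +
                         outer(rep(1, length(dy)), dx^2) * a))
    img[jy, jx] <- img[jy, jx] + g
  }
  new_retina_image(img, pixel_scale, origin = c(xs[1], ys[1]))
}

new_retina_image <- function(pixels, pixel_scale, origin) {
  structure(pixels, pixel_scale = pixel_scale, origin = origin,
            class = c("retina_image", "matrix", "array"))
}

#' @export
print.retina_image <- function(x, ...) {
  cat(sprintf("<retina_image> %d x %d px, %.4g arcmin/px, origin (%.3g, %.3g) arcmin\n",
              nrow(x), ncol(x), attr(x, "pixel_scale"),
              attr(x, "origin")[1], attr(x, "origin")[2]))
  invisible(x)
}

# Value of a retina_image at continuous arcmin coordinates (bilinear).
retina_value_at <- function(retina, x, y) {
  ps <- attr(retina, "pixel_scale"); o <- attr(retina, "origin")
  interp2_bilinear(unclass(retina), (y - o[2]) / ps + 1, (x - o[1]) / ps + 1)
}

#' Read or write a cone mosaic as CSV
#'
#' Columns `mu_x, mu_y, sigma_x, sigma_y, theta, A`, header row, units
#' arcmin (theta in radians).
#'
#' @param mosaic A `cone_mosaic`.
#' @param path File path.
#' @return `write_cone_mosaic_csv()` returns `path` invisibly;
#'   `read_cone_mosaic_csv()` returns a `cone_mosaic`.
#' @export
write_cone_mosaic_csv <- function(mosaic, path) {
  utils::write.csv(as.data.frame(mosaic)[c("mu_x", "mu_y", "sigma_x",
                                           "sigma_y", "theta", "A")],
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cone_mosaic_csv
#' @export
read_cone_mosaic_csv <- function(path) {
  df <- utils::read.csv(path)
  cone_mosaic(df[c("mu_x", "mu_y")], sigma_x = df$sigma_x,
              sigma_y = df$sigma_y, theta = df$theta, A = df$A)
}

#' Write a retina image as 32-bit float TIFF
#'
#' Pixel scale is recorded in the TIFF description tag and in a JSON sidecar
#' (`<path>.json`).
#'
#' @param retina A `retina_image`.
#' @param path Output path.
#' @export
write_retina_tiff <- function(retina, path) {
  meta <- list(pixel_scale_arcmin = attr(retina, "pixel_scale"),
               origin_arcmin = attr(retina, "origin"))
  tiff::writeTIFF(unclass(retina), path, bits.per.sample = 32L,
                  description = jsonlite::toJSON(meta, auto_unbox = TRUE))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}
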