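#' End-to-end simulation configuration
#'
#' Bundles every stage of the simulator: retinal eccentricity and mosaic
#' generation, the optical model, the raster scan, eye motion, noise and
#' run flags. `seed` fixes the entire run.
#'
#' @param eccentricity_deg Retinal eccentricity (degrees).
#' @param axial_length_mm Axial length of the simulated eye (mm).
#' @param scan A [scan_config()].
#' @param optics An [optical_model()].
#' @param eye An [eye_motion_params()].
#' @param noise_mean,noise_sd Additive detector noise (fraction of signal
#'   full scale), applied in raw-sample space.
#' @param n_frames Number of frames.
#' @param seed Integer seed for the whole run.
#' @param motion,aberrations,noise Stage flags; with all three off, every
#'   frame equals the reference frame.
#' @param mosaic Optional user-supplied `cone_mosaic` (arcmin coordinates);
#'   by default one is generated by reaction-diffusion and scaled to
#'   `eccentricity_deg`.
#' @param zernike_series Optional per-frame aberrations: data frame with
#'   columns `frame`, `index`, `value_um`; overrides `optics$zernike`
#'   frame by frame.
#' @param rd_grid,rd_steps Reaction-diffusion grid size and step count used
#'   when `mosaic` is NULL.
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(eccentricity_deg = 3, axial_length_mm = 24,
                              scan = scan_config(n_lines = 128,
                                                 samples_per_line = 128,
                                                 fov_x = 0.5, fov_y = 0.5),
                              optics = optical_model(),
                              eye = eye_motion_params(),
                              noise_mean = 0, noise_sd = 0.02,
                              n_frames = 1, seed = 1,
                              motion = TRUE, aberrations = TRUE, noise = TRUE,
                              mosaic = NULL, zernike_series = NULL,
                              rd_grid = 300, rd_steps = 20000) {
  stopifnot(n_frames >= 1)
  structure(as.list(environment()), class = "simulation_config")
}

#' Generate a synthetic AOSLO dataset with ground truth
#'
#' Runs the full pipeline: cone mosaic (reaction-diffusion, scaled to the
#' configured eccentricity, Marcuse widths, modulated reflectances) ->
#' analytic retina render on a fine grid -> effective confocal kernel ->
#' eye trace -> raster sampling -> additive noise -> desinusoiding.
#' The returned object carries the full ground truth and a motion-, noise-
#' and aberration-free reference frame; re-running with the same config is
#' bit-identical.
#'
#' @param cfg A [simulation_config()].
#' @return A `frame_set`: list with `frames` (list of matrices),
#'   `raw_streams` (list of per-frame raw sample vectors), `reference_frame`,
#'   `ground_truth` (list: `mosaic`, `trace`, `zernike`, `seed`, `config`).
#' @export
generate_dataset <- function(cfg) {
  stopifnot(inherits(cfg, "simulation_config"))
  withr::local_seed(cfg$seed)
  scan <- cfg$scan

  # --- ground-truth mosaic --------------------------------------------------
  mosaic <- cfg$mosaic
  if (is.null(mosaic)) {
    centres <- rd_cone_positions(n = cfg$rd_grid, n_steps = cfg$rd_steps)
    m <- scale_mosaic_to_eccentricity(centres, cfg$eccentricity_deg,
                                      cfg$axial_length_mm)
    sig_um <- cone_width_marcuse(
      cone_radius_histology_um(cfg$eccentricity_deg),
      cfg$optics$wavelength_nm / 1000)
    sig_arcmin <- sig_um / (mm_per_deg(cfg$axial_length_mm) * 1000 / 60)
    a <- assign_reflectances(m)
    mosaic <- cone_mosaic(m[, c("mu_x", "mu_y")], sigma_x = sig_arcmin,
                          theta = 0, A = a,
                          eccentricity_deg = cfg$eccentricity_deg)
  }

  # --- eye motion -----------------------------------------------------------
  duration <- cfg$n_frames / scan$frame_rate
  trace <- if (cfg$motion) {
    generate_eye_trace(duration + 2 / scan$frame_rate, cfg$eye)
  } else {
    zero_trace(duration + 2 / scan$frame_rate, cfg$eye$sample_rate)
  }

  pattern <- build_scan_pattern(scan, cfg$n_frames)
  pattern <- combine_motion(pattern, trace)

  # --- analytic retina on the fine grid ------------------------------------
  # guard band: kernel half-width plus the actual gaze excursion of this run
  out_scale <- 60 * scan$fov_x / scan$samples_per_line      # arcmin/px
  fine <- out_scale / cfg$optics$oversample
  ksize <- 2 * floor(cfg$optics$psf_extent_arcmin / fine / 2) + 1
  guard <- (ksize - 1) / 2 * fine + 2 * fine
  half_x <- max(abs(pattern$x)) + guard
  half_y <- max(abs(pattern$y)) + guard
  retina <- render_retina(mosaic, fine, c(-half_x, half_x, -half_y, half_y))

  # --- per-frame capture ----------------------------------------------------
  zs <- if (cfg$aberrations) cfg$zernike_series else NULL
  static_model <- frame_model(cfg, 0L)
  frames <- vector("list", cfg$n_frames)
  raws <- vector("list", cfg$n_frames)
  field <- NULL
  for (fr in seq_len(cfg$n_frames)) {
    model <- if (is.null(zs)) static_model else frame_model(cfg, fr)
    if (is.null(field) || !is.null(zs)) {
      k <- effective_kernel(model, fine, ksize)
      field <- xcorr2(unclass(retina), unclass(k))
    }
    rows_fr <- pattern$frame == fr
    o <- attr(retina, "origin")
    ri <- (pattern$y[rows_fr] - o[2]) / fine + 1
    ci <- (pattern$x[rows_fr] - o[1]) / fine + 1
    stream <- interp2_bilinear(field, ri, ci)
    if (cfg$noise && (cfg$noise_sd > 0 || cfg$noise_mean != 0)) {
      stream <- stream + rnorm(length(stream), cfg$noise_mean * max(stream),
                               cfg$noise_sd * max(stream))
    }
    raws[[fr]] <- stream
    frames[[fr]] <- desinusoid(stream, scan)
  }

  # --- reference frame: no motion, no aberration, no noise ------------------
  ref_model <- frame_model(cfg, 0L, diffraction_limited = TRUE)
  kref <- effective_kernel(ref_model, fine, ksize)
  ref_field <- xcorr2(unclass(retina), unclass(kref))
  pat0 <- build_scan_pattern(scan, 1)
  o <- attr(retina, "origin")
  ref_stream <- interp2_bilinear(ref_field, (pat0$y - o[2]) / fine + 1,
                                 (pat0$x - o[1]) / fine + 1)
  reference <- desinusoid(ref_stream, scan)

  structure(list(frames = frames, raw_streams = raws,
                 reference_frame = reference,
                 ground_truth = list(mosaic = mosaic, trace = trace,
                                     zernike = zs %||% cfg$optics$zernike,
                                     seed = cfg$seed, config = cfg)),
            class = "frame_set")
}

frame_model <- function(cfg, frame, diffraction_limited = FALSE) {
  model <- cfg$optics
  if (diffraction_limited || !cfg$aberrations) {
    model$zernike <- NULL
    model$zernike_out <- NULL
  } else if (!is.null(cfg$zernike_series) && frame > 0) {
    zf <- dplyr::filter(cfg$zernike_series, .data$frame == !!frame)
    model$zernike <- tibble(index = zf$index, value_um = zf$value_um)
  }
  model
}

zero_trace <- function(duration, sample_rate) {
  n <- round(duration * sample_rate)
  tt <- (seq_len(n) - 1) / sample_rate
  structure(tibble(t = tt, x = 0, y = 0, event = 1L),
            events = tibble(event = 1L, kind = "drift", t_start = 0,
                            t_end = duration, amplitude = 0,
                            direction = NA_real_, tremor_cf = NA_real_,
                            tremor_bw = NA_real_, tremor_amp = NA_real_),
            sample_rate = sample_rate,
            class = c("eye_trace", class(tibble())))
}

#' @export
print.frame_set <- function(x, ...) {
  f <- x$frames[[1]]
  cat(sprintf("<frame_set> %d frame(s) of %d x %d px, %d ground-truth cones\n",
              length(x$frames), nrow(f), ncol(f),
              nrow(x$ground_truth$mosaic)))
  invisible(x)
}

#' Frame-set summary
#' @param x A `frame_set`.
#' @param ... Unused.
#' @return One-row tibble with run-level summaries.
#' @export
glance.frame_set <- function(x, ...) {
  cfg <- x$ground_truth$config
  tibble(n_frames = length(x$frames),
         n_cones = nrow(x$ground_truth$mosaic),
         eccentricity_deg = cfg$eccentricity_deg,
         fov_x_deg = cfg$scan$fov_x, fov_y_deg = cfg$scan$fov_y,
         seed = cfg$seed)
}

#' Linear intensity scaling to 8 bits with controlled saturation
#'
#' Scales a frame linearly and clips so that the requested fraction of
#' pixels saturates at 255 (matching the saturated-pixel count of real
#' detector gains, about 10 percent by default). Order-preserving below
#' saturation; invariant to multiplying the input by a constant.
#'
#' @param frame Numeric matrix.
#' @param saturation_fraction Fraction of pixels to saturate, in `[0, 1)`.
#' @return Integer matrix of values 0..255.
#' @export
intensity_scale <- function(frame, saturation_fraction = 0.10) {
  stopifnot(saturation_fraction >= 0, saturation_fraction < 1)
  v <- as.vector(frame)
  lo <- min(v)
  if (max(v) - lo < .Machine$double.eps * max(1, abs(lo))) {
    warn("constant frame: scaling to mid-grey")
    return(matrix(128L, nrow(frame), ncol(frame)))
  }
  n <- length(v)
  n_sat <- ceiling(saturation_fraction * n)
  top <- if (n_sat == 0) max(v) else sort(v, partial = n - n_sat + 1)[n - n_sat + 1]
  scaled <- round((frame - lo) / (top - lo) * 255)
  res <- pmin(pmax(scaled, 0), 255)
  res[frame < top & res == 255] <- 254   # keep the saturated count exact
  res[frame >= top] <- 255
  matrix(as.integer(res), nrow(frame), ncol(frame))
}

#' Write a frame-set bundle to a directory
#'
#' One directory per run: `config.yaml`, `mosaic.csv`, `trace.csv` (+ events
#' JSON), `zernike.csv`, per-frame 32-bit float TIFFs, raw streams as
#' `raw_streams.json`, and a `manifest.json` with content hashes.
#'
#' @param fs A `frame_set`.
#' @param dir Output directory (created if needed).
#' @export
write_dataset <- function(fs, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  gt <- fs$ground_truth
  cfg <- gt$config
  yaml::write_yaml(serialize_config(cfg), file.path(dir, "config.yaml"))
  write_cone_mosaic_csv(gt$mosaic, file.path(dir, "mosaic.csv"))
  write_eye_trace_csv(gt$trace, file.path(dir, "trace.csv"))
  if (!is.null(gt$zernike)) {
    utils::write.csv(as.data.frame(gt$zernike), file.path(dir, "zernike.csv"),
                     row.names = FALSE)
  }
  for (i in seq_along(fs$frames)) {
    f <- fs$frames[[i]]
    rng <- range(f)
    tiff::writeTIFF((f - rng[1]) / max(rng[2] - rng[1], .Machine$double.eps),
                    file.path(dir, sprintf("frame_%03d.tiff", i)),
                    bits.per.sample = 32L)
  }
  jsonlite::write_json(fs$raw_streams, file.path(dir, "raw_streams.json"),
                       digits = NA)
  files <- setdiff(list.files(dir), "manifest.json")
  manifest <- lapply(files, function(f) {
    list(file = f, bytes = file.size(file.path(dir, f)))
  })
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE)
  invisible(dir)
}

serialize_config <- function(cfg) {
  lapply(cfg, function(x) {
    if (inherits(x, "scan_config") || inherits(x, "eye_motion_params") ||
        inherits(x, "optical_model")) {
      lapply(unclass(x), function(e) if (is.data.frame(e)) as.list(e) else e)
    } else if (is.data.frame(x)) as.list(x) else x
  })
}
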