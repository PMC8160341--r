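#' Raster-scan configuration
#'
#' Describes the AOSLO raster: a sinusoidal (resonant) horizontal fast scan
#' and a sawtooth vertical slow scan with a flyback region. Only the central
#' monotone portion of the sine (the `duty` fraction of the forward sweep)
#' maps to image columns, as in real systems. The frame rate is derived as
#' `line_rate * (1 - flyback_fraction) / n_lines`.
#'
#' @param fov_x,fov_y Field of view (degrees). Fields beyond 2 degrees are
#'   flagged with an anisoplanatism advisory (a single PSF no longer
#'   represents the whole field well).
#' @param n_lines Lines per frame.
#' @param samples_per_line Samples digitised per line.
#' @param line_rate Fast-scanner line rate (Hz).
#' @param flyback_fraction Fraction of the frame period spent in slow-scan
#'   flyback (no imaging samples).
#' @param duty Fraction of the forward fast-scan sweep used for imaging.
#' @param fast_scan `"sinusoidal"` (default) or `"linear"` (idealised scanner;
#'   desinusoiding becomes the identity).
#' @param phase Static phase offset of the fast scan (radians); a non-zero
#'   value emulates desinusoiding calibration error when it differs between
#'   generation and [desinusoid()].
#' @return A `scan_config` list (includes the derived `frame_rate`).
#' @export
scan_config <- function(fov_x = 1, fov_y = 1, n_lines = 512,
                        samples_per_line = 512, line_rate = 15600,
                        flyback_fraction = 0.05, duty = 0.8,
                        fast_scan = c("sinusoidal", "linear"), phase = 0) {
  fast_scan <- match.arg(fast_scan)
  stopifnot(fov_x > 0, fov_y > 0, n_lines >= 1, samples_per_line >= 2,
            line_rate > 0, flyback_fraction >= 0, flyback_fraction < 1,
            duty > 0, duty <= 1)
  if (max(fov_x, fov_y) > 2) {
    warn("field of view exceeds 2 degrees: a single isoplanatic PSF is a coarse approximation")
  }
  cfg <- as.list(environment())
  cfg$frame_rate <- line_rate * (1 - flyback_fraction) / n_lines
  structure(cfg, class = "scan_config")
}

# Fast-scan position across a line as a function of within-line phase
# u in [-1, 1] (u = 0 at line centre). Returns position in deg.
fast_scan_position <- function(cfg, u) {
  if (cfg$fast_scan == "linear") {
    u * cfg$fov_x / 2
  } else {
    (cfg$fov_x / 2) * sin(u * cfg$duty * pi / 2 + cfg$phase) /
      sin(cfg$duty * pi / 2)
  }
}

#' Build the spatio-temporal raster sampling pattern
#'
#' Per-sample beam positions for `n_frames` frames with no eye motion.
#' Within each line, samples are uniform in time over the imaging (duty)
#' window of the sinusoidal sweep, so `x(t) = (fov_x/2) sin(2 pi line_rate t
#' + phase)` up to normalisation to the full field width; the slow scan is a
#' continuous sawtooth spanning `fov_y` over the active frame period, with
#' flyback excluded from imaging samples. The pattern is periodic with the
#' frame period.
#'
#' @param cfg A [scan_config()].
#' @param n_frames Number of frames.
#' @return A `scan_pattern` tibble: `frame`, `line`, `sample`, `t` (s),
#'   `x`, `y` (beam position, arcmin), with attribute `config`.
#' @export
build_scan_pattern <- function(cfg, n_frames = 1) {
  stopifnot(inherits(cfg, "scan_config"), n_frames >= 1)
  S <- cfg$samples_per_line; L <- cfg$n_lines
  t_frame <- 1 / cfg$frame_rate
  t_active <- (1 - cfg$flyback_fraction) * t_frame
  t_line <- 1 / cfg$line_rate
  # within-line phase u in (-1, 1), uniform in time across the duty window
  u <- ((seq_len(S) - 0.5) / S) * 2 - 1
  x_line <- 60 * fast_scan_position(cfg, u)
  t_in_line <- (u * cfg$duty / 2 + 0.5) * t_line
  grid <- tidyr::expand_grid(frame = seq_len(n_frames), line = seq_len(L),
                             sample = seq_len(S))
  t_line_start <- (grid$line - 1) * t_line
  t <- (grid$frame - 1) * t_frame + t_line_start + t_in_line[grid$sample]
  # slow scan: sawtooth over the active period, constant within a line
  y <- 60 * cfg$fov_y * ((t_line_start + t_line / 2) / t_active - 0.5)
  structure(tibble(frame = grid$frame, line = grid$line, sample = grid$sample,
                   t = t, x = x_line[grid$sample], y = y),
            config = cfg,
            class = c("scan_pattern", class(tibble())))
}

#' Add eye motion to a scan pattern
#'
#' Beam position on the retina = scan position + linearly interpolated eye
#' displacement at each sample time. A zero trace leaves the pattern
#' unchanged.
#'
#' @param pattern A `scan_pattern` from [build_scan_pattern()].
#' @param trace An `eye_trace` covering the pattern's time span.
#' @return The pattern with displaced `x`, `y` (and the trace attached).
#' @export
combine_motion <- function(pattern, trace) {
  tmax <- max(pattern$t)
  trace_end <- max(trace$t) + 1 / attr(trace, "sample_rate")
  if (tmax > trace_end + 1e-12) {
    abort("eye trace is shorter than the scan pattern's time span")
  }
  ex <- approx(trace$t, trace$x, xout = pattern$t, rule = 2)$y
  ey <- approx(trace$t, trace$y, xout = pattern$t, rule = 2)$y
  pattern$x <- pattern$x + ex
  pattern$y <- pattern$y + ey
  attr(pattern, "trace") <- trace
  pattern
}

#' Desinusoid a raw sample stream into a frame
#'
#' Each line of the raw stream was sampled uniformly in time through the
#' sinusoidal fast scan, so it is non-uniform in space. Desinusoiding
#' resamples each line onto a spatially uniform grid by (cubic spline)
#' interpolation against the sine position, exactly as applied to real
#' detector streams. With a linear scan the operation is the identity (up to
#' resampling onto `out_width` columns).
#'
#' @param stream Numeric vector of length `n_lines * samples_per_line`
#'   (one frame, line-major) or a matrix with `n_lines` rows.
#' @param cfg The [scan_config()] describing the sine used for resampling
#'   (which may deliberately differ from the one used for generation, to
#'   emulate calibration errors).
#' @param out_width Output columns (defaults to `samples_per_line`).
#' @return `n_lines x out_width` matrix.
#' @export
desinusoid <- function(stream, cfg, out_width = cfg$samples_per_line) {
  S <- cfg$samples_per_line; L <- cfg$n_lines
  if (is.matrix(stream)) {
    if (ncol(stream) != S) abort("stream has wrong samples_per_line")
    m <- stream
    L <- nrow(stream)
  } else {
    if (length(stream) != L * S) {
      abort(sprintf("stream length %d != n_lines * samples_per_line = %d",
                    length(stream), L * S))
    }
    m <- matrix(stream, nrow = L, byrow = TRUE)
  }
  u <- ((seq_len(S) - 0.5) / S) * 2 - 1
  src <- fast_scan_position(cfg, u)          # deg, non-uniform
  dst <- seq(min(src), max(src), length.out = out_width)
  if (cfg$fast_scan == "linear" && out_width == S) return(m)
  out <- matrix(0, L, out_width)
  for (l in seq_len(L)) {
    out[l, ] <- splinefun(src, m[l, ], method = "natural")(dst)
  }
  out
}
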