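#' Fixational eye-movement parameters
#'
#' Parameter set for the three classes of fixational eye movement.
#' Microsaccade amplitudes, inter-microsaccade intervals, tremor centre
#' frequency, bandwidth and amplitude, and drift amplitude are each drawn
#' per event from normal distributions; the defaults are
#' amplitude N(30, 3) arcmin, interval N(1.0, 0.5) s, tremor centre
#' frequency N(65, 7.5) Hz, tremor bandwidth N(25, 2.5) Hz, tremor
#' amplitude N(0.08, 0.03) arcmin and drift amplitude N(6.5, 0.7) arcmin.
#'
#' Intervals are redrawn when they fall outside a symmetric window
#' `[min_interval, 2 * mean - min_interval]`, which enforces the minimum
#' separation between microsaccades while preserving the configured mean.
#'
#' @param ms_amp_mean,ms_amp_sd Microsaccade amplitude distribution (arcmin).
#' @param ms_interval_mean,ms_interval_sd Inter-microsaccade interval (s).
#' @param tremor_cf_mean,tremor_cf_sd Tremor centre frequency (Hz).
#' @param tremor_bw_mean,tremor_bw_sd Tremor bandwidth, Gaussian FWHM (Hz).
#' @param tremor_amp_mean,tremor_amp_sd Tremor amplitude, segment RMS (arcmin).
#' @param drift_amp_mean,drift_amp_sd Drift amplitude, peak displacement of a
#'   segment from its start (arcmin).
#' @param sample_rate Trace sample rate (Hz).
#' @param bounds Containment radius (arcmin); microsaccades become
#'   centre-seeking whenever gaze exceeds half this radius.
#' @param min_interval Minimum inter-microsaccade interval (s).
#' @param main_sequence_slope Slope `m` of the main sequence
#'   `log(v_peak) = log(c) + m log(amplitude)`.
#' @param main_sequence_rate Constant `c` (per second): peak velocity of a
#'   unit-amplitude (1 arcmin) microsaccade, arcmin/s.
#' @param centering_jitter_deg Angular jitter (degrees, sd) added to the
#'   centre-ward direction of corrective microsaccades.
#' @return An `eye_motion_params` list.
#' @export
eye_motion_params <- function(ms_amp_mean = 30, ms_amp_sd = 3,
                              ms_interval_mean = 1.0, ms_interval_sd = 0.5,
                              tremor_cf_mean = 65, tremor_cf_sd = 7.5,
                              tremor_bw_mean = 25, tremor_bw_sd = 2.5,
                              tremor_amp_mean = 0.08, tremor_amp_sd = 0.03,
                              drift_amp_mean = 6.5, drift_amp_sd = 0.7,
                              sample_rate = 1000, bounds = 60,
                              min_interval = 0.2,
                              main_sequence_slope = 1,
                              main_sequence_rate = 70,
                              centering_jitter_deg = 15) {
  p <- as.list(environment())
  sds <- p[grepl("_sd$", names(p))]
  if (any(unlist(sds) < 0)) abort("all standard deviations must be >= 0")
  if (p$sample_rate <= 0 || p$bounds <= 0) abort("sample_rate and bounds must be positive")
  if (p$bounds < p$ms_amp_mean) {
    warn("containment bounds smaller than the mean microsaccade amplitude")
  }
  structure(p, class = "eye_motion_params")
}

# Event-parameter draws (exposed so parameter-recovery studies can sample
# the generative distributions directly).

#' Draw per-event fixational parameters
#'
#' Draws the event-level parameters used by [generate_eye_trace()]:
#' tremor centre frequency, bandwidth and amplitude, and drift amplitude,
#' one row per drift period. All draws are truncated at zero (redrawn).
#'
#' @param n Number of draws.
#' @param params An [eye_motion_params()] object.
#' @param seed Optional RNG seed.
#' @return Tibble with columns `tremor_cf`, `tremor_bw`, `tremor_amp`,
#'   `drift_amp`.
#' @export
draw_drift_period_params <- function(n, params = eye_motion_params(),
                                     seed = NULL) {
  with_seed_if(seed, tibble(
    tremor_cf = rnorm_trunc(n, params$tremor_cf_mean, params$tremor_cf_sd),
    tremor_bw = rnorm_trunc(n, params$tremor_bw_mean, params$tremor_bw_sd),
    tremor_amp = rnorm_trunc(n, params$tremor_amp_mean, params$tremor_amp_sd),
    drift_amp = rnorm_trunc(n, params$drift_amp_mean, params$drift_amp_sd)
  ))
}

#' Sample a single microsaccade event
#'
#' Amplitude is drawn from the (truncated) normal amplitude distribution;
#' peak velocity follows the main sequence
#' `v_peak = c * amplitude^m` (proportionality in log-log coordinates);
#' the velocity profile is a raised cosine, so displacement along the
#' saccade direction is smooth and monotone with zero velocity at both ends.
#' Direction is uniform unless `position` exceeds half the containment
#' bounds, in which case it points centre-ward with Gaussian jitter.
#'
#' @param params An [eye_motion_params()].
#' @param position Current gaze position `c(x, y)` (arcmin).
#' @param seed Optional RNG seed.
#' @return List with `amplitude` (arcmin), `direction` (radians),
#'   `v_peak` (arcmin/s), `duration` (s) and `displacement(tau)`, a function
#'   returning the along-direction displacement at time `tau` from onset.
#' @export
sample_microsaccade <- function(params = eye_motion_params(),
                                position = c(0, 0), seed = NULL) {
  with_seed_if(seed, {
    a <- rnorm_trunc(1, params$ms_amp_mean, params$ms_amp_sd)
    if (sqrt(sum(position^2)) > params$bounds / 2) {
      dir <- atan2(-position[2], -position[1]) +
        rnorm(1, 0, params$centering_jitter_deg * pi / 180)
    } else {
      dir <- runif(1, 0, 2 * pi)
    }
    v_peak <- params$main_sequence_rate * a^params$main_sequence_slope
    # raised-cosine velocity: mean velocity = v_peak / 2; degenerate
    # zero-amplitude events keep a nominal duration
    dur <- if (a > 0) 2 * a / v_peak else 0.02
    list(
      amplitude = a, direction = dir, v_peak = v_peak, duration = dur,
      displacement = function(tau) {
        if (a == 0) return(rep(0, length(tau)))
        tau <- pmin(pmax(tau, 0), dur)
        a * (tau / dur - sin(2 * pi * tau / dur) / (2 * pi))
      }
    )
  })
}

#' Generate a drift segment with a 1/f^2 displacement spectrum
#'
#' Each axis is synthesised from random spectral phases with amplitude
#' proportional to 1/f (power 1/f^2), then the two-axis segment is rescaled
#' so its peak displacement from the starting point equals `amplitude`.
#' The segment starts at (0, 0).
#'
#' @param duration Segment duration (s), > 2 samples.
#' @param amplitude Peak displacement (arcmin).
#' @param sample_rate Hz.
#' @param seed Optional RNG seed.
#' @return Tibble `t`, `x`, `y`.
#' @export
generate_drift <- function(duration, amplitude, sample_rate = 1000,
                           seed = NULL) {
  n <- round(duration * sample_rate)
  if (n < 2) abort("drift duration must cover at least 2 samples")
  with_seed_if(seed, {
    one_axis <- function() {
      nf <- n %/% 2
      amp <- c(0, 1 / seq_len(nf))
      ph <- runif(nf + 1, 0, 2 * pi)
      spec <- complex(modulus = amp, argument = ph)
      full <- c(spec, Conj(rev(spec[2:(n - nf)])))
      x <- Re(fft(full, inverse = TRUE)) / n
      x - x[1]
    }
    x <- one_axis(); y <- one_axis()
    if (amplitude == 0) {
      x <- numeric(n); y <- numeric(n)
    } else {
      peak <- max(sqrt(x^2 + y^2))
      if (peak > 0) { x <- x * amplitude / peak; y <- y * amplitude / peak }
    }
    tibble(t = (seq_len(n) - 1) / sample_rate, x = x, y = y)
  })
}

#' Generate a tremor segment (Gaussian band-pass filtered noise)
#'
#' White noise on each axis is filtered with a Gaussian magnitude profile
#' centred at `cf` with FWHM bandwidth `bw`, then the segment is rescaled so
#' the RMS of the radial displacement equals `amplitude`.
#'
#' @param duration Segment duration (s).
#' @param cf Centre frequency (Hz); `cf + bw/2` must be below Nyquist.
#' @param bw Bandwidth (FWHM, Hz).
#' @param amplitude RMS amplitude (arcmin).
#' @param sample_rate Hz.
#' @param seed Optional RNG seed.
#' @return Tibble `t`, `x`, `y`.
#' @export
generate_tremor <- function(duration, cf = 65, bw = 25, amplitude = 0.08,
                            sample_rate = 1000, seed = NULL) {
  n <- round(duration * sample_rate)
  if (n < 2) abort("tremor duration must cover at least 2 samples")
  if (cf + bw / 2 >= sample_rate / 2) {
    abort("tremor band exceeds the Nyquist frequency of the sample rate")
  }
  with_seed_if(seed, {
    f <- c(0:(n %/% 2), -((n - n %/% 2 - 1):1)) * sample_rate / n
    sig_f <- bw / (2 * sqrt(2 * log(2)))
    h <- exp(-(abs(f) - cf)^2 / (2 * sig_f^2))
    one_axis <- function() Re(fft(fft(rnorm(n)) * h, inverse = TRUE)) / n
    x <- one_axis(); y <- one_axis()
    if (amplitude == 0) {
      x <- numeric(n); y <- numeric(n)
    } else {
      r <- sqrt(mean(x^2 + y^2))
      if (r > 0) { x <- x * amplitude / r; y <- y * amplitude / r }
    }
    tibble(t = (seq_len(n) - 1) / sample_rate, x = x, y = y)
  })
}

#' Generate a fixational eye-movement trace with event ground truth
#'
#' Microsaccade onsets are pre-determined by drawing inter-event intervals
#' from the interval distribution; between microsaccades, gaze follows
#' drift (1/f^2) with superimposed tremor; microsaccade directions become
#' centre-seeking whenever gaze strays beyond half the containment bounds,
#' so the trace maintains a locus about the centre of the mosaic. The trace
#' is continuous across segment boundaries.
#'
#' @param duration Trace duration (s).
#' @param params An [eye_motion_params()].
#' @param seed Optional RNG seed.
#' @return An `eye_trace`: tibble with `t` (s), `x`, `y` (arcmin) and
#'   `event` (integer id into the event table), with attributes
#'   `events` (tibble: `event`, `kind` ("drift" or "microsaccade"),
#'   `t_start`, `t_end`, `amplitude`, `direction`, `tremor_cf`, `tremor_bw`,
#'   `tremor_amp`) and `sample_rate`.
#' @export
generate_eye_trace <- function(duration, params = eye_motion_params(),
                               seed = NULL) {
  stopifnot(duration > 0)
  with_seed_if(seed, {
    rate <- params$sample_rate
    dt <- 1 / rate
    n <- round(duration * rate)
    tt <- (seq_len(n) - 1) * dt

    # microsaccade onset times
    onsets <- numeric(0)
    t_next <- draw_interval(params)
    while (t_next < duration) {
      onsets <- c(onsets, t_next)
      t_next <- t_next + draw_interval(params)
    }

    x <- numeric(n); y <- numeric(n); ev <- integer(n)
    events <- list()
    pos <- c(0, 0)
    cursor <- 1L   # next sample index to fill
    eid <- 0L

    fill_drift <- function(i0, i1) {
      len <- i1 - i0 + 1L
      pp <- draw_drift_period_params(1, params)
      seg_dur <- len * dt
      if (len >= 2) {
        d <- generate_drift(seg_dur, pp$drift_amp, rate)
        tr <- generate_tremor(seg_dur, pp$tremor_cf, pp$tremor_bw,
                              pp$tremor_amp, rate)
        segx <- d$x[seq_len(len)] + tr$x[seq_len(len)]
        segy <- d$y[seq_len(len)] + tr$y[seq_len(len)]
      } else {
        segx <- 0; segy <- 0
      }
      eid <<- eid + 1L
      x[i0:i1] <<- pos[1] + segx
      y[i0:i1] <<- pos[2] + segy
      ev[i0:i1] <<- eid
      pos <<- c(x[i1], y[i1])
      events[[eid]] <<- tibble(
        event = eid, kind = "drift",
        t_start = tt[i0], t_end = tt[i1] + dt,
        amplitude = pp$drift_amp, direction = NA_real_,
        tremor_cf = pp$tremor_cf, tremor_bw = pp$tremor_bw,
        tremor_amp = pp$tremor_amp
      )
    }

    for (on in onsets) {
      i_on <- min(n, floor(on / dt) + 1L)
      if (i_on > cursor) {
        fill_drift(cursor, i_on - 1L)
        cursor <- i_on
      }
      ms <- sample_microsaccade(params, pos)
      n_ms <- max(1L, ceiling(ms$duration / dt))
      i_end <- min(n, cursor + n_ms - 1L)
      tau <- (seq_len(i_end - cursor + 1L)) * dt
      s <- ms$displacement(tau)
      eid <- eid + 1L
      x[cursor:i_end] <- pos[1] + s * cos(ms$direction)
      y[cursor:i_end] <- pos[2] + s * sin(ms$direction)
      ev[cursor:i_end] <- eid
      events[[eid]] <- tibble(
        event = eid, kind = "microsaccade",
        t_start = tt[cursor], t_end = tt[i_end] + dt,
        amplitude = ms$amplitude, direction = ms$direction,
        tremor_cf = NA_real_, tremor_bw = NA_real_, tremor_amp = NA_real_
      )
      pos <- c(x[i_end], y[i_end])
      cursor <- i_end + 1L
      if (cursor > n) break
    }
    if (cursor <= n) fill_drift(cursor, n)

    structure(tibble(t = tt, x = x, y = y, event = ev),
              events = bind_rows(events), sample_rate = rate,
              params = params,
              class = c("eye_trace", class(tibble())))
  })
}

draw_interval <- function(params) {
  m <- params$ms_interval_mean
  lo <- params$min_interval
  if (m <= lo) return(m)
  rnorm_trunc(1, m, params$ms_interval_sd, lower = lo, upper = 2 * m - lo)
}

#' Event table of an eye trace
#' @param x An `eye_trace`.
#' @param ... Unused.
#' @return The labelled event tibble (see [generate_eye_trace()]).
#' @export
tidy.eye_trace <- function(x, ...) attr(x, "events")

#' Write an eye trace to CSV (+ events JSON)
#'
#' The trace (`t`, `x`, `y`, `event_kind`) goes to `path`; the event table
#' goes to `<path stem>_events.json`.
#'
#' @param trace An `eye_trace`.
#' @param path CSV path.
#' @export
write_eye_trace_csv <- function(trace, path) {
  events <- tidy(trace)
  kind <- events$kind[match(trace$event, events$event)]
  utils::write.csv(data.frame(t = trace$t, x = trace$x, y = trace$y,
                              event_kind = kind),
                   path, row.names = FALSE)
  jsonlite::write_json(events, sub("\\.csv$", "_events.json", path),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}
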