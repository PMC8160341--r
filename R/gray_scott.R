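#' Initialise a Gray-Scott reaction-diffusion state
#'
#' The Gray-Scott system models two chemicals U and V that diffuse and react
#' (U + 2V -> 3V, V -> P). With suitable coefficients the V concentration
#' self-organises into a pseudo-hexagonal pattern of round spots, which this
#' package uses as cone photoreceptor positions. The default coefficients
#' (`du = 0.14`, `dv = 0.06`, `f = 0.035`, `k = 0.065`) produce spots; as a
#' rule of thumb spots remain round while `du` is at least twice `dv`.
#'
#' The field is seeded at `u = 1`, `v = 0` (a fixed point of the dynamics)
#' with a small central square perturbation plus low-amplitude uniform noise,
#' so that the pattern grows outward from the centre.
#'
#' @param n Grid side length (pixels); the grid is `n x n`.
#' @param du Diffusion coefficient of U.
#' @param dv Diffusion coefficient of V; a scalar, or an `n x n` matrix for
#'   spatially varying diffusion (a radially increasing `dv` yields a
#'   foveated mosaic whose spot spacing grows with radius).
#' @param f Feed rate of U.
#' @param k Kill rate of V.
#' @param dt Euler time step.
#' @param seed_halfwidth Half-width (pixels) of the central seeded square.
#' @param seed_noise Amplitude of the uniform noise added inside the seed.
#' @param boundary `"periodic"` (default) or `"neumann"` (zero flux);
#'   foveated runs should use `"neumann"` so the pattern is not toroidal.
#' @param seed Optional RNG seed for the seeding noise.
#' @return An object of class `gs_state`: list with matrices `u`, `v`, the
#'   coefficients, and the elapsed step count `t`.
#' @export
#' @examples
#' st <- gs_state(n = 64, seed = 1)
#' st <- step_gray_scott(st, 200)
gs_state <- function(n = 300, du = 0.14, dv = 0.06, f = 0.035, k = 0.065,
                     dt = 1, seed_halfwidth = 5, seed_noise = 0.02,
                     boundary = c("periodic", "neumann"), seed = NULL) {
  boundary <- match.arg(boundary)
  stopifnot(n >= 8, du > 0, all(dv > 0), f >= 0, k >= 0, dt > 0)
  if (is.matrix(dv)) stopifnot(nrow(dv) == n, ncol(dv) == n)
  if (du < 2 * max(dv)) {
    warn("du is less than twice max(dv); spot patterns may not form")
  }
  u <- matrix(1, n, n)
  v <- matrix(0, n, n)
  c0 <- (n + 1) / 2
  idx <- max(1, round(c0 - seed_halfwidth)):min(n, round(c0 + seed_halfwidth))
  with_seed_if(seed, {
    u[idx, idx] <- 0.5 + runif(length(idx)^2, -seed_noise, seed_noise)
    v[idx, idx] <- 0.25 + runif(length(idx)^2, -seed_noise, seed_noise)
  })
  structure(list(u = u, v = v, du = du, dv = dv, f = f, k = k, dt = dt,
                 boundary = boundary, t = 0L),
            class = "gs_state")
}

#' Advance a Gray-Scott state by explicit Euler steps
#'
#' Integrates du/dt = Du lap(u) - u v^2 + f(1-u) and
#' dv/dt = Dv lap(v) + u v^2 - (f+k) v with a 5-point Laplacian.
#' Divergent coefficient choices raise an "unstable coefficients" error
#' naming the step at which non-finite values appeared.
#'
#' @param state A `gs_state`.
#' @param n_steps Number of Euler steps (>= 1).
#' @return The advanced `gs_state`.
#' @export
step_gray_scott <- function(state, n_steps) {
  stopifnot(inherits(state, "gs_state"), n_steps >= 1)
  dv <- if (is.matrix(state$dv)) state$dv else matrix(state$dv, 1, 1)
  res <- .gs_advance(state$u, state$v, state$du, dv, state$f, state$k,
                     state$dt, as.integer(n_steps),
                     identical(state$boundary, "periodic"),
                     check_every = 200L, t0 = state$t)
  state$u <- res$u
  state$v <- res$v
  state$t <- as.integer(res$t)
  state
}

#' Detect spot centres in a concentration field
#'
#' Applies local-maximum peak detection to the final V concentration of a
#' stable spot pattern. A pixel is a peak if it is the strict maximum of its
#' 3x3 neighbourhood and exceeds a relative threshold between the field
#' minimum and maximum. Peak positions are refined to sub-pixel accuracy by
#' a separable quadratic fit unless `subpixel = FALSE`.
#'
#' @param v_field Matrix (e.g. `state$v` after [step_gray_scott()]).
#' Shallow or still-forming spots can carry twin local maxima; peaks closer
#' than `min_distance` (default: half the median nearest-neighbour distance)
#' are merged to their midpoint.
#'
#' @param threshold_rel Relative threshold in (0, 1).
#' @param subpixel Refine peak positions by quadratic interpolation.
#' @param min_distance Merge radius in pixels, or `NULL` for the adaptive
#'   default; `0` disables merging.
#' @return Tibble with columns `x` (column coordinate) and `y` (row
#'   coordinate), in pixels; centres lie strictly inside the field.
#' @export
detect_cone_centres <- function(v_field, threshold_rel = 0.3, subpixel = TRUE,
                                min_distance = NULL) {
  stopifnot(is.matrix(v_field), all(is.finite(v_field)))
  nr <- nrow(v_field); nc <- ncol(v_field)
  thr <- min(v_field) + threshold_rel * (max(v_field) - min(v_field))
  inner <- v_field[2:(nr - 1), 2:(nc - 1)]
  sh <- function(dr, dc) v_field[2:(nr - 1) + dr, 2:(nc - 1) + dc]
  is_peak <- inner > thr &
    inner > sh(-1, 0) & inner >= sh(1, 0) &
    inner > sh(0, -1) & inner >= sh(0, 1) &
    inner > sh(-1, -1) & inner >= sh(1, 1) &
    inner > sh(-1, 1) & inner >= sh(1, -1)
  idx <- which(is_peak, arr.ind = TRUE)
  if (nrow(idx) == 0) {
    abort("no mosaic formed: no peaks detected (unstable or failed pattern)")
  }
  r <- idx[, 1] + 1L
  c <- idx[, 2] + 1L
  y <- as.numeric(r); x <- as.numeric(c)
  if (subpixel) {
    # separable quadratic vertex: offset = (f(-1) - f(+1)) / (2 (f(-1) - 2 f(0) + f(+1)))
    f0 <- v_field[cbind(r, c)]
    dy_den <- v_field[cbind(r - 1, c)] - 2 * f0 + v_field[cbind(r + 1, c)]
    dx_den <- v_field[cbind(r, c - 1)] - 2 * f0 + v_field[cbind(r, c + 1)]
    dy <- ifelse(dy_den < 0, (v_field[cbind(r - 1, c)] - v_field[cbind(r + 1, c)]) / (2 * dy_den), 0)
    dx <- ifelse(dx_den < 0, (v_field[cbind(r, c - 1)] - v_field[cbind(r, c + 1)]) / (2 * dx_den), 0)
    y <- y + pmin(pmax(dy, -0.5), 0.5)
    x <- x + pmin(pmax(dx, -0.5), 0.5)
  }
  merge_close_peaks(tibble(x = x, y = y), min_distance)
}

merge_close_peaks <- function(centres, min_distance) {
  if (nrow(centres) < 2) return(centres)
  xy <- cbind(centres$x, centres$y)
  if (is.null(min_distance)) {
    d <- as.matrix(stats::dist(xy)); diag(d) <- Inf
    min_distance <- 0.5 * stats::median(apply(d, 1, min))
  }
  if (min_distance <= 0) return(centres)
  repeat {
    d <- as.matrix(stats::dist(xy)); diag(d) <- Inf
    if (min(d) >= min_distance) break
    pair <- which(d == min(d), arr.ind = TRUE)[1, ]
    xy[pair[1], ] <- colMeans(xy[pair, , drop = FALSE])
    xy <- xy[-pair[2], , drop = FALSE]
  }
  tibble(x = xy[, 1], y = xy[, 2])
}

#' Generate cone positions by reaction-diffusion
#'
#' Convenience pipeline: seed a Gray-Scott state, integrate, detect spot
#' centres, and crop to the interior of the grid (the pattern is generated
#' over an extended bounding box and only the central fraction is kept, so
#' the returned positions are free of boundary effects and of the unseeded
#' margin of short runs).
#'
#' @inheritParams gs_state
#' @param n_steps Number of Euler steps (20000 with the default coefficients
#'   gives a stable spot pattern on a 300 x 300 grid).
#' @param crop_fraction Central fraction of the grid to keep.
#' @param ... Passed to [gs_state()].
#' @return Tibble of centres (`x`, `y`, pixels, cropped region only).
#' @export
rd_cone_positions <- function(n = 300, n_steps = 20000, crop_fraction = 0.8,
                              seed = NULL, ...) {
  st <- gs_state(n = n, seed = seed, ...)
  st <- step_gray_scott(st, n_steps)
  centres <- detect_cone_centres(st$v)
  half <- crop_fraction * n / 2
  c0 <- (n + 1) / 2
  dplyr::filter(centres,
                abs(.data$x - c0) <= half,
                abs(.data$y - c0) <= half)
}
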