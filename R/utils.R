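# Internal numerical helpers shared across modules.

# Draw from Normal(mean, sd) restricted to [lower, upper] by redrawing.
# With a symmetric window about the mean the configured mean is preserved.
rnorm_trunc <- function(n, mean, sd, lower = 0, upper = Inf) {
  if (sd == 0) return(rep(mean, n))
  x <- rnorm(n, mean, sd)
  bad <- which(x <= lower | x >= upper)
  guard <- 0L
  while (length(bad) > 0) {
    x[bad] <- rnorm(length(bad), mean, sd)
    bad <- bad[x[bad] <= lower | x[bad] >= upper]
    guard <- guard + 1L
    if (guard > 10000L) abort("truncated-normal rejection sampling failed to converge")
  }
  x
}

# DFT index shifts (match numpy fftshift/ifftshift, including odd sizes).
fftshift2 <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  m[c(seq(nr - nr %/% 2 + 1, nr), seq_len(nr - nr %/% 2)),
    c(seq(nc - nc %/% 2 + 1, nc), seq_len(nc - nc %/% 2)), drop = FALSE]
}

ifftshift2 <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  m[c(seq(nr %/% 2 + 1, nr), seq_len(nr %/% 2)),
    c(seq(nc %/% 2 + 1, nc), seq_len(nc %/% 2)), drop = FALSE]
}

# Cross-correlation of image with an odd-sized kernel, same-size output,
# zero padding outside the image. corr(I, K)(x) = sum_u I(x + u) K(u), with
# the kernel origin at its centre pixel.
xcorr2 <- function(image, kernel) {
  nr <- nrow(image); nc <- ncol(image)
  kr <- nrow(kernel); kc <- ncol(kernel)
  stopifnot(kr %% 2 == 1, kc %% 2 == 1)
  pr <- nr + kr - 1; pc <- nc + kc - 1
  ip <- matrix(0, pr, pc); ip[seq_len(nr), seq_len(nc)] <- image
  kp <- matrix(0, pr, pc)
  # place flipped kernel for correlation-as-convolution
  kf <- kernel[kr:1, kc:1, drop = FALSE]
  kp[seq_len(kr), seq_len(kc)] <- kf
  out <- Re(fft(fft(ip) * fft(kp), inverse = TRUE)) / (pr * pc)
  hr <- (kr - 1) %/% 2; hc <- (kc - 1) %/% 2
  # full correlation starts at lag -(k-1); same-size block offset is k-1-h
  out[(kr - hr):(kr - hr + nr - 1), (kc - hc):(kc - hc + nc - 1), drop = FALSE]
}

# Bilinear interpolation of matrix z at continuous (row, col) positions
# (1-based pixel-centre coordinates). Positions must lie inside the grid.
interp2_bilinear <- function(z, row, col) {
  nr <- nrow(z); nc <- ncol(z)
  if (any(row < 1 - 1e-9) || any(row > nr + 1e-9) ||
      any(col < 1 - 1e-9) || any(col > nc + 1e-9)) {
    abort("interpolation positions fall outside the image grid")
  }
  row <- pmin(pmax(row, 1), nr); col <- pmin(pmax(col, 1), nc)
  r0 <- pmin(floor(row), nr - 1); c0 <- pmin(floor(col), nc - 1)
  fr <- row - r0; fc <- col - c0
  z00 <- z[cbind(r0, c0)];     z10 <- z[cbind(r0 + 1, c0)]
  z01 <- z[cbind(r0, c0 + 1)]; z11 <- z[cbind(r0 + 1, c0 + 1)]
  (1 - fr) * (1 - fc) * z00 + fr * (1 - fc) * z10 +
    (1 - fr) * fc * z01 + fr * fc * z11
}

hann2 <- function(nr, nc = nr) {
  wr <- 0.5 - 0.5 * cos(2 * pi * (seq_len(nr) - 1) / (nr - 1))
  wc <- 0.5 - 0.5 * cos(2 * pi * (seq_len(nc) - 1) / (nc - 1))
  outer(wr, wc)
}

# Smooth Gaussian random field sampled at arbitrary positions: white noise on
# a coarse grid, Gaussian-kernel smoothing by FFT, bilinear interpolation.
smooth_random_field <- function(x, y, correlation_length, pad = 3) {
  stopifnot(correlation_length > 0)
  h <- correlation_length / 4            # grid pitch: 4 nodes per corr length
  x0 <- min(x) - pad * correlation_length
  y0 <- min(y) - pad * correlation_length
  nx <- max(8, ceiling((max(x) - x0 + pad * correlation_length) / h))
  ny <- max(8, ceiling((max(y) - y0 + pad * correlation_length) / h))
  z <- matrix(rnorm(ny * nx), ny, nx)
  sig <- correlation_length / h
  fy <- c(0:(ny %/% 2), -((ny - ny %/% 2 - 1):1)) / ny
  fx <- c(0:(nx %/% 2), -((nx - nx %/% 2 - 1):1)) / nx
  g <- outer(exp(-2 * (pi * sig * fy)^2), exp(-2 * (pi * sig * fx)^2))
  zs <- Re(fft(fft(z) * g, inverse = TRUE)) / (ny * nx)
  zs <- zs / stats::sd(as.vector(zs))
  interp2_bilinear(zs, (y - y0) / h + 1, (x - x0) / h + 1)
}

# Accept positions as a matrix, a data frame with x/y, or a cone mosaic with
# mu_x/mu_y; return a two-column matrix (x, y).
as_positions <- function(positions) {
  if (is.matrix(positions)) {
    stopifnot(ncol(positions) == 2)
    return(unname(positions))
  }
  if (is.data.frame(positions)) {
    if (all(c("mu_x", "mu_y") %in% names(positions))) {
      return(cbind(positions$mu_x, positions$mu_y))
    }
    if (all(c("x", "y") %in% names(positions))) {
      return(cbind(positions$x, positions$y))
    }
  }
  abort("positions must be a two-column matrix or a data frame with x/y or mu_x/mu_y columns")
}

with_seed_if <- function(seed, code) {
  if (is.null(seed)) code else withr::with_seed(seed, code)
}
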