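# Packing-regularity metrics and radially averaged power spectra.

# Voronoi/Delaunay adjacency from deldir. Strict adjacency: two cones are
# neighbours only if their Voronoi cells share an edge of positive length
# (this gives 4, not 8, neighbours on a square lattice where the diagonal
# circumcircles are degenerate). Border cells are those whose Voronoi cell
# is clipped by the enclosing window.
voronoi_structure <- function(positions, eps = 1e-9) {
  xy <- as_positions(positions)
  n <- nrow(xy)
  if (n < 4) abort("at least 4 positions are required")
  dd <- tryCatch(
    deldir::deldir(xy[, 1], xy[, 2],
                   rw = c(range(xy[, 1]) + c(-1, 1) * 0.05 * diff(range(xy[, 1])),
                          range(xy[, 2]) + c(-1, 1) * 0.05 * diff(range(xy[, 2])))),
    error = function(e) abort(paste0("degenerate geometry: ", conditionMessage(e)))
  )
  ds <- dd$dirsgs
  len <- sqrt((ds$x1 - ds$x2)^2 + (ds$y1 - ds$y2)^2)
  keep <- len > eps * max(1, stats::median(len))
  adj <- vector("list", n)
  for (i in seq_len(nrow(ds))) {
    if (!keep[i]) next
    a <- ds$ind1[i]; b <- ds$ind2[i]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  # Border cells: Voronoi cell clipped by the window, or reaching outside the
  # convex hull of the points (such cells are incomplete: some of their true
  # neighbours are missing from the data).
  border <- rep(FALSE, n)
  hull <- xy[grDevices::chull(xy), , drop = FALSE]
  scale <- max(diff(range(xy[, 1])), diff(range(xy[, 2])))
  out1 <- !points_strictly_inside(cbind(ds$x1, ds$y1), hull, 1e-7 * scale)
  out2 <- !points_strictly_inside(cbind(ds$x2, ds$y2), hull, 1e-7 * scale)
  flag <- (ds$bp1 | ds$bp2 | out1 | out2)
  for (i in which(flag)) {
    border[ds$ind1[i]] <- TRUE
    border[ds$ind2[i]] <- TRUE
  }
  border[grDevices::chull(xy)] <- TRUE
  list(adjacency = lapply(adj, unique), border = border, xy = xy)
}

# TRUE for points strictly inside a convex polygon (vertices in hull order),
# with an eps margin: points on the boundary count as outside.
points_strictly_inside <- function(pts, hull, eps) {
  m <- nrow(hull)
  inside <- rep(TRUE, nrow(pts))
  # orientation of the hull
  area2 <- sum(hull[, 1] * hull[c(2:m, 1), 2] - hull[c(2:m, 1), 1] * hull[, 2])
  s <- sign(area2)
  for (i in seq_len(m)) {
    a <- hull[i, ]; b <- hull[if (i == m) 1 else i + 1, ]
    cross <- (b[1] - a[1]) * (pts[, 2] - a[2]) - (b[2] - a[2]) * (pts[, 1] - a[1])
    inside <- inside & (s * cross > eps)
  }
  inside
}

#' Voronoi neighbour counts
#'
#' Number of Voronoi cells sharing a positive-length edge with each cone's
#' cell (6 for every interior cone of a hexagonal lattice; 4 on a square
#' lattice under strict adjacency). Cones whose cell is clipped by the
#' bounding window are flagged as border cells; their counts are unreliable
#' and are excluded from [regularity()] sampling.
#'
#' @param positions Positions (matrix, data frame with x/y, or cone mosaic).
#' @return Tibble: `id`, `n_neighbours`, `border`.
#' @export
voronoi_neighbour_counts <- function(positions) {
  vs <- voronoi_structure(positions)
  tibble(id = seq_along(vs$adjacency),
         n_neighbours = vapply(vs$adjacency, length, integer(1)),
         border = vs$border)
}

#' Nearest-neighbour distances
#'
#' Euclidean distance from each cone to its closest other cone.
#'
#' @inheritParams voronoi_neighbour_counts
#' @return Numeric vector, one distance per cone.
#' @export
nearest_neighbour_distances <- function(positions) {
  xy <- as_positions(positions)
  n <- nrow(xy)
  if (n < 2) abort("at least 2 positions are required")
  if (n <= 2000) {
    d <- as.matrix(stats::dist(xy))
    diag(d) <- Inf
    unname(apply(d, 1, min))
  } else {
    # block-wise to bound memory on large mosaics
    out <- numeric(n)
    bs <- 1000L
    for (s in seq(1, n, by = bs)) {
      e <- min(n, s + bs - 1L)
      d <- outer(xy[s:e, 1], xy[, 1], "-")^2 + outer(xy[s:e, 2], xy[, 2], "-")^2
      d[cbind(seq_len(e - s + 1L), s:e)] <- Inf
      out[s:e] <- sqrt(apply(d, 1, min))
    }
    out
  }
}

nearest_neighbour_index <- function(xy) {
  d <- as.matrix(stats::dist(xy))
  diag(d) <- Inf
  apply(d, 1, which.min)
}

#' Vertex angles of the packing
#'
#' For each cone: the angle at the cone between its nearest neighbour and
#' the closest common neighbour — the cone Voronoi-adjacent to both the cone
#' and its nearest neighbour that minimises the summed distance to the pair
#' (ties broken towards the smaller index). 60 degrees everywhere on a
#' hexagonal lattice.
#'
#' @inheritParams voronoi_neighbour_counts
#' @return Tibble: `id`, `angle_deg` (NA where no common neighbour exists),
#'   `border`.
#' @export
vertex_angles <- function(positions) {
  xy <- as_positions(positions)
  n <- nrow(xy)
  if (n < 3) abort("at least 3 positions are required")
  if (n == 3) {
    adj <- list(c(2L, 3L), c(1L, 3L), c(1L, 2L))
    border <- rep(TRUE, 3)
  } else {
    vs <- voronoi_structure(xy)
    adj <- vs$adjacency
    border <- vs$border
  }
  nn <- nearest_neighbour_index(xy)
  ang <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    j <- nn[i]
    common <- intersect(adj[[i]], adj[[j]])
    common <- setdiff(common, c(i, j))
    if (length(common) == 0) next
    dsum <- sqrt((xy[common, 1] - xy[i, 1])^2 + (xy[common, 2] - xy[i, 2])^2) +
      sqrt((xy[common, 1] - xy[j, 1])^2 + (xy[common, 2] - xy[j, 2])^2)
    k <- common[order(dsum, common)][1]
    v1 <- xy[j, ] - xy[i, ]
    v2 <- xy[k, ] - xy[i, ]
    cosang <- sum(v1 * v2) / (sqrt(sum(v1^2)) * sqrt(sum(v2^2)))
    ang[i] <- acos(pmin(pmax(cosang, -1), 1)) * 180 / pi
  }
  tibble(id = seq_len(n), angle_deg = ang, border = border)
}

#' Packing-regularity report
#'
#' Computes one of three regularity statistics over a random sample of
#' interior cones and summarises it as a normalised variability:
#' standard deviation divided by the mean (or by 60 degrees for the vertex
#' angle). Zero for a perfectly regular hexagonal lattice; a uniform-random
#' mosaic of the same cone count scores far higher on all three.
#'
#' @inheritParams voronoi_neighbour_counts
#' @param metric One of `"neighbour_count"`, `"nn_distance"`,
#'   `"vertex_angle"`.
#' @param n_sample Number of interior cones to sample (capped at the number
#'   available).
#' @param seed Optional RNG seed for the sampling.
#' @return A `regularity_report`: list with `metric`, `values` (raw
#'   per-sampled-cone values), `variability`, `n_sampled`.
#' @export
regularity <- function(positions,
                       metric = c("neighbour_count", "nn_distance", "vertex_angle"),
                       n_sample = 100, seed = NULL) {
  metric <- match.arg(metric)
  xy <- as_positions(positions)
  vs <- voronoi_structure(xy)
  interior <- which(!vs$border)
  if (length(interior) == 0) abort("no interior cones: mosaic too small")
  with_seed_if(seed, {
    take <- if (length(interior) > n_sample) {
      sort(sample(interior, n_sample))
    } else interior
    values <- switch(
      metric,
      neighbour_count = vapply(vs$adjacency[take], length, integer(1)),
      nn_distance = nearest_neighbour_distances(xy)[take],
      vertex_angle = vertex_angles(xy)$angle_deg[take]
    )
    values <- values[!is.na(values)]
    denom <- if (metric == "vertex_angle") 60 else mean(values)
    structure(list(metric = metric, values = as.numeric(values),
                   variability = stats::sd(values) / denom,
                   n_sampled = length(values)),
              class = "regularity_report")
  })
}

#' @export
print.regularity_report <- function(x, ...) {
  cat(sprintf("<regularity_report> %s: variability %.4f (n = %d)\n",
              x$metric, x$variability, x$n_sampled))
  invisible(x)
}

#' @rdname regularity
#' @param x A `regularity_report`.
#' @param ... Unused.
#' @export
tidy.regularity_report <- function(x, ...) {
  tibble(metric = x$metric, value = x$values)
}

#' @rdname regularity
#' @export
glance.regularity_report <- function(x, ...) {
  tibble(metric = x$metric, variability = x$variability,
         n_sampled = x$n_sampled,
         mean = mean(x$values), sd = stats::sd(x$values))
}

#' Radially averaged power spectrum of a retinal image
#'
#' Hann-windowed 2-D power spectrum, averaged over one-bin annuli, with the
#' frequency axis in cycles/degree. The modal cone-spacing frequency appears
#' as a peak (Yellott's ring) below ~50 c/deg for human eccentricities.
#'
#' @param image A `retina_image`, or a matrix with `pixel_scale_arcmin`.
#' @param pixel_scale_arcmin Pixel scale if `image` is a bare matrix.
#' @return Tibble: `freq_cpd`, `power` (annulus means, DC bin included as
#'   `freq_cpd = 0`).
#' @export
radial_power_spectrum <- function(image, pixel_scale_arcmin = NULL) {
  ps <- pixel_scale_arcmin %||% attr(image, "pixel_scale")
  if (is.null(ps)) abort("pixel scale unknown: supply pixel_scale_arcmin")
  m <- unclass(image)
  m <- (m - mean(m)) * hann2(nrow(m), ncol(m))
  p <- Mod(fftshift2(fft(m)))^2
  nr <- nrow(p); nc <- ncol(p)
  cy <- nr %/% 2 + 1; cx <- nc %/% 2 + 1
  fy <- (seq_len(nr) - cy) / (nr * ps / 60)   # cycles/deg
  fx <- (seq_len(nc) - cx) / (nc * ps / 60)
  rr <- sqrt(outer(fy^2, rep(1, nc)) + outer(rep(1, nr), fx^2))
  bin_w <- 1 / (min(nr, nc) * ps / 60)        # one frequency bin in c/deg
  bin <- round(rr / bin_w)
  keep <- bin <= (min(nr, nc) %/% 2)
  agg <- tapply(p[keep], bin[keep], mean)
  tibble(freq_cpd = as.numeric(names(agg)) * bin_w,
         power = as.numeric(agg))
}

#' Yellott's-ring peak frequency
#'
#' Frequency of the maximum of the radially averaged power spectrum above a
#' low-frequency exclusion zone. Two guards are applied: a DC exclusion of
#' `dc_exclude_bins` frequency bins, and a floor of `min_freq_cpd` that
#' skips the band dominated by the low-spatial-frequency reflectance
#' modulation of the mosaic (correlation length ~15 arcmin, i.e. power
#' concentrated below ~8 c/deg). The modal cone-spacing peak lies well above
#' this floor throughout the modelled eccentricity range (up to 10 degrees).
#'
#' @param x A spectrum tibble from [radial_power_spectrum()], a
#'   `retina_image`, or a matrix (then `pixel_scale_arcmin` is required).
#' @inheritParams radial_power_spectrum
#' @param dc_exclude_bins Number of low-frequency bins to exclude.
#' @param min_freq_cpd Lower bound of the peak search (c/deg).
#' @return Peak frequency (c/deg).
#' @export
yellott_peak <- function(x, pixel_scale_arcmin = NULL, dc_exclude_bins = 2,
                         min_freq_cpd = 10) {
  spec <- if (is.data.frame(x)) x else radial_power_spectrum(x, pixel_scale_arcmin)
  bin_w <- min(diff(sort(unique(spec$freq_cpd))))
  floor_cpd <- max(dc_exclude_bins * bin_w, min_freq_cpd)
  s <- dplyr::filter(spec, .data$freq_cpd > floor_cpd + 1e-12)
  if (nrow(s) == 0) abort("no spectrum bins above the low-frequency exclusion")
  s$freq_cpd[which.max(s$power)]
}

#' Perfect hexagonal lattice (test/reference geometry)
#'
#' @param nx,ny Columns and rows of the lattice.
#' @param spacing Centre-to-centre spacing.
#' @return Tibble `x`, `y` centred on the origin.
#' @export
hex_lattice <- function(nx = 12, ny = 12, spacing = 1) {
  pts <- tidyr::expand_grid(row = seq_len(ny), col = seq_len(nx))
  x <- (pts$col - 1) * spacing + ifelse(pts$row %% 2 == 0, spacing / 2, 0)
  y <- (pts$row - 1) * spacing * sqrt(3) / 2
  tibble(x = x - mean(x), y = y - mean(y))
}
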