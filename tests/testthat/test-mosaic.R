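test_that("hexagonal spacing-density relation and its inverse hold", {
  expect_equal(spacing_from_density(2 / sqrt(3)), sqrt(3) / 2, tolerance = 1e-12)
  # power law: quadrupling density halves spacing
  expect_equal(spacing_from_density(4 * 1.7), spacing_from_density(1.7) / 2,
               tolerance = 1e-12)
  # round trip: the algebraic inverse of the spacing formula
  for (s in c(0.5, 1, 2)) {
    expect_equal(spacing_from_density(sqrt(3) / (2 * s^2)), s, tolerance = 1e-12)
  }
  expect_error(spacing_from_density(0), "positive")
  expect_error(spacing_from_density(-1), "positive")
})

test_that("eccentricity scaling hits the target spacing exactly and is a similarity", {
  hex <- hex_lattice(10, 10, spacing = 3.7)
  m <- scale_mosaic_to_eccentricity(hex, 3)
  target <- cone_spacing_arcmin(3)
  nn <- nearest_neighbour_distances(m)
  expect_equal(mean(nn), target, tolerance = 1e-3 * 0.1)  # within 0.1%
  # uniform lattice: every distance equals the target
  expect_equal(max(abs(nn - target)), 0, tolerance = 1e-9)

  # similarity: all pairwise distance ratios preserved
  rd <- rd_small_centres()[1:40, ]
  sc <- scale_mosaic_to_eccentricity(rd, 6)
  d0 <- as.vector(dist(cbind(rd$x, rd$y)))
  d1 <- as.vector(dist(cbind(sc$mu_x, sc$mu_y)))
  ratio <- d1 / d0
  expect_lt(diff(range(ratio)) / mean(ratio), 1e-9)
})

test_that("scaling with identity target leaves geometry unchanged; spacing ordered by eccentricity", {
  rd <- rd_small_centres()
  m15 <- scale_mosaic_to_eccentricity(rd, 1.5)
  m3 <- scale_mosaic_to_eccentricity(rd, 3)
  m6 <- scale_mosaic_to_eccentricity(rd, 6)
  s <- vapply(list(m15, m3, m6),
              function(m) mean(nearest_neighbour_distances(m)), numeric(1))
  expect_true(all(diff(s) > 0))  # spacing grows with eccentricity
  expect_error(scale_mosaic_to_eccentricity(rd, 25), "domain")
  expect_error(scale_mosaic_to_eccentricity(rd[1:3, ], 3), "at least 7")
})

test_that("axial length rescales angular spacing inversely", {
  hex <- hex_lattice(8, 8)
  m24 <- scale_mosaic_to_eccentricity(hex, 3, axial_length_mm = 24)
  m26 <- scale_mosaic_to_eccentricity(hex, 3, axial_length_mm = 26.4)
  expect_equal(mean(nearest_neighbour_distances(m26)) * 26.4 / 24,
               mean(nearest_neighbour_distances(m24)), tolerance = 1e-9)
})

test_that("Marcuse mode radius matches independent evaluation and its limits", {
  # independent evaluation of the closed form
  a <- 1.0; lambda <- 0.84; nco <- 1.39; ncl <- 1.34
  v <- 2 * pi * a / lambda * sqrt(nco^2 - ncl^2)
  w_expect <- a * (0.65 + 1.619 * v^(-1.5) + 2.879 * v^(-6))
  expect_equal(marcuse_mode_radius(a, lambda, nco, ncl), w_expect,
               tolerance = 1e-12)
  expect_equal(cone_width_marcuse(a, lambda, nco, ncl), w_expect / sqrt(2),
               tolerance = 1e-12)
  # w increases with core radius in the guided regime
  radii <- seq(0.8, 3, by = 0.2)
  expect_true(all(diff(marcuse_mode_radius(radii)) > 0))
  # large-V limit: w/a -> 0.65
  expect_equal(marcuse_mode_radius(1e4) / 1e4, 0.65, tolerance = 1e-6)
  expect_error(marcuse_mode_radius(1, n_core = 1.3, n_clad = 1.35), "exceed")
})

test_that("reflectance assignment preserves the configured mean and is clipped at zero", {
  pos <- cbind(runif(10000, 0, 200), runif(10000, 0, 200))
  a <- assign_reflectances(pos, mean = 1, sd = 0.2, seed = 9)
  expect_true(all(a >= 0))
  expect_lt(abs(mean(a) - 1), 0.02)
  # sd = 0 and no modulation: all identical
  a0 <- assign_reflectances(pos[1:50, ], mean = 2, sd = 0, modulation = FALSE)
  expect_equal(a0, rep(2, 50))
  expect_error(assign_reflectances(pos[1:5, ], mean = -1), "non-negative")
})

test_that("low-frequency modulation induces short-range spatial correlation", {
  withr::with_seed(21, {
    pos <- cbind(runif(4000, 0, 120), runif(4000, 0, 120))
  })
  a <- assign_reflectances(pos, mean = 1, sd = 0, modulation = TRUE,
                           mod_length_arcmin = 15, seed = 4)
  # empirical correlogram: close pairs more similar than distant pairs
  d <- as.matrix(dist(pos))
  dev <- a - mean(a)
  prod <- outer(dev, dev)
  near <- d > 0 & d < 5
  far <- d > 40 & d < 60
  expect_gt(mean(prod[near]), mean(prod[far]) + 0.5 * var(dev))
})

test_that("retina rendering evaluates the Gaussian sum exactly", {
  m <- cone_mosaic(cbind(0, 0), sigma_x = 2, sigma_y = 2, A = 1)
  img <- render_retina(m, pixel_scale = 0.5, bounds = c(-8, 8, -8, 8))
  val <- retsim:::retina_value_at(img, 0, 0)
  expect_equal(val, 1, tolerance = 1e-12)
  expect_equal(retsim:::retina_value_at(img, 2, 0), exp(-0.5), tolerance = 1e-12)
  expect_equal(retsim:::retina_value_at(img, 0, 2), exp(-0.5), tolerance = 1e-12)
})

test_that("rendering is linear in reflectance and superposes", {
  pos <- rbind(c(-5, -4), c(6, 5))
  m1 <- cone_mosaic(pos[1, , drop = FALSE], sigma_x = 1.2, A = 0.7)
  m2 <- cone_mosaic(pos[2, , drop = FALSE], sigma_x = 0.9, A = 1.3)
  both <- cone_mosaic(pos, sigma_x = c(1.2, 0.9), A = c(0.7, 1.3))
  bounds <- c(-10, 10, -10, 10)
  i1 <- render_retina(m1, 0.25, bounds)
  i2 <- render_retina(m2, 0.25, bounds)
  ib <- render_retina(both, 0.25, bounds)
  expect_equal(unclass(ib), unclass(i1) + unclass(i2), tolerance = 1e-12)
  # doubling A doubles the image
  m2x <- cone_mosaic(pos, sigma_x = c(1.2, 0.9), A = 2 * c(0.7, 1.3))
  expect_equal(unclass(render_retina(m2x, 0.25, bounds)), 2 * unclass(ib),
               tolerance = 1e-12)
})

test_that("orientation theta rotates the elliptical profile", {
  bounds <- c(-6, 6, -6, 6)
  m0 <- cone_mosaic(cbind(0, 0), sigma_x = 2, sigma_y = 0.8, theta = 0)
  m90 <- cone_mosaic(cbind(0, 0), sigma_x = 2, sigma_y = 0.8, theta = pi / 2)
  i0 <- unclass(render_retina(m0, 0.5, bounds))
  i90 <- unclass(render_retina(m90, 0.5, bounds))
  # 90-degree rotation of a centred image = transpose for symmetric grids
  expect_equal(i90, t(i0), tolerance = 1e-12)
  # arbitrary angle: value at rotated probe point matches the unrotated value
  th <- 0.7
  mth <- cone_mosaic(cbind(0, 0), sigma_x = 2, sigma_y = 0.8, theta = th)
  ith <- render_retina(mth, 0.05, bounds)
  p <- c(1.3, 0.4)  # point in the cone's own frame
  probe <- c(cos(th) * p[1] - sin(th) * p[2], sin(th) * p[1] + cos(th) * p[2])
  v_expect <- exp(-(p[1]^2 / (2 * 2^2) + p[2]^2 / (2 * 0.8^2)))
  expect_equal(retsim:::retina_value_at(ith, probe[1], probe[2]), v_expect,
               tolerance = 1e-3)
})

test_that("rendering is equivariant to integer-pixel translation", {
  ps <- 0.5
  m <- cone_mosaic(cbind(0.3, -0.2), sigma_x = 1.5)
  ma <- cone_mosaic(cbind(0.3 + 4 * ps, -0.2 + 2 * ps), sigma_x = 1.5)
  i0 <- unclass(render_retina(m, ps, c(-8, 8, -8, 8)))
  i1 <- unclass(render_retina(ma, ps, c(-8, 8, -8, 8)))
  expect_equal(i1[(1 + 2):nrow(i1), (1 + 4):ncol(i1)],
               i0[1:(nrow(i0) - 2), 1:(ncol(i0) - 4)], tolerance = 1e-10)
})

test_that("bounds excluding all cones warn and return a blank image", {
  m <- cone_mosaic(cbind(100, 100), sigma_x = 1)
  expect_warning(img <- render_retina(m, 1, c(-5, 5, -5, 5)), "blank")
  expect_true(all(unclass(img) == 0))
})

test_that("random mosaics are seed-reproducible and in bounds", {
  a <- random_mosaic(500, c(-20, 20, -10, 10), seed = 5)
  b <- random_mosaic(500, c(-20, 20, -10, 10), seed = 5)
  c_ <- random_mosaic(500, c(-20, 20, -10, 10), seed = 6)
  expect_identical(a$mu_x, b$mu_x)
  expect_false(identical(a$mu_x, c_$mu_x))
  expect_true(all(a$mu_x >= -20 & a$mu_x <= 20))
  expect_true(all(a$mu_y >= -10 & a$mu_y <= 10))
  one <- random_mosaic(1, c(0, 1, 0, 1), seed = 2)
  expect_equal(nrow(one), 1)
})

test_that("cone mosaic CSV round-trips", {
  m <- cone_mosaic(cbind(c(0, 3, -2), c(1, -1, 2)), sigma_x = c(1, 1.2, 0.9),
                   theta = c(0, 0.4, 1.2), A = c(1, 0.5, 1.5))
  path <- tempfile(fileext = ".csv")
  write_cone_mosaic_csv(m, path)
  back <- read_cone_mosaic_csv(path)
  expect_equal(as.data.frame(back), as.data.frame(m), tolerance = 1e-12)
})
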