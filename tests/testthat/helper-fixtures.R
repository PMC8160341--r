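# Shared fixtures, generated in code.

# A jittered hexagonal lattice: regular but not perfect, a cheap stand-in
# for a self-organised mosaic in unit tests (the real reaction-diffusion
# mosaic is exercised where the packing ordering itself is under test).
jittered_hex <- function(nx = 14, ny = 14, spacing = 1, jitter = 0.06,
                         seed = 1) {
  withr::with_seed(seed, {
    h <- hex_lattice(nx, ny, spacing)
    h$x <- h$x + rnorm(nrow(h), 0, jitter * spacing)
    h$y <- h$y + rnorm(nrow(h), 0, jitter * spacing)
    h
  })
}

# Small reaction-diffusion mosaic shared across tests (cached per session).
rd_small_centres <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- rd_cone_positions(n = 150, n_steps = 8000, seed = 11)
    }
    cache
  }
})

# Toy optical model with a small kernel for fast capture tests.
toy_model <- function(...) {
  optical_model(pupil_diameter_mm = 5, wavelength_nm = 840,
                psf_extent_arcmin = 4, ...)
}

expect_rel_equal <- function(actual, expected, tol) {
  expect_lt(max(abs(actual - expected)) / max(abs(expected)), tol)
}
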