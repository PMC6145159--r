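test_that("spectra are normalized with support below the tube voltage", {
  s <- make_spectrum(140, 50)
  expect_equal(sum(s$weights), 1, tolerance = 1e-12)
  expect_true(all(s$weights >= 0))
  expect_true(all(s$energies <= 140))
  expect_true(all(diff(s$energies) > 0))

  s1 <- make_spectrum(80, 1)
  expect_equal(s1$weights, 1)

  mean80 <- sum(make_spectrum(80, 50)$energies * make_spectrum(80, 50)$weights)
  mean140 <- sum(s$energies * s$weights)
  expect_gt(mean140, mean80)

  expect_error(make_spectrum(30), "40, 150")
})

test_that("effective attenuation averages the curve over the spectrum", {
  model <- default_attenuation_model()
  # monoenergetic: exactly the tabulated value
  expect_equal(effective_mu("tissue", mono_spectrum(60), model),
               model$mu$tissue[model$energies == 60])
  # uniform two-bin: arithmetic mean of the two tabulated values
  two <- structure(list(energies = c(40, 80), weights = c(0.5, 0.5),
                        kvp = 80), class = "spectrum")
  expect_equal(effective_mu("bone", two, model),
               mean(model$mu$bone[model$energies %in% c(40, 80)]))
  # bounded by the curve on the support, and softer spectrum attenuates more
  s80 <- make_spectrum(80, 50); s140 <- make_spectrum(140, 50)
  mu80 <- effective_mu("bone", s80, model)
  expect_gt(mu80, min(mu_bone <- with(model, mu$bone)))
  expect_lt(mu80, max(mu_bone))
  expect_gt(mu80, effective_mu("bone", s140, model))
  expect_error(effective_mu("iron", s80, model), "unknown material")
})

test_that("forward projection is linear and reproduces chord lengths", {
  n <- 128; d <- 0.1; r <- 32
  img <- disk_image(n, r, v = 0.7)
  s <- forward_project(img, pixel_size = d)
  # central ray: chord 2 r d v, within 2% discretization tolerance
  expect_equal(max(s$values), 2 * r * d * 0.7, tolerance = 0.02)
  # linearity is exact for the sampled projector
  expect_equal(forward_project(2 * img, pixel_size = d)$values,
               2 * s$values, tolerance = 1e-12)
  zero <- forward_project(matrix(0, n, n), pixel_size = d)
  expect_true(all(zero$values == 0))
  expect_error(forward_project(matrix(0, 4, 6)), "square")
})

test_that("polyenergetic projection composes Beer-Lambert over the spectrum", {
  model <- default_attenuation_model()
  geom <- function(v) sinogram(matrix(v, 2, 3), c(0, 90))
  # zero path -> zero projection
  p0 <- polyenergetic_projection(geom(0), geom(0), make_spectrum(80, 30),
                                 model)
  expect_equal(p0$values, matrix(0, 2, 3))
  # monoenergetic: exactly mu(E) L
  mono <- mono_spectrum(60)
  p <- polyenergetic_projection(geom(2), geom(0), mono, model)
  mu60 <- effective_mu("tissue", mono, model)
  expect_equal(p$values, matrix(2 * mu60, 2, 3), tolerance = 1e-12)
  # beam hardening: p(2L) < 2 p(L) for a broad spectrum
  sp <- make_spectrum(80, 40)
  p1 <- polyenergetic_projection(geom(1), geom(0), sp, model)$values[1, 1]
  p2 <- polyenergetic_projection(geom(2), geom(0), sp, model)$values[1, 1]
  expect_lt(p2, 2 * p1)
  expect_error(
    polyenergetic_projection(geom(1), sinogram(matrix(0, 1, 3), 0), sp,
                             model),
    "geometry")
})

test_that("photon noise follows the log-Poisson model", {
  # near-unbiasedness at high counts: mean within 3 standard errors of 0
  p <- sinogram(matrix(0, 100, 100), seq(0, 179.9, length.out = 100))
  noisy <- add_photon_noise(p, incident = 1e6, seed = 11)
  se <- stats::sd(noisy$values) / 100
  expect_lt(abs(mean(noisy$values)), 3 * se)

  # delta-method variance ~ e^p / I: 100x fewer photons, ~100x variance
  v4 <- var(as.vector(add_photon_noise(p, 1e4, seed = 2)$values))
  v6 <- var(as.vector(add_photon_noise(p, 1e6, seed = 3)$values))
  expect_equal(v4 / v6, 100, tolerance = 0.15)

  # determinism and the one-photon clamp
  expect_identical(add_photon_noise(p, 1e5, seed = 4),
                   add_photon_noise(p, 1e5, seed = 4))
  dark <- sinogram(matrix(30, 5, 5), c(0, 40, 80, 120, 160))
  clamped <- add_photon_noise(dark, incident = 10, seed = 1)
  expect_true(all(clamped$values <= log(10) + 1e-12))
  expect_true(any(clamped$values == log(10)))
  expect_error(add_photon_noise(p, -1), "positive")
})
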