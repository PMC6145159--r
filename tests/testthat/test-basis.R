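test_that("basis estimation averages ROIs and flags singular bases", {
  h <- matrix(1, 8, 8); l <- matrix(1, 8, 8)
  h[1:4, ] <- 2                       # ROI-1 rows have mu_H = 2
  roi1 <- matrix(FALSE, 8, 8); roi1[1:4, ] <- TRUE
  roi2 <- !roi1
  img <- dual_energy_image(l, h)
  b <- estimate_basis(img, roi1, roi2)
  expect_equal(c(b$mu1H, b$mu2H, b$mu1L, b$mu2L), c(2, 1, 1, 1))
  expect_equal(b$delta, 1)

  # identical columns: delta = 0 -> singular-basis error
  const <- dual_energy_image(matrix(1, 8, 8), matrix(2, 8, 8))
  expect_error(estimate_basis(const, roi1, roi2), "singular")

  # single-pixel ROI picks up that pixel's values
  r1 <- matrix(FALSE, 8, 8); r1[3, 5] <- TRUE
  img2 <- dual_energy_image(matrix(runif(64), 8), matrix(runif(64), 8))
  b2 <- estimate_basis(img2, r1, roi2)
  expect_equal(b2$mu1H, img2$mu_H[3, 5])
  expect_equal(b2$mu1L, img2$mu_L[3, 5])

  expect_error(estimate_basis(img, matrix(FALSE, 8, 8), roi2), "empty ROI")
})

test_that("forward mixing and matrix inversion are exact inverses", {
  b <- test_basis()
  ones <- material_image(matrix(1, 3, 3), matrix(1, 3, 3))
  img <- forward_mix(ones, b)
  expect_equal(img$mu_H, matrix(3, 3, 3))
  expect_equal(img$mu_L, matrix(2, 3, 3))

  back <- invert_decompose(img, b)
  expect_equal(back$x1, matrix(1, 3, 3), tolerance = 1e-12)
  expect_equal(back$x2, matrix(1, 3, 3), tolerance = 1e-12)

  ident <- basis2x2(1, 0, 0, 1)
  m <- material_image(matrix(runif(9), 3), matrix(runif(9), 3))
  expect_equal(forward_mix(m, ident)$mu_H, m$x1)
  expect_equal(forward_mix(m, ident)$mu_L, m$x2)
  id_img <- dual_energy_image(matrix(runif(9), 3), matrix(runif(9), 3))
  dec <- invert_decompose(id_img, ident)
  expect_equal(dec$x1, id_img$mu_H)
  expect_equal(dec$x2, id_img$mu_L)

  expect_error(invert_decompose(img, basis2x2(1, 1, 1, 1)), "singular")
})

test_that("round-trip recovery holds across random non-singular bases", {
  withr::with_seed(42, {
    for (i in 1:100) {
      repeat {
        b <- basis2x2(runif(1, 0.1, 3), runif(1, 0.1, 3),
                      runif(1, 0.1, 3), runif(1, 0.1, 3))
        if (abs(b$delta) > 1e-6) break
      }
      m <- material_image(matrix(runif(16, 0, 2), 4),
                          matrix(runif(16, 0, 2), 4))
      back <- invert_decompose(forward_mix(m, b), b)
      expect_lt(max(abs(back$x1 - m$x1)) / max(m$x1), 1e-10)
      expect_lt(max(abs(back$x2 - m$x2)) / max(m$x2), 1e-10)
    }
  })
})

test_that("inversion noise grows as the reciprocal determinant", {
  withr::with_seed(7, {
    noise_h <- matrix(rnorm(64^2, sd = 0.01), 64)
    noise_l <- matrix(rnorm(64^2, sd = 0.01), 64)
  })
  sd_for <- function(b) {
    img <- dual_energy_image(matrix(1, 64, 64) + noise_l,
                             matrix(1, 64, 64) + noise_h)
    stats::sd(invert_decompose(img, b)$x1)
  }
  # two bases with identical entries scale except delta shrunk 5x
  b1 <- basis2x2(2, 1, 1, 1)              # delta 1
  b2 <- basis2x2(1.2, 1, 1, 1)            # delta 0.2
  expect_equal(sd_for(b2) / sd_for(b1), 5, tolerance = 0.25)
})

test_that("iterative decomposition smooths, descends and nests inversion", {
  b <- test_basis()
  withr::with_seed(3, {
    img <- forward_mix(material_image(matrix(1, 32, 32) +
                                        matrix(rnorm(1024, sd = 0.2), 32),
                                      matrix(0.5, 32, 32)), b)
  })
  direct <- invert_decompose(img, b)

  # n_iter = 0 returns the matrix-inversion initialization
  init <- iterative_decompose(img, b, smoothness_weight = 1, n_iter = 0)
  expect_equal(init$x1, direct$x1)

  # lambda = 0: stays at the unpenalized optimum
  free <- iterative_decompose(img, b, smoothness_weight = 0, n_iter = 200)
  expect_lt(max(abs(free$x1 - direct$x1)) / max(abs(direct$x1)), 1e-4)

  # smoothing strictly reduces output variance on noisy input
  smooth <- iterative_decompose(img, b, smoothness_weight = 2, n_iter = 200)
  expect_lt(var(as.vector(smooth$x1)), var(as.vector(direct$x1)))

  # objective is monotone non-increasing
  obj <- attr(smooth, "objective")
  expect_length(obj, 201)
  expect_true(all(diff(obj) <= 1e-9))
})
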