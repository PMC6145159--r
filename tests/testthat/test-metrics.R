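test_that("bias reproduces hand-computed values and conventions", {
  roi <- matrix(TRUE, 1, 3)
  expect_equal(decomp_bias(matrix(c(1, 2, 3), 1), matrix(1, 1, 3), roi), 1.0)
  expect_equal(decomp_bias(matrix(1:4 / 2, 2), matrix(1:4 / 2, 2)), 0)
  pred <- matrix(runif(16), 4)
  expect_equal(decomp_bias(pred + 0.5, pred), 0.5)
  # signed convention detects direction; absolute does not cancel
  expect_equal(decomp_bias(matrix(c(2, 0), 1), matrix(c(1, 1), 1),
                           signed = TRUE), 0)
  expect_equal(decomp_bias(matrix(c(2, 0), 1), matrix(c(1, 1), 1)), 1)
  expect_error(decomp_bias(pred, pred, matrix(FALSE, 4, 4)), "empty ROI")
  expect_error(decomp_bias(pred, matrix(0, 2, 2)), "dimensions")
})

test_that("sd reproduces hand-computed dispersion with homogeneity", {
  expect_equal(decomp_sd(matrix(c(1, 3), 1)), 1.0)
  expect_equal(decomp_sd(matrix(5, 4, 4)), 0)
  pred <- matrix(runif(25), 5)
  expect_equal(decomp_sd(-3 * pred), 3 * decomp_sd(pred))
  # offset-invariant, order-invariant
  expect_equal(decomp_sd(pred + 7), decomp_sd(pred))
  roi_a <- matrix(FALSE, 5, 5); roi_a[1, ] <- TRUE
  vals <- pred; vals[1, ] <- c(2, 1, 4, 3, 5)
  roi_perm <- matrix(FALSE, 5, 5); roi_perm[1, ] <- TRUE
  expect_equal(decomp_sd(vals, roi_a), decomp_sd(vals, roi_perm))
})

test_that("difference images are symmetric absolute deviations", {
  a <- material_image(matrix(runif(16), 4), matrix(runif(16), 4))
  expect_true(all(difference_image(a, a)$x1 == 0))
  b <- material_image(a$x1 + matrix(c(0.2, -0.2), 4, 4), a$x2)
  d <- difference_image(a, b)
  expect_equal(d$x1, matrix(0.2, 4, 4))
  expect_equal(difference_image(b, a)$x1, d$x1)
  expect_error(difference_image(a, material_image(matrix(0, 2, 2),
                                                  matrix(0, 2, 2))),
               "dimensions")
})

test_that("experiment harness scores, orders noise effects and is seeded", {
  # classical methods only, so the harness itself stays quick
  cfg <- experiment_config(seed = 21, shape = c(96L, 96L), n_train = 1L,
                           methods = c("inverse", "iterative"),
                           iterative_iters = 30L)
  res <- run_experiment(cfg)
  m <- res$metrics
  expect_s3_class(m, "tbl_df")
  expect_setequal(names(m), c("method", "material", "noise", "bias", "sd",
                              "n"))
  expect_equal(nrow(m), 8)
  expect_true(all(m$bias >= 0) && all(m$sd >= 0))

  # photon noise strictly inflates the dispersion of matrix inversion
  inv <- m[m$method == "inverse", ]
  for (mat in c("tissue", "bone")) {
    expect_gt(inv$sd[inv$material == mat & inv$noise == "photon"],
              inv$sd[inv$material == mat & inv$noise == "noiseless"])
  }

  res2 <- run_experiment(cfg)
  expect_identical(res$metrics, res2$metrics)

  expect_error(experiment_config(methods = "deep"), "unknown method")
})

test_that("noiseless monoenergetic inversion is accurate to FBP tolerance", {
  ph <- generate_phantom(96, 96, 1, 1, seed = 5)
  spec_L <- mono_spectrum(55); spec_H <- mono_spectrum(75)
  img <- simulate_dect(ph, spec_L, spec_H)
  model <- default_attenuation_model()
  basis <- basis2x2(effective_mu("tissue", spec_H, model),
                    effective_mu("bone", spec_H, model),
                    effective_mu("tissue", spec_L, model),
                    effective_mu("bone", spec_L, model))
  sc <- score_decomposition(invert_decompose(img, basis), ph)
  expect_lt(sc$bias[sc$material == "tissue"], 0.05)
  expect_lt(sc$bias[sc$material == "bone"], 0.05)
})
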