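test_that("generated phantoms have disjoint, non-trivial material partitions", {
  ph <- generate_phantom(512, 512, n_bone = 3, n_tissue = 2, seed = 3)
  expect_identical(dim(ph$x1), dim(ph$x2))
  expect_true(all(ph$x1 * ph$x2 == 0))
  expect_gt(sum(ph$x1 != 0), 0)
  expect_gt(sum(ph$x2 != 0), 0)
  expect_true(all(ph$x1 >= 0) && all(ph$x2 >= 0))

  empty <- generate_phantom(128, 128, n_bone = 0, n_tissue = 0, seed = 1)
  expect_true(all(empty$x1 == 0) && all(empty$x2 == 0))
})

test_that("phantom generation is deterministic in the seed and validates size", {
  a <- generate_phantom(128, 128, 2, 1, seed = 7)
  b <- generate_phantom(128, 128, 2, 1, seed = 7)
  expect_identical(a, b)
  c <- generate_phantom(128, 128, 2, 1, seed = 8)
  expect_false(identical(a$x1, c$x1))
  expect_error(generate_phantom(64, 128, 1, 1, seed = 1), "at least 65")
})

test_that("value transform is the stated element-wise linear scaling", {
  raw_t <- matrix(0.02, 4, 4)
  raw_b <- matrix(0, 4, 4); raw_b[2, 3] <- 0.1
  out <- apply_value_transform(raw_t, raw_b,
                               transform_params(lambda_t = 50, lambda_b = 15))
  expect_equal(out$x1, matrix(1, 4, 4))
  expect_equal(out$x2[2, 3], 1.5)
  expect_equal(sum(out$x2 != 0), 1)

  ident <- apply_value_transform(raw_t, raw_b, transform_params(1, 1))
  expect_equal(ident$x1, raw_t)
  expect_equal(ident$x2, raw_b)

  # homogeneity: transform(a x) = a transform(x)
  sc <- apply_value_transform(3 * raw_t, 3 * raw_b, transform_params())
  expect_equal(sc$x1, 3 * out$x1 * (50 / 50))
  expect_equal(sc$x2, 3 * apply_value_transform(raw_t, raw_b)$x2)

  expect_error(apply_value_transform(matrix(0, 2, 2), matrix(0, 3, 3)),
               "dimensions")
})

test_that("dataset generation splits reproducibly with distinct phantoms", {
  d <- make_dataset(2, 1, shape = c(128, 128), seed = 5)
  expect_length(d$train, 2)
  expect_length(d$test, 1)
  d2 <- make_dataset(2, 1, shape = c(128, 128), seed = 5)
  expect_identical(d, d2)

  d3 <- make_dataset(1, 1, shape = c(128, 128), seed = 5)
  expect_false(identical(d3$train[[1]]$x1, d3$test[[1]]$x1))
})
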