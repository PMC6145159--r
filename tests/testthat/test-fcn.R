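test_that("shape propagation follows the layer table", {
  rep <- shape_report(fcn_config())
  expect_equal(rep$out_side, c(33, 17, 9, 1))
  expect_equal(rep$channels, c(64, 128, 256, 512))

  quarter <- shape_report(fcn_config(channel_scale = 0.25))
  expect_equal(quarter$channels, c(16, 32, 64, 128))
  expect_equal(quarter$out_side, c(33, 17, 9, 1))

  # stride-1 variant: same-padded sides stay 65, final valid conv gives 57
  cfg1 <- fcn_config()
  cfg1$strides <- c(1L, 1L, 1L, 1L)
  expect_equal(shape_report(cfg1)$out_side, c(65, 65, 65, 57))
})

test_that("patch extraction counts, labels and validation are correct", {
  # sliding-window count formula on the clinical image size
  expect_length(dectdecomp:::patch_grid(512L, 65L, 5L), 90)

  ph <- generate_phantom(70, 70, 0, 1, seed = 2)
  img <- dual_energy_image(matrix(runif(70 * 70), 70),
                           matrix(runif(70 * 70), 70))
  # 66x66 area at stride 1 -> 2x2 placements on a 70x70 image gives 6x6
  ps <- extract_patches(img, ph, stride = 1)
  expect_equal(dim(ps$low)[3], 36)

  one <- extract_patches(dual_energy_image(img$mu_L[1:65, 1:65],
                                           img$mu_H[1:65, 1:65]),
                         material_image(ph$x1[1:65, 1:65],
                                        ph$x2[1:65, 1:65]),
                         stride = 5)
  expect_equal(dim(one$low)[3], 1)
  expect_equal(one$labels[1, 1], ph$x1[33, 33])
  expect_equal(one$low[, , 1], img$mu_L[1:65, 1:65])

  # padded extraction: centers tile the full image
  padded <- extract_patches(img, ph, stride = 10, pad = TRUE)
  expect_equal(dim(padded$low)[3], 49)
  expect_equal(padded$labels[1, ], c(ph$x1[1, 1], ph$x2[1, 1]))

  small <- dual_energy_image(matrix(0, 30, 30), matrix(0, 30, 30))
  expect_error(extract_patches(small, material_image(matrix(0, 30, 30),
                                                     matrix(0, 30, 30))),
               "smaller than one patch")
})

test_that("forward pass: bias-only nets, rectification and branch asymmetry", {
  net <- fcn_init(tiny_config())
  pl <- matrix(runif(65 * 65), 65); ph <- matrix(runif(65 * 65), 65)

  # bias-only network: output is the head bias regardless of input
  zeroed <- net
  for (br in c("L", "H")) for (l in 1:4) {
    zeroed$params[[br]][[l]]$W[] <- 0
    zeroed$params[[br]][[l]]$b[] <- 0
  }
  zeroed$params$Wc[] <- 0
  zeroed$params$bc <- c(0.3, 0.7)
  expect_equal(fcn_forward(zeroed, pl, ph), c(0.3, 0.7))
  expect_equal(fcn_forward(zeroed, ph, pl), c(0.3, 0.7))

  # all-negative pre-activations die under the rectifier
  neg <- net
  for (br in c("L", "H")) for (l in 1:4) neg$params[[br]][[l]]$b[] <- -1e6
  feats <- dectdecomp:::branch_forward(
    dectdecomp:::as_patch_array(pl), neg$params$L, neg$dims)$feat
  expect_true(all(feats == 0))

  # the two branches are independent: swapping inputs changes the output
  out1 <- fcn_forward(net, pl, ph)
  out2 <- fcn_forward(net, ph, pl)
  expect_false(isTRUE(all.equal(out1, out2)))

  expect_error(fcn_forward(net, matrix(0, 10, 10), matrix(0, 10, 10)),
               "65 x 65")
})

test_that("training overfits a repeated sample and is seed-reproducible", {
  ps <- repeated_patch_set(8)
  cfg <- tiny_config(epochs = 120, batch_size = 8, seed = 4)
  net <- fcn_train(ps, cfg)
  h <- net$history
  expect_equal(nrow(h), 120)
  expect_lt(h$loss[120], 0.01 * h$loss[1])
  pred <- fcn_forward(net, ps$low[, , 1], ps$high[, , 1])
  expect_equal(unname(pred), c(0.8, 1.2), tolerance = 0.15)

  # learning-rate schedule: base 5e-3 decaying by 0.9 each epoch
  expect_equal(h$lr, 5e-3 * 0.9^(0:119))
  expect_true(all(diff(h$lr) < 0))
  expect_equal(lr_schedule(cfg), h$lr)

  net2 <- fcn_train(ps, cfg)
  expect_identical(net$history, net2$history)
  expect_identical(net$params, net2$params)

  expect_error(fcn_train(list(low = array(0, c(65, 65, 0))), cfg))
})

test_that("image decomposition is per-pixel with reflection-padded borders", {
  cfg <- tiny_config()
  net <- fcn_init(cfg)
  img <- dual_energy_image(matrix(runif(80 * 80), 80),
                           matrix(runif(80 * 80), 80))

  # bias-only network gives constant maps of the head bias
  bias_net <- net
  for (br in c("L", "H")) for (l in 1:4) {
    bias_net$params[[br]][[l]]$W[] <- 0
    bias_net$params[[br]][[l]]$b[] <- 0
  }
  bias_net$params$Wc[] <- 0
  bias_net$params$bc <- c(0.25, 0.5)
  dec <- decompose_image(bias_net, img)
  expect_identical(dim(dec$x1), c(80L, 80L))
  expect_true(all(dec$x1 == 0.25) && all(dec$x2 == 0.5))

  # constant input image: identical neighborhoods give constant output
  const <- dual_energy_image(matrix(0.4, 70, 70), matrix(0.8, 70, 70))
  dc <- decompose_image(net, const)
  expect_lt(diff(range(dc$x1)), 1e-10)
  expect_lt(diff(range(dc$x2)), 1e-10)

  # masked evaluation fills only the requested pixels
  mask <- matrix(FALSE, 80, 80); mask[10:12, 20:22] <- TRUE
  dm <- decompose_image(net, img, pixels = mask)
  expect_true(all(is.na(dm$x1[!mask])))
  expect_true(all(!is.na(dm$x1[mask])))
})

test_that("tidy and glance summarize architecture and training", {
  net <- fcn_init(fcn_config(channel_scale = 0.25))
  td <- tidy(net)
  expect_equal(nrow(td), 9)
  expect_equal(td$out_side[td$branch == "L"], c(33, 17, 9, 1))
  expect_equal(sum(td$n_weights) + sum(td$n_biases),
               dectdecomp:::n_parameters(net))
  g0 <- glance(net)
  expect_equal(g0$epochs, 0L)
  expect_true(is.na(g0$final_loss))

  trained <- fcn_train(repeated_patch_set(4),
                       tiny_config(epochs = 3, batch_size = 4))
  g <- glance(trained)
  expect_equal(g$epochs, 3L)
  expect_equal(g$final_loss, trained$history$loss[3])
})
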