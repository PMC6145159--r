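# Shared fixtures, all built in code.

# uniform disk image: value v inside radius r (pixels), centered
disk_image <- function(n, r, v = 1) {
  cy <- (n - 1) / 2; cx <- (n - 1) / 2
  m <- matrix(0, n, n)
  inside <- (row(m) - 1 - cy)^2 + (col(m) - 1 - cx)^2 <= r^2
  m[inside] <- v
  m
}

disk_mask <- function(n, r) {
  cy <- (n - 1) / 2; cx <- (n - 1) / 2
  m <- matrix(0, n, n)
  (row(m) - 1 - cy)^2 + (col(m) - 1 - cx)^2 <= r^2
}

# a small non-trivial basis used across decomposition tests
test_basis <- function() basis2x2(mu1H = 2, mu2H = 1, mu1L = 1, mu2L = 1)

# tiny network configuration: full spatial arithmetic, 1/16 channels
tiny_config <- function(epochs = 1L, batch_size = 8L, seed = 1L) {
  fcn_config(channel_scale = 1 / 16, epochs = epochs,
             batch_size = batch_size, seed = seed)
}

# patch_set holding one repeated patch pair
repeated_patch_set <- function(n = 8L, seed = 1L) {
  withr::with_seed(seed, {
    pl <- matrix(runif(65 * 65), 65)
    ph <- matrix(runif(65 * 65), 65)
  })
  structure(list(low = array(rep(pl, n), c(65, 65, n)),
                 high = array(rep(ph, n), c(65, 65, n)),
                 labels = matrix(rep(c(0.8, 1.2), each = n), n),
                 patch_side = 65L, stride = 5L),
            class = "patch_set")
}
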