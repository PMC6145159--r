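#' Configuration of the two-branch convolutional decomposer
#'
#' Each energy branch is a stack of four convolutional layers with
#' rectified-linear activations: 5x5 kernels with stride 2 ("same"-style
#' ceiling-division padding) in layers 1-3, and a 9x9 stride-1 unpadded
#' layer 4 that collapses the remaining 9x9 map into a feature vector.
#' At full size the channel counts are 64 / 128 / 256 / 512 per layer, so
#' a 65x65 input patch maps through 33x33x64, 17x17x128, 9x9x256 to a
#' 512-length feature vector; the two branch vectors are concatenated and
#' a linear head maps the joint 1024-vector to the two material
#' coefficients.  `channel_scale` multiplies every channel count for
#' desk-scale training while preserving the spatial arithmetic.
#'
#' @param channel_scale Channel multiplier in `(0, 1]` (default 1).
#' @param epochs Training epochs.
#' @param batch_size Samples per optimizer step (default 1200).
#' @param base_lr Base learning rate (default `5e-3`).
#' @param lr_decay Exponential decay factor applied per epoch
#'   (default 0.9), so the rate at epoch `e` (1-based) is
#'   `base_lr * lr_decay^(e - 1)`.
#' @param seed Seed for weight initialization and batch shuffling.
#' @return An `fcn_config` object.
#' @export
fcn_config <- function(channel_scale = 1, epochs = 40L, batch_size = 1200L,
                       base_lr = 5e-3, lr_decay = 0.9, seed = 1L) {
  if (channel_scale <= 0 || channel_scale > 1)
    stop("`channel_scale` must lie in (0, 1]", call. = FALSE)
  stop_if_not_scalar_count(epochs, "epochs", 1L)
  stop_if_not_scalar_count(batch_size, "batch_size", 1L)
  structure(list(
    patch_side = 65L,
    kernels = c(5L, 5L, 5L, 9L),
    strides = c(2L, 2L, 2L, 1L),
    padding = c("same", "same", "same", "valid"),
    base_channels = c(64L, 128L, 256L, 512L),
    channels = pmax(1L, as.integer(round(c(64, 128, 256, 512) *
                                           channel_scale))),
    channel_scale = channel_scale,
    epochs = as.integer(epochs), batch_size = as.integer(batch_size),
    base_lr = base_lr, lr_decay = lr_decay, seed = as.integer(seed)),
    class = "fcn_config")
}

conv_out_side <- function(side, k, stride, padding) {
  if (padding == "same") as.integer(ceiling(side / stride))
  else as.integer(floor((side - k) / stride) + 1L)
}

pad_before_for <- function(side, out, k, stride, padding) {
  if (padding == "valid") return(0L)
  as.integer(max((out - 1L) * stride + k - side, 0L) %/% 2L)
}

#' Layer-by-layer shape report of one branch
#'
#' Propagates a `patch_side` x `patch_side` x 1 input through the four
#' convolutional layers under the configured kernel / stride / padding
#' conventions.
#'
#' @param config An [fcn_config()].
#' @return A tibble with columns `layer`, `kernel`, `stride`, `out_side`,
#'   `channels`.
#' @export
shape_report <- function(config = fcn_config()) {
  side <- config$patch_side
  sides <- integer(4)
  for (l in 1:4) {
    side <- conv_out_side(side, config$kernels[l], config$strides[l],
                          config$padding[l])
    sides[l] <- side
  }
  tibble(layer = paste0("conv", 1:4), kernel = config$kernels,
         stride = config$strides, out_side = sides,
         channels = config$channels)
}

# ---- patch extraction ------------------------------------------------------

patch_grid <- function(extent, side, stride) {
  if (extent < side)
    stop("image smaller than one patch", call. = FALSE)
  seq.int(1L, extent - side + 1L, by = stride)
}

#' Extract co-registered training patch pairs
#'
#' Slides a `patch_side` window with the given stride over the dual-energy
#' image; every placement yields a (low patch, high patch, label) triple,
#' the label being the true coefficient pair at the patch center pixel.
#'
#' @param img A [dual_energy_image()].
#' @param truth The aligned ground-truth [material_image()].
#' @param patch_side Patch side in pixels (default 65).
#' @param stride Sliding interval in pixels (default 5).
#' @param pad With `pad = FALSE` (default) every patch lies fully inside
#'   the image, so patch centers only cover its interior.  With
#'   `pad = TRUE` the images are reflection-padded by half a patch first
#'   and the stride grid runs over all pixel positions, so patch centers
#'   cover the full image — the same border convention that
#'   [decompose_image()] uses at inference.
#' @return A `patch_set`: list with arrays `low` and `high` of dimension
#'   `(patch_side, patch_side, n)` and an `n x 2` matrix `labels`.
#' @export
extract_patches <- function(img, truth, patch_side = 65L, stride = 5L,
                            pad = FALSE) {
  if (!identical(dim(img$mu_L), dim(truth$x1)))
    stop("image and truth must be aligned", call. = FALSE)
  half <- (patch_side - 1L) %/% 2L
  h <- nrow(img$mu_L); w <- ncol(img$mu_L)
  if (pad) {
    ri <- mirror_seq(h, half); ci <- mirror_seq(w, half)
    muL <- img$mu_L[ri, ci]; muH <- img$mu_H[ri, ci]
    rows <- seq.int(1L, h, by = stride)   # patch start in padded = center
    cols <- seq.int(1L, w, by = stride)
    center_off <- 0L
  } else {
    muL <- img$mu_L; muH <- img$mu_H
    rows <- patch_grid(h, patch_side, stride)
    cols <- patch_grid(w, patch_side, stride)
    center_off <- half
  }
  n <- length(rows) * length(cols)
  low <- array(0, c(patch_side, patch_side, n))
  high <- array(0, c(patch_side, patch_side, n))
  labels <- matrix(0, n, 2)
  i <- 0L
  for (c0 in cols) for (r0 in rows) {
    i <- i + 1L
    rr <- r0:(r0 + patch_side - 1L); cc <- c0:(c0 + patch_side - 1L)
    low[, , i] <- muL[rr, cc]
    high[, , i] <- muH[rr, cc]
    labels[i, ] <- c(truth$x1[r0 + center_off, c0 + center_off],
                     truth$x2[r0 + center_off, c0 + center_off])
  }
  structure(list(low = low, high = high, labels = labels,
                 patch_side = as.integer(patch_side),
                 stride = as.integer(stride)),
            class = "patch_set")
}

#' Extract patch pairs centered on chosen pixels
#'
#' Like [extract_patches()] with `pad = TRUE`, but the patch centers are
#' given explicitly instead of lying on a stride grid.  Useful for
#' composing class-balanced training sets when one material occupies only
#' a small fraction of the image.
#'
#' @param img A [dual_energy_image()].
#' @param truth The aligned ground-truth [material_image()].
#' @param centers Two-column matrix of (row, col) center pixels.
#' @param patch_side Patch side in pixels (default 65).
#' @return A `patch_set`.
#' @export
extract_patches_at <- function(img, truth, centers, patch_side = 65L) {
  if (!identical(dim(img$mu_L), dim(truth$x1)))
    stop("image and truth must be aligned", call. = FALSE)
  centers <- as.matrix(centers)
  if (ncol(centers) != 2L || nrow(centers) < 1L)
    stop("`centers` must be a non-empty (row, col) matrix", call. = FALSE)
  half <- (patch_side - 1L) %/% 2L
  h <- nrow(img$mu_L); w <- ncol(img$mu_L)
  ri <- mirror_seq(h, half); ci <- mirror_seq(w, half)
  muL <- img$mu_L[ri, ci]; muH <- img$mu_H[ri, ci]
  n <- nrow(centers)
  low <- array(0, c(patch_side, patch_side, n))
  high <- array(0, c(patch_side, patch_side, n))
  labels <- matrix(0, n, 2)
  for (i in seq_len(n)) {
    r0 <- centers[i, 1]; c0 <- centers[i, 2]   # padded start == center
    rr <- r0:(r0 + patch_side - 1L); cc <- c0:(c0 + patch_side - 1L)
    low[, , i] <- muL[rr, cc]
    high[, , i] <- muH[rr, cc]
    labels[i, ] <- c(truth$x1[r0, c0], truth$x2[r0, c0])
  }
  structure(list(low = low, high = high, labels = labels,
                 patch_side = as.integer(patch_side), stride = NA_integer_),
            class = "patch_set")
}

#' @export
print.patch_set <- function(x, ...) {
  cat(sprintf("<patch_set> %d pairs of %dx%d patches (stride %d)\n",
              dim(x$low)[3], x$patch_side, x$patch_side, x$stride))
  invisible(x)
}

merge_patch_sets <- function(sets) {
  structure(list(
    low = array(unlist(lapply(sets, `[[`, "low")),
                c(dim(sets[[1]]$low)[1:2], sum(vapply(sets, function(s)
                  dim(s$low)[3], 1L)))),
    high = array(unlist(lapply(sets, `[[`, "high")),
                 c(dim(sets[[1]]$high)[1:2], sum(vapply(sets, function(s)
                   dim(s$high)[3], 1L)))),
    labels = do.call(rbind, lapply(sets, `[[`, "labels")),
    patch_side = sets[[1]]$patch_side, stride = sets[[1]]$stride),
    class = "patch_set")
}

# ---- network parameters ----------------------------------------------------

branch_layer_dims <- function(config) {
  side <- config$patch_side
  cin <- 1L
  dims <- vector("list", 4)
  for (l in 1:4) {
    out <- conv_out_side(side, config$kernels[l], config$strides[l],
                         config$padding[l])
    dims[[l]] <- list(
      k = config$kernels[l], stride = config$strides[l],
      cin = cin, cout = config$channels[l], in_side = side, out_side = out,
      pad_before = pad_before_for(side, out, config$kernels[l],
                                  config$strides[l], config$padding[l]))
    side <- out
    cin <- config$channels[l]
  }
  dims
}

init_branch <- function(dims) {
  lapply(dims, function(d) {
    fan_in <- d$k^2 * d$cin
    list(W = matrix(rnorm(d$cout * fan_in, sd = sqrt(2 / fan_in)),
                    d$cout, fan_in),
         b = numeric(d$cout))
  })
}

#' Initialize a two-branch network
#'
#' Seeded He-style Gaussian initialization of both branch stacks and the
#' linear head.
#'
#' @param config An [fcn_config()].
#' @return An `fcn_network` object (untrained).
#' @export
fcn_init <- function(config = fcn_config()) {
  dims <- branch_layer_dims(config)
  feat <- dims[[4]]$cout
  withr::with_seed(config$seed, {
    params <- list(
      L = init_branch(dims), H = init_branch(dims),
      # small head init: predictions start near zero, so early steps fit
      # the coefficient scale instead of unwinding a large random output
      Wc = matrix(rnorm(2 * 2 * feat, sd = 0.01), 2, 2 * feat),
      bc = numeric(2))
  })
  structure(list(config = config, dims = dims, params = params,
                 norm = list(center = c(L = 0, H = 0),
                             scale = c(L = 1, H = 1)),
                 history = NULL), class = "fcn_network")
}

#' @export
print.fcn_network <- function(x, ...) {
  np <- n_parameters(x)
  cat(sprintf(
    "<fcn_network> channel_scale %.3g, %s parameters, %s\n",
    x$config$channel_scale, format(np, big.mark = ","),
    if (is.null(x$history)) "untrained"
    else sprintf("trained %d epochs (final loss %.4g)",
                 nrow(x$history), x$history$loss[nrow(x$history)])))
  invisible(x)
}

n_parameters <- function(network) {
  p <- network$params
  sum(vapply(c(p$L, p$H), function(l) length(l$W) + length(l$b), 1)) +
    length(p$Wc) + length(p$bc)
}

# ---- forward / backward ----------------------------------------------------

# One branch forward: x is an array (H, W, 1, B).  Layer inputs and ReLU
# outputs are cached for the backward pass (the output's positivity pattern
# doubles as the activation mask).
branch_forward <- function(x, branch, dims, keep_cache = FALSE) {
  caches <- vector("list", 4)
  for (l in 1:4) {
    d <- dims[[l]]
    dm <- dim(x)
    out <- .cpp_conv_fwd(x, branch[[l]]$W, branch[[l]]$b,
                         dm[1], dm[2], dm[3], dm[4], d$k, d$stride,
                         d$pad_before, d$out_side, d$out_side)
    if (keep_cache) caches[[l]] <- list(x = x, out = out)
    x <- out
  }
  B <- dim(x)[4]
  feat <- matrix(x, dims[[4]]$cout, B)  # conv4 output is 1 x 1 spatially
  list(feat = feat, caches = caches)
}

branch_backward <- function(dfeat, branch, dims, caches) {
  B <- ncol(dfeat)
  dout <- array(dfeat, c(1L, 1L, nrow(dfeat), B))
  grads <- vector("list", 4)
  for (l in 4:1) {
    d <- dims[[l]]
    cache <- caches[[l]]
    dm <- dim(cache$x)
    r <- .cpp_conv_bwd(cache$x, branch[[l]]$W, cache$out, dout,
                       dm[1], dm[2], dm[3], dm[4], d$k, d$stride,
                       d$pad_before, d$out_side, d$out_side, l > 1L)
    grads[[l]] <- list(W = r$W, b = r$b)
    if (l > 1L) dout <- r$dx
  }
  grads
}

as_patch_array <- function(p) {
  if (is.matrix(p)) p <- array(p, c(dim(p), 1L))
  if (length(dim(p)) != 3L)
    stop("patches must be a matrix or (side, side, n) array", call. = FALSE)
  array(p, c(dim(p)[1], dim(p)[2], 1L, dim(p)[3]))
}

#' Evaluate the network on patch pairs
#'
#' Runs the low-energy patches through the L branch and the high-energy
#' patches through the H branch, concatenates the two feature vectors and
#' applies the linear head.
#'
#' @param network An [fcn_init()] or [fcn_train()] network.
#' @param patch_L,patch_H A `side x side` matrix or a
#'   `(side, side, n)` array of patches.
#' @return An `n x 2` matrix of predicted `(x1, x2)` pairs (a length-2
#'   vector for single-matrix input).
#' @export
fcn_forward <- function(network, patch_L, patch_H) {
  single <- is.matrix(patch_L)
  xl <- as_patch_array(patch_L); xh <- as_patch_array(patch_H)
  side <- network$config$patch_side
  if (any(dim(xl)[1:2] != side) || any(dim(xh)[1:2] != side))
    stop(sprintf("patches must be %d x %d", side, side), call. = FALSE)
  nrm <- network$norm
  xl <- (xl - nrm$center[["L"]]) / nrm$scale[["L"]]
  xh <- (xh - nrm$center[["H"]]) / nrm$scale[["H"]]
  fl <- branch_forward(xl, network$params$L, network$dims)$feat
  fh <- branch_forward(xh, network$params$H, network$dims)$feat
  X <- network$params$Wc %*% rbind(fl, fh) + network$params$bc
  if (single) drop(X) else t(X)
}

# ---- training --------------------------------------------------------------

flatten_params <- function(p) {
  out <- list()
  for (br in c("L", "H")) for (l in 1:4) {
    out[[paste0(br, l, "W")]] <- p[[br]][[l]]$W
    out[[paste0(br, l, "b")]] <- p[[br]][[l]]$b
  }
  out$Wc <- p$Wc; out$bc <- p$bc
  out
}

unflatten_params <- function(flat, template) {
  for (br in c("L", "H")) for (l in 1:4) {
    template[[br]][[l]]$W <- flat[[paste0(br, l, "W")]]
    template[[br]][[l]]$b <- flat[[paste0(br, l, "b")]]
  }
  template$Wc <- flat$Wc; template$bc <- flat$bc
  template
}

# forward + backward over one chunk; returns loss sum and flat gradients of
# the summed half-squared error divided by n_batch.
fcn_chunk_grads <- function(params, dims, xl, xh, y, n_batch) {
  rl <- branch_forward(xl, params$L, dims, keep_cache = TRUE)
  rh <- branch_forward(xh, params$H, dims, keep_cache = TRUE)
  M <- rbind(rl$feat, rh$feat)
  X <- params$Wc %*% M + params$bc
  resid <- X - t(y)
  loss_sum <- 0.5 * sum(resid^2)
  dX <- resid / n_batch
  feat <- nrow(rl$feat)
  dM <- crossprod(params$Wc, dX)
  gL <- branch_backward(dM[seq_len(feat), , drop = FALSE], params$L, dims,
                        rl$caches)
  gH <- branch_backward(dM[feat + seq_len(feat), , drop = FALSE], params$H,
                        dims, rh$caches)
  flat <- list()
  for (l in 1:4) {
    flat[[paste0("L", l, "W")]] <- gL[[l]]$W
    flat[[paste0("L", l, "b")]] <- gL[[l]]$b
    flat[[paste0("H", l, "W")]] <- gH[[l]]$W
    flat[[paste0("H", l, "b")]] <- gH[[l]]$b
  }
  flat$Wc <- dX %*% t(M)
  flat$bc <- rowSums(dX)
  list(loss_sum = loss_sum, grads = flat)
}

#' Train the two-branch decomposer
#'
#' Minimizes the mean over each batch of `0.5 * ||X - label||^2` with the
#' adaptive-moment (Adam) optimizer.  The learning rate starts at
#' `base_lr` and is multiplied by `lr_decay` after every epoch.  Weight
#' initialization and shuffling are driven by `config$seed`, so two runs
#' with the same seed produce identical loss histories.
#'
#' @param patches A [extract_patches()] `patch_set` (or several merged).
#' @param config An [fcn_config()].
#' @param chunk_size Internal forward/backward chunk (memory knob, no
#'   effect on results beyond floating-point summation order).
#' @param verbose Print per-epoch loss.
#' @return A trained `fcn_network` whose `history` field is a tibble with
#'   columns `epoch`, `loss` (mean per-sample loss) and `lr`.
#' @export
fcn_train <- function(patches, config = fcn_config(), chunk_size = 128L,
                      verbose = FALSE) {
  n <- dim(patches$low)[3]
  if (is.null(n) || n < 1L) stop("empty training set", call. = FALSE)
  network <- fcn_init(config)
  dims <- network$dims
  # standardize each energy channel over the training patches; the same
  # affine is applied by every later forward pass through this network
  network$norm <- list(
    center = c(L = mean(patches$low), H = mean(patches$high)),
    scale = c(L = max(stats::sd(patches$low), 1e-8),
              H = max(stats::sd(patches$high), 1e-8)))
  flat <- flatten_params(network$params)
  m <- lapply(flat, function(x) x * 0)
  v <- lapply(flat, function(x) x * 0)
  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
  t_step <- 0L
  history <- vector("list", config$epochs)

  low <- array((patches$low - network$norm$center[["L"]]) /
                 network$norm$scale[["L"]], c(dim(patches$low)[1:2], 1L, n))
  high <- array((patches$high - network$norm$center[["H"]]) /
                  network$norm$scale[["H"]], c(dim(patches$high)[1:2], 1L, n))

  withr::with_seed(config$seed + 1L, {
    for (epoch in seq_len(config$epochs)) {
      lr <- config$base_lr * config$lr_decay^(epoch - 1L)
      perm <- sample.int(n)
      loss_total <- 0
      start <- 1L
      while (start <= n) {
        idx <- perm[start:min(start + config$batch_size - 1L, n)]
        nb <- length(idx)
        params <- unflatten_params(flat, network$params)
        grads <- NULL
        cstart <- 1L
        while (cstart <= nb) {
          cidx <- idx[cstart:min(cstart + chunk_size - 1L, nb)]
          r <- fcn_chunk_grads(params, dims,
                               low[, , , cidx, drop = FALSE],
                               high[, , , cidx, drop = FALSE],
                               patches$labels[cidx, , drop = FALSE], nb)
          loss_total <- loss_total + r$loss_sum
          grads <- if (is.null(grads)) r$grads
                   else mapply(`+`, grads, r$grads, SIMPLIFY = FALSE)
          cstart <- cstart + chunk_size
        }
        t_step <- t_step + 1L
        for (nm in names(flat)) {
          m[[nm]] <- beta1 * m[[nm]] + (1 - beta1) * grads[[nm]]
          v[[nm]] <- beta2 * v[[nm]] + (1 - beta2) * grads[[nm]]^2
          mhat <- m[[nm]] / (1 - beta1^t_step)
          vhat <- v[[nm]] / (1 - beta2^t_step)
          flat[[nm]] <- flat[[nm]] - lr * mhat / (sqrt(vhat) + eps)
        }
        start <- start + config$batch_size
      }
      history[[epoch]] <- tibble(epoch = epoch, loss = loss_total / n,
                                 lr = lr)
      if (verbose)
        message(sprintf("epoch %d: loss %.5g (lr %.4g)", epoch,
                        loss_total / n, lr))
    }
  })
  network$params <- unflatten_params(flat, network$params)
  network$history <- do.call(rbind, history)
  network
}

#' Per-epoch learning-rate schedule
#'
#' @param config An [fcn_config()].
#' @return Numeric vector of length `epochs`:
#'   `base_lr * lr_decay^(epoch - 1)`.
#' @export
lr_schedule <- function(config) {
  config$base_lr * config$lr_decay^(seq_len(config$epochs) - 1L)
}

# ---- whole-image decomposition ---------------------------------------------

mirror_seq <- function(n, pad) {
  k <- (1 - pad):(n + pad)
  m <- ((k - 1) %% (2 * n) + 2 * n) %% (2 * n)
  ifelse(m < n, m + 1, 2 * n - m)
}

#' Decompose a dual-energy image pixel by pixel
#'
#' Evaluates the trained network on the `patch_side` neighborhood centered
#' on every pixel (the input images are reflection-padded at the borders),
#' so the output coefficient maps have exactly the input dimensions.
#'
#' @param network A trained `fcn_network`.
#' @param img A [dual_energy_image()] of any size.
#' @param pixels Optional logical mask of pixels to evaluate; others are
#'   returned as `NA` (useful when only ROI metrics are needed).
#' @param chunk_size Patches evaluated per forward pass.
#' @return A [material_image()] (values unconstrained; `NA` outside
#'   `pixels` if a mask was given).
#' @export
decompose_image <- function(network, img, pixels = NULL, chunk_size = 256L) {
  side <- network$config$patch_side
  half <- (side - 1L) %/% 2L
  h <- nrow(img$mu_L); w <- ncol(img$mu_L)
  ri <- mirror_seq(h, half); ci <- mirror_seq(w, half)
  padL <- img$mu_L[ri, ci]; padH <- img$mu_H[ri, ci]
  if (is.null(pixels)) {
    targets <- cbind(rep(seq_len(h), w), rep(seq_len(w), each = h))
  } else {
    if (!is.logical(pixels) || !identical(dim(pixels), c(h, w)))
      stop("`pixels` must be a logical mask matching the image",
           call. = FALSE)
    targets <- which(pixels, arr.ind = TRUE)
  }
  x1 <- matrix(NA_real_, h, w); x2 <- matrix(NA_real_, h, w)
  n <- nrow(targets)
  start <- 1L
  while (start <= n) {
    idx <- start:min(start + chunk_size - 1L, n)
    nb <- length(idx)
    pl <- array(0, c(side, side, nb)); ph <- array(0, c(side, side, nb))
    for (j in seq_len(nb)) {
      r0 <- targets[idx[j], 1]; c0 <- targets[idx[j], 2]
      rr <- r0:(r0 + side - 1L); cc <- c0:(c0 + side - 1L)
      pl[, , j] <- padL[rr, cc]; ph[, , j] <- padH[rr, cc]
    }
    pred <- fcn_forward(network, pl, ph)
    x1[targets[idx, , drop = FALSE]] <- pred[, 1]
    x2[targets[idx, , drop = FALSE]] <- pred[, 2]
    start <- start + chunk_size
  }
  structure(list(x1 = x1, x2 = x2, pixel_size = img$pixel_size),
            class = "material_image")
}

# ---- broom-style summaries -------------------------------------------------

#' @export
tidy.fcn_network <- function(x, ...) {
  rows <- list()
  for (br in c("L", "H")) for (l in 1:4) {
    d <- x$dims[[l]]
    rows[[paste0(br, l)]] <- tibble(
      branch = br, layer = paste0("conv", l), kernel = d$k,
      stride = d$stride, out_side = d$out_side, channels = d$cout,
      n_weights = length(x$params[[br]][[l]]$W),
      n_biases = length(x$params[[br]][[l]]$b))
  }
  rows$head <- tibble(branch = "joint", layer = "fc", kernel = NA_integer_,
                      stride = NA_integer_, out_side = 1L, channels = 2L,
                      n_weights = length(x$params$Wc),
                      n_biases = length(x$params$bc))
  do.call(rbind, rows)
}

#' @export
glance.fcn_network <- function(x, ...) {
  trained <- !is.null(x$history)
  tibble(
    n_parameters = n_parameters(x),
    channel_scale = x$config$channel_scale,
    epochs = if (trained) nrow(x$history) else 0L,
    initial_loss = if (trained) x$history$loss[1] else NA_real_,
    final_loss = if (trained) x$history$loss[nrow(x$history)] else NA_real_,
    final_lr = if (trained) x$history$lr[nrow(x$history)] else NA_real_)
}
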