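#' Basis-material coefficient maps
#'
#' A `material_image` holds the per-pixel coefficients of the two basis
#' materials used throughout the package: `x1` for soft tissue and `x2` for
#' bone.  For ground-truth phantoms the two partitions are disjoint
#' (`x1 * x2 == 0` pixel-wise) and non-negative; maps predicted by a
#' decomposer carry no such constraint.
#'
#' @param x1 Numeric matrix of tissue coefficients (dimensionless).
#' @param x2 Numeric matrix of bone coefficients, same dimensions as `x1`.
#' @param pixel_size Physical pixel width in cm.
#' @return An object of class `material_image` with fields `x1`, `x2`,
#'   `pixel_size`.
#' @export
material_image <- function(x1, x2, pixel_size = 0.1) {
  x1 <- as.matrix(x1); x2 <- as.matrix(x2)
  if (!identical(dim(x1), dim(x2)))
    stop("`x1` and `x2` must have identical dimensions", call. = FALSE)
  if (!all(is.finite(x1)) || !all(is.finite(x2)))
    stop("coefficient maps must be finite", call. = FALSE)
  if (!is.numeric(pixel_size) || length(pixel_size) != 1L || pixel_size <= 0)
    stop("`pixel_size` must be a positive scalar (cm)", call. = FALSE)
  structure(list(x1 = x1, x2 = x2, pixel_size = pixel_size),
            class = "material_image")
}

#' @export
print.material_image <- function(x, ...) {
  cat(sprintf(
    "<material_image> %d x %d pixels (%.3g cm/px)\n", nrow(x$x1),
    ncol(x$x1), x$pixel_size))
  cat(sprintf("  tissue x1: range [%.4g, %.4g], nonzero %d px\n",
              min(x$x1), max(x$x1), sum(x$x1 != 0)))
  cat(sprintf("  bone   x2: range [%.4g, %.4g], nonzero %d px\n",
              min(x$x2), max(x$x2), sum(x$x2 != 0)))
  invisible(x)
}

#' @export
dim.material_image <- function(x) dim(x$x1)

#' Value-transform parameters
#'
#' Scale factors applied to raw single-energy pixel values to bring the
#' tissue and bone partitions into a convenient numeric range before they
#' are used as decomposition ground truth.  Defaults are 50 for tissue and
#' 15 for bone.
#'
#' @param lambda_t Tissue scale factor (> 0).
#' @param lambda_b Bone scale factor (> 0).
#' @return A `transform_params` object.
#' @export
transform_params <- function(lambda_t = 50, lambda_b = 15) {
  if (lambda_t <= 0 || lambda_b <= 0)
    stop("scale factors must be positive", call. = FALSE)
  structure(list(lambda_t = lambda_t, lambda_b = lambda_b),
            class = "transform_params")
}

#' Apply the linear value transform to raw partition images
#'
#' Multiplies the raw tissue partition by `lambda_t` and the raw bone
#' partition by `lambda_b`, element-wise, producing the coefficient maps
#' used as decomposition ground truth.
#'
#' @param raw_tissue,raw_bone Numeric matrices of identical dimensions.
#' @param params A [transform_params()] object.
#' @param pixel_size Pixel width in cm for the returned image.
#' @return A [material_image()].
#' @export
apply_value_transform <- function(raw_tissue, raw_bone,
                                  params = transform_params(),
                                  pixel_size = 0.1) {
  raw_tissue <- as.matrix(raw_tissue); raw_bone <- as.matrix(raw_bone)
  if (!identical(dim(raw_tissue), dim(raw_bone)))
    stop("raw partition images must share dimensions", call. = FALSE)
  material_image(params$lambda_t * raw_tissue, params$lambda_b * raw_bone,
                 pixel_size = pixel_size)
}

# Filled-ellipse mask on an H x W pixel grid (0-based centers).
ellipse_mask <- function(h, w, cy, cx, ry, rx, theta = 0) {
  row <- matrix(seq_len(h) - 1, h, w)
  col <- matrix(seq_len(w) - 1, h, w, byrow = TRUE)
  dy <- row - cy; dx <- col - cx
  u <- cos(theta) * dx + sin(theta) * dy
  v <- -sin(theta) * dx + cos(theta) * dy
  (u / rx)^2 + (v / ry)^2 <= 1
}

#' Generate a seeded synthetic phantom
#'
#' Builds a 2D phantom with disjoint tissue and bone partitions from
#' analytic shapes: large smooth ellipses for soft tissue, and thin
#' elliptical annuli (skull-like rings) or small dense ellipses (rib-like
#' inserts) for bone.  Raw values are drawn near 0.02 for tissue and
#' 0.05-0.09 for bone and then passed through the value transform so that
#' transformed coefficients land near 1.  Bone takes precedence where
#' shapes overlap, which keeps the two partitions disjoint.
#'
#' @param height,width Image dimensions in pixels; at least 65 (one network
#'   input patch).
#' @param n_bone,n_tissue Number of bone / tissue structures (>= 0).
#' @param seed Integer seed; identical arguments and seed give bit-identical
#'   phantoms.
#' @param params Value-transform parameters, see [transform_params()].
#' @param pixel_size Pixel width in cm.
#' @return A [material_image()] ground-truth phantom.
#' @export
generate_phantom <- function(height, width, n_bone = 2L, n_tissue = 1L,
                             seed = 1L, params = transform_params(),
                             pixel_size = 0.1) {
  stop_if_not_scalar_count(height, "height", 1L)
  stop_if_not_scalar_count(width, "width", 1L)
  if (height < 65 || width < 65)
    stop("phantom dimensions must be at least 65 pixels ",
         "(one network input patch)", call. = FALSE)
  stop_if_not_scalar_count(n_bone, "n_bone")
  stop_if_not_scalar_count(n_tissue, "n_tissue")

  raw_t <- matrix(0, height, width)
  bone_mask <- matrix(FALSE, height, width)
  raw_b <- matrix(0, height, width)

  withr::with_seed(as.integer(seed), {
    side <- min(height, width)
    cy0 <- (height - 1) / 2; cx0 <- (width - 1) / 2
    tissue_masks <- vector("list", n_tissue)
    for (i in seq_len(n_tissue)) {
      cy <- cy0 + runif(1, -0.08, 0.08) * side
      cx <- cx0 + runif(1, -0.08, 0.08) * side
      ry <- runif(1, 0.26, 0.40) * side
      rx <- runif(1, 0.26, 0.40) * side
      th <- runif(1, 0, pi)
      m <- ellipse_mask(height, width, cy, cx, ry, rx, th)
      raw_t[m] <- runif(1, 0.018, 0.022)
      tissue_masks[[i]] <- list(cy = cy, cx = cx, ry = ry, rx = rx, th = th)
    }
    for (i in seq_len(n_bone)) {
      annulus <- n_tissue > 0 && (i %% 2L == 1L)
      if (annulus) {
        # ring hugging the boundary of a tissue ellipse, like a skull
        host <- tissue_masks[[1L + (i - 1L) %% n_tissue]]
        thick <- runif(1, 0.035, 0.06) * side
        outer <- ellipse_mask(height, width, host$cy, host$cx,
                              host$ry + thick, host$rx + thick, host$th)
        inner <- ellipse_mask(height, width, host$cy, host$cx,
                              host$ry, host$rx, host$th)
        m <- outer & !inner
      } else {
        # small dense ellipse, like a rib cross-section
        cy <- runif(1, 0.2, 0.8) * (height - 1)
        cx <- runif(1, 0.2, 0.8) * (width - 1)
        m <- ellipse_mask(height, width, cy, cx,
                          runif(1, 0.03, 0.07) * side,
                          runif(1, 0.03, 0.07) * side, runif(1, 0, pi))
      }
      raw_b[m] <- runif(1, 0.05, 0.09)
      bone_mask <- bone_mask | m
    }
  })

  raw_t[bone_mask] <- 0  # bone wins: partitions are disjoint
  apply_value_transform(raw_t, raw_b, params, pixel_size = pixel_size)
}

#' Generate a seeded train/test phantom collection
#'
#' Draws `n_train + n_test` phantoms from independent sub-seeds derived from
#' one master seed, so the split is reproducible and no phantom appears in
#' both partitions.
#'
#' @param n_train,n_test Phantom counts (>= 1).
#' @param shape Length-2 vector `c(height, width)` in pixels.
#' @param seed Master seed.
#' @param n_bone,n_tissue Structure counts passed to [generate_phantom()].
#' @param ... Further arguments passed to [generate_phantom()].
#' @return A list with elements `train` and `test`, each a list of
#'   [material_image()] phantoms.
#' @export
make_dataset <- function(n_train, n_test, shape = c(128L, 128L), seed = 1L,
                         n_bone = 2L, n_tissue = 1L, ...) {
  stop_if_not_scalar_count(n_train, "n_train", 1L)
  stop_if_not_scalar_count(n_test, "n_test", 1L)
  gen <- function(index) {
    generate_phantom(shape[1], shape[2], n_bone = n_bone,
                     n_tissue = n_tissue, seed = sub_seed(seed, index), ...)
  }
  list(train = lapply(seq_len(n_train), gen),
       test = lapply(n_train + seq_len(n_test), gen))
}
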