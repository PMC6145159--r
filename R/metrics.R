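#' ROI bias of a decomposed coefficient map
#'
#' Mean deviation between predicted and true coefficients over a region of
#' interest.  By default the mean absolute deviation
#' `(1/N) * sum |x_i - xhat_i|` is reported; `signed = TRUE` gives the
#' plain signed mean instead.
#'
#' @param pred,truth Numeric matrices of identical dimensions.
#' @param roi Logical mask with at least one `TRUE` pixel.
#' @param signed Use the signed mean rather than the absolute convention.
#' @return Scalar bias in coefficient units.
#' @export
decomp_bias <- function(pred, truth, roi = NULL, signed = FALSE) {
  pred <- as.matrix(pred); truth <- as.matrix(truth)
  if (!identical(dim(pred), dim(truth)))
    stop("`pred` and `truth` must share dimensions", call. = FALSE)
  if (is.null(roi)) roi <- matrix(TRUE, nrow(pred), ncol(pred))
  check_roi(roi, dim(pred))
  d <- pred[roi] - truth[roi]
  if (signed) mean(d) else mean(abs(d))
}

#' ROI standard deviation of a decomposed coefficient map
#'
#' Dispersion of the predicted coefficients about their ROI mean:
#' `sqrt((1/N) * sum (x_i - mu)^2)` with `mu` the ROI mean (population
#' normalization).
#'
#' @param pred Numeric matrix.
#' @param roi Logical mask with at least one `TRUE` pixel.
#' @return Scalar standard deviation in coefficient units.
#' @export
decomp_sd <- function(pred, roi = NULL) {
  pred <- as.matrix(pred)
  if (is.null(roi)) roi <- matrix(TRUE, nrow(pred), ncol(pred))
  check_roi(roi, dim(pred))
  x <- pred[roi]
  sqrt(mean((x - mean(x))^2))
}

check_roi <- function(roi, dims) {
  if (!is.logical(roi) || !identical(dim(roi), dims))
    stop("`roi` must be a logical mask matching the image", call. = FALSE)
  if (!any(roi)) stop("empty ROI", call. = FALSE)
  invisible(roi)
}

#' Absolute difference between two material images
#'
#' @param a,b [material_image()]s of identical dimensions.
#' @return A [material_image()] holding `|a - b|` per map.
#' @export
difference_image <- function(a, b) {
  if (!identical(dim(a$x1), dim(b$x1)))
    stop("images must share dimensions", call. = FALSE)
  structure(list(x1 = abs(a$x1 - b$x1), x2 = abs(a$x2 - b$x2),
                 pixel_size = a$pixel_size),
            class = "material_image")
}

# Binary erosion by a (2r+1) square structuring element via shifting.
erode_mask <- function(mask, r = 2L) {
  out <- mask
  h <- nrow(mask); w <- ncol(mask)
  for (dr in -r:r) for (dc in -r:r) {
    ri <- pmin(pmax(seq_len(h) + dr, 1L), h)
    ci <- pmin(pmax(seq_len(w) + dc, 1L), w)
    out <- out & mask[ri, ci]
  }
  out
}

#' Material ROIs of a ground-truth phantom
#'
#' The disjoint material partitions of the phantom, eroded by a few pixels
#' so that reconstruction edge ringing does not leak into the metrics.
#'
#' @param phantom A ground-truth [material_image()].
#' @param erode Erosion radius in pixels (default 2).
#' @return List with logical masks `tissue` and `bone`.
#' @export
material_rois <- function(phantom, erode = 2L) {
  list(tissue = erode_mask(phantom$x1 > 0, erode),
       bone = erode_mask(phantom$x2 > 0, erode))
}

#' Bias and SD of a decomposition over the material ROIs
#'
#' @param pred Predicted [material_image()].
#' @param truth Ground-truth [material_image()].
#' @param rois List of logical masks as from [material_rois()]; defaults to
#'   the eroded partitions of `truth`.
#' @param signed Bias convention, see [decomp_bias()].
#' @return A tibble with one row per material: columns `material`, `bias`,
#'   `sd`, `n`.
#' @export
score_decomposition <- function(pred, truth, rois = material_rois(truth),
                                signed = FALSE) {
  maps <- list(tissue = list(p = pred$x1, t = truth$x1, roi = rois$tissue),
               bone = list(p = pred$x2, t = truth$x2, roi = rois$bone))
  do.call(rbind, lapply(names(maps), function(m) {
    z <- maps[[m]]
    tibble(material = m,
           bias = decomp_bias(z$p, z$t, z$roi, signed = signed),
           sd = decomp_sd(z$p, z$roi),
           n = sum(z$roi))
  }))
}
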