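#' Effective 2x2 basis of attenuation coefficients
#'
#' The four spectrum-averaged attenuation coefficients that link material
#' coefficients to dual-energy attenuation values:
#' `mu_H = mu1H * x1 + mu2H * x2` and `mu_L = mu1L * x1 + mu2L * x2`.
#' The determinant `delta = mu1H * mu2L - mu2H * mu1L` governs
#' invertibility; decomposition divides by it, so noise in the attenuation
#' images is amplified roughly as `1 / delta`.
#'
#' @param mu1H,mu2H,mu1L,mu2L Effective attenuation of material 1 (tissue)
#'   and material 2 (bone) under the high- and low-energy spectra, per unit
#'   material coefficient.
#' @param singular_tol Determinant magnitude below which the basis is
#'   treated as singular (default `1e-12`).
#' @return A `basis2x2` object with a `delta` field.
#' @export
basis2x2 <- function(mu1H, mu2H, mu1L, mu2L, singular_tol = 1e-12) {
  delta <- mu1H * mu2L - mu2H * mu1L
  structure(list(mu1H = mu1H, mu2H = mu2H, mu1L = mu1L, mu2L = mu2L,
                 delta = delta, singular_tol = singular_tol),
            class = "basis2x2")
}

#' @export
print.basis2x2 <- function(x, ...) {
  cat(sprintf("<basis2x2> H: (%.4g, %.4g)  L: (%.4g, %.4g)  delta = %.4g\n",
              x$mu1H, x$mu2H, x$mu1L, x$mu2L, x$delta))
  invisible(x)
}

check_invertible <- function(basis) {
  if (abs(basis$delta) <= basis$singular_tol)
    stop("singular basis: |delta| = ", format(abs(basis$delta)),
         " is at or below the tolerance ", format(basis$singular_tol),
         "; the 2x2 system cannot be solved", call. = FALSE)
  invisible(basis)
}

#' Estimate the basis from uniform regions of interest
#'
#' Mirrors the classical calibration procedure: the effective attenuation
#' of each basis material is read off as the mean of the low- and
#' high-energy images over a uniform ROI containing only that material.
#' ROI means are divided by the known material coefficient inside the ROI
#' so that the basis maps unit coefficient to attenuation.
#'
#' @param img A [dual_energy_image()].
#' @param roi_mat1,roi_mat2 Logical masks (same dimensions as the images)
#'   selecting uniform regions of material 1 (tissue) and material 2 (bone).
#' @param coef1,coef2 Known material coefficients inside the ROIs
#'   (default 1).
#' @param singular_tol Passed to [basis2x2()].
#' @return A [basis2x2()]; errors if a ROI is empty or the resulting
#'   determinant is at or below `singular_tol`.
#' @export
estimate_basis <- function(img, roi_mat1, roi_mat2, coef1 = 1, coef2 = 1,
                           singular_tol = 1e-12) {
  for (roi in list(roi_mat1, roi_mat2)) {
    if (!is.logical(roi) || !identical(dim(roi), dim(img$mu_H)))
      stop("ROIs must be logical masks matching the image", call. = FALSE)
    if (!any(roi)) stop("empty ROI", call. = FALSE)
  }
  b <- basis2x2(mu1H = mean(img$mu_H[roi_mat1]) / coef1,
                mu2H = mean(img$mu_H[roi_mat2]) / coef2,
                mu1L = mean(img$mu_L[roi_mat1]) / coef1,
                mu2L = mean(img$mu_L[roi_mat2]) / coef2,
                singular_tol = singular_tol)
  check_invertible(b)
}

#' Forward mixing model
#'
#' Composes material coefficient maps into dual-energy attenuation images:
#' `mu_H = mu1H * x1 + mu2H * x2`, `mu_L = mu1L * x1 + mu2L * x2`.
#'
#' @param mat A [material_image()].
#' @param basis A [basis2x2()].
#' @return A [dual_energy_image()].
#' @export
forward_mix <- function(mat, basis) {
  dual_energy_image(
    mu_L = basis$mu1L * mat$x1 + basis$mu2L * mat$x2,
    mu_H = basis$mu1H * mat$x1 + basis$mu2H * mat$x2,
    pixel_size = mat$pixel_size)
}

#' Direct decomposition by 2x2 matrix inversion
#'
#' Solves the mixing model pixel-wise:
#' `x1 = (mu2L * mu_H - mu2H * mu_L) / delta`,
#' `x2 = (-mu1L * mu_H + mu1H * mu_L) / delta`.
#' This is the exact algebraic inverse of [forward_mix()]; it is also the
#' decomposer most sensitive to noise, since every pixel is divided by the
#' (often small) determinant.
#'
#' @param img A [dual_energy_image()].
#' @param basis A [basis2x2()] with non-singular determinant.
#' @return A [material_image()] (values unconstrained in sign).
#' @export
invert_decompose <- function(img, basis) {
  check_invertible(basis)
  x1 <- (basis$mu2L * img$mu_H - basis$mu2H * img$mu_L) / basis$delta
  x2 <- (-basis$mu1L * img$mu_H + basis$mu1H * img$mu_L) / basis$delta
  structure(list(x1 = x1, x2 = x2, pixel_size = img$pixel_size),
            class = "material_image")
}

# 4-neighbor graph Laplacian applied to a map: L x = sum_neighbors (x - x_nb)
laplacian4 <- function(x) {
  h <- nrow(x); w <- ncol(x)
  up <- rbind(x[1, , drop = FALSE], x[-h, , drop = FALSE])
  dn <- rbind(x[-1, , drop = FALSE], x[h, , drop = FALSE])
  lf <- cbind(x[, 1, drop = FALSE], x[, -w, drop = FALSE])
  rt <- cbind(x[, -1, drop = FALSE], x[, w, drop = FALSE])
  4 * x - up - dn - lf - rt
}

#' Iterative decomposition with a quadratic smoothness prior
#'
#' A penalized least-squares comparator: minimizes, by gradient descent
#' with a fixed step equal to the reciprocal Lipschitz constant of the
#' objective,
#' `sum_pixels ||A x - mu||^2 + lambda * sum_4-neighbor (x_i - x_j)^2`
#' where `A` is the 2x2 basis matrix and the smoothness penalty acts on
#' both coefficient maps.  Iterations start from the matrix-inversion
#' solution, so `n_iter = 0` returns that solution and `lambda = 0`
#' leaves it unchanged (up to numerical convergence).  The quadratic
#' objective makes every iteration non-increasing.
#'
#' @param img A [dual_energy_image()].
#' @param basis A non-singular [basis2x2()].
#' @param smoothness_weight Penalty weight `lambda >= 0`.
#' @param n_iter Number of gradient steps (>= 0).
#' @return A [material_image()] with attribute `"objective"`: the objective
#'   value before each step and after the last (length `n_iter + 1`).
#' @export
iterative_decompose <- function(img, basis, smoothness_weight = 0.1,
                                n_iter = 50L) {
  check_invertible(basis)
  if (smoothness_weight < 0) stop("`smoothness_weight` must be >= 0",
                                  call. = FALSE)
  stop_if_not_scalar_count(n_iter, "n_iter")
  lam <- smoothness_weight
  A <- matrix(c(basis$mu1H, basis$mu1L, basis$mu2H, basis$mu2L), 2, 2)
  AtA <- crossprod(A)
  init <- invert_decompose(img, basis)
  x1 <- init$x1; x2 <- init$x2
  muH <- img$mu_H; muL <- img$mu_L

  objective <- function(x1, x2) {
    rH <- basis$mu1H * x1 + basis$mu2H * x2 - muH
    rL <- basis$mu1L * x1 + basis$mu2L * x2 - muL
    pen <- function(x) {
      dh <- x[-1, , drop = FALSE] - x[-nrow(x), , drop = FALSE]
      dv <- x[, -1, drop = FALSE] - x[, -ncol(x), drop = FALSE]
      sum(dh^2) + sum(dv^2)
    }
    sum(rH^2) + sum(rL^2) + lam * (pen(x1) + pen(x2))
  }

  # Lipschitz bound of the gradient: 2 (lambda_max(A'A) + 8 lambda)
  step <- 1 / (2 * (max(eigen(AtA, symmetric = TRUE,
                              only.values = TRUE)$values) + 8 * lam))
  obj <- numeric(n_iter + 1L)
  obj[1L] <- objective(x1, x2)
  for (it in seq_len(n_iter)) {
    rH <- basis$mu1H * x1 + basis$mu2H * x2 - muH
    rL <- basis$mu1L * x1 + basis$mu2L * x2 - muL
    g1 <- 2 * (basis$mu1H * rH + basis$mu1L * rL) + 2 * lam * laplacian4(x1)
    g2 <- 2 * (basis$mu2H * rH + basis$mu2L * rL) + 2 * lam * laplacian4(x2)
    x1 <- x1 - step * g1
    x2 <- x2 - step * g2
    obj[it + 1L] <- objective(x1, x2)
  }
  out <- structure(list(x1 = x1, x2 = x2, pixel_size = img$pixel_size),
                   class = "material_image")
  attr(out, "objective") <- obj
  out
}
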