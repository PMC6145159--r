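#' Sinogram container
#'
#' Log-projection (or path-length) data organized as angles by detector
#' bins, together with the acquisition geometry.
#'
#' @param values Numeric matrix, one row per projection angle.
#' @param angles Projection angles in degrees, strictly increasing within
#'   `[0, 180)`.
#' @param pixel_size Detector bin spacing in cm (equals the image pixel
#'   size in this parallel-beam geometry).
#' @param incident_photons Incident photon count per ray for noisy data, or
#'   `NULL` for noiseless sinograms.
#' @return A `sinogram` object.
#' @export
sinogram <- function(values, angles, pixel_size = 0.1,
                     incident_photons = NULL) {
  values <- as.matrix(values)
  if (!all(is.finite(values)))
    stop("sinogram values must be finite", call. = FALSE)
  if (length(angles) != nrow(values))
    stop("one angle per sinogram row required", call. = FALSE)
  if (any(angles < 0 | angles >= 180) || any(diff(angles) <= 0))
    stop("angles must be strictly increasing within [0, 180)", call. = FALSE)
  structure(list(values = values, angles = as.numeric(angles),
                 n_detectors = ncol(values), pixel_size = pixel_size,
                 incident_photons = incident_photons),
            class = "sinogram")
}

#' @export
print.sinogram <- function(x, ...) {
  cat(sprintf("<sinogram> %d angles x %d bins (%.3g cm spacing)%s\n",
              nrow(x$values), x$n_detectors, x$pixel_size,
              if (is.null(x$incident_photons)) "" else
                sprintf(", I = %g photons/ray", x$incident_photons)))
  invisible(x)
}

default_angles <- function(n_views = 180L) seq(0, 180, length.out = n_views + 1L)[-(n_views + 1L)]

#' Parallel-beam forward projection
#'
#' Line integrals of a square image over a set of view angles.  Detector
#' bins are spaced one pixel apart and centered on the image; rays are
#' sampled with bilinear interpolation at a quarter-pixel step, so the
#' operator is exactly linear in the image values.
#'
#' @param image Square numeric matrix.
#' @param angles Projection angles in degrees (default 180 views over
#'   `[0, 180)`).
#' @param pixel_size Pixel width in cm.
#' @param n_detectors Number of detector bins (default: image side).
#' @param oversample Integration substeps per pixel (default 4).
#' @return A [sinogram()] of line integrals (image units times cm).
#' @export
forward_project <- function(image, angles = default_angles(),
                            pixel_size = 0.1, n_detectors = nrow(image),
                            oversample = 4L) {
  image <- as.matrix(image)
  if (nrow(image) != ncol(image))
    stop("`image` must be square", call. = FALSE)
  if (length(angles) < 1L) stop("at least one angle required", call. = FALSE)
  vals <- .cpp_forward_project(image, angles * pi / 180, as.integer(n_detectors),
                               pixel_size, as.integer(oversample))
  sinogram(vals, angles, pixel_size = pixel_size)
}

#' Polyenergetic log projection from per-material path lengths
#'
#' Composes material path-length sinograms into the log projection
#' `p = -ln sum_b w_b exp(-mu_t(E_b) L_t - mu_b(E_b) L_b)` under the
#' Beer-Lambert law, element-wise over the sinogram.  With a single-bin
#' spectrum this reduces exactly to `mu(E) * L`; with a broad spectrum it
#' exhibits beam hardening (`p` sub-linear in thickness).
#'
#' @param tissue_path,bone_path [sinogram()]s of material path lengths
#'   (coefficient times cm), sharing geometry.
#' @param spectrum A [make_spectrum()] object.
#' @param model Attenuation model, see [default_attenuation_model()].
#' @return A [sinogram()] of log projections (dimensionless).
#' @export
polyenergetic_projection <- function(tissue_path, bone_path, spectrum,
                                     model = default_attenuation_model()) {
  if (!identical(dim(tissue_path$values), dim(bone_path$values)) ||
      !isTRUE(all.equal(tissue_path$angles, bone_path$angles)))
    stop("path sinograms must share geometry", call. = FALSE)
  mu_t <- mu_at(model, "tissue", spectrum$energies)
  mu_b <- mu_at(model, "bone", spectrum$energies)
  w <- spectrum$weights / sum(spectrum$weights)
  acc <- matrix(0, nrow(tissue_path$values), ncol(tissue_path$values))
  for (b in seq_along(w)) {
    acc <- acc + w[b] * exp(-mu_t[b] * tissue_path$values -
                              mu_b[b] * bone_path$values)
  }
  sinogram(-log(acc), tissue_path$angles, pixel_size = tissue_path$pixel_size)
}

#' Add Poisson photon noise to a log projection
#'
#' Replaces each log-projection element `p` by `ln I - ln g(I e^{-p})`
#' where `g(x)` is a Poisson draw with mean `x`: the detected photon count
#' fluctuates statistically around the Beer-Lambert expectation.  Draws of
#' zero photons are clamped to one before the logarithm, the minimal
#' intervention that keeps the transform defined.
#'
#' @param p A [sinogram()] of noiseless log projections.
#' @param incident Incident photon count per ray, `I > 0`.  Conventional
#'   settings are `5e5` for the low-energy and `1e6` for the high-energy
#'   channel.
#' @param seed Integer seed; fixed seed gives identical noise.
#' @return A noisy [sinogram()] with `incident_photons` recorded.
#' @export
add_photon_noise <- function(p, incident, seed = 1L) {
  if (!is.numeric(incident) || length(incident) != 1L || incident <= 0)
    stop("`incident` must be a positive photon count", call. = FALSE)
  lam <- incident * exp(-p$values)
  counts <- withr::with_seed(as.integer(seed),
                             rpois(length(lam), as.vector(lam)))
  counts <- pmax(counts, 1)  # clamp empty-detector draws to one photon
  vals <- matrix(log(incident) - log(counts), nrow(p$values), ncol(p$values))
  sinogram(vals, p$angles, pixel_size = p$pixel_size,
           incident_photons = incident)
}
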