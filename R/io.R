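# TIFF storage uses [0, 1]-scaled pages plus a YAML sidecar carrying the
# per-page affine (offset, scale) and the pixel size, so arbitrary-valued
# float maps survive the round trip exactly up to 32-bit precision.

write_paged_tiff <- function(pages, path, pixel_size, extra = list()) {
  scales <- lapply(pages, function(p) {
    rng <- range(p)
    span <- if (diff(rng) > 0) diff(rng) else 1
    list(offset = rng[1], scale = span)
  })
  scaled <- Map(function(p, s) (p - s$offset) / s$scale, pages, scales)
  suppressWarnings(tiff::writeTIFF(scaled, path, bits.per.sample = 32L,
                                   compression = "none"))
  meta <- c(list(pixel_size = pixel_size,
                 pages = lapply(scales, function(s)
                   list(offset = s$offset, scale = s$scale))),
            extra)
  yaml::write_yaml(meta, paste0(path, ".yaml"))
  invisible(path)
}

read_paged_tiff <- function(path) {
  meta <- yaml::read_yaml(paste0(path, ".yaml"))
  pages <- tiff::readTIFF(path, all = TRUE)
  pages <- Map(function(p, s) p * s$scale + s$offset, pages, meta$pages)
  list(pages = pages, meta = meta)
}

#' Write / read a material image as multi-page TIFF
#'
#' Page 0 holds the tissue map and page 1 the bone map.  Values are
#' rescaled to the unit interval for storage; the affine transform and the
#' pixel size live in a YAML sidecar next to the TIFF.
#'
#' @param mat A [material_image()].
#' @param path Output path (`.tif`).
#' @return `path`, invisibly (writer); a [material_image()] (reader).
#' @export
write_material_tiff <- function(mat, path) {
  write_paged_tiff(list(mat$x1, mat$x2), path, mat$pixel_size,
                   extra = list(kind = "material_image"))
}

#' @rdname write_material_tiff
#' @export
read_material_tiff <- function(path) {
  r <- read_paged_tiff(path)
  structure(list(x1 = r$pages[[1]], x2 = r$pages[[2]],
                 pixel_size = r$meta$pixel_size),
            class = "material_image")
}

#' Write / read a dual-energy image as multi-page TIFF
#'
#' Page 0 holds the low-energy attenuation image and page 1 the
#' high-energy image.
#'
#' @param img A [dual_energy_image()].
#' @param path Output path (`.tif`).
#' @return `path`, invisibly (writer); a [dual_energy_image()] (reader).
#' @export
write_dect_tiff <- function(img, path) {
  write_paged_tiff(list(img$mu_L, img$mu_H), path, img$pixel_size,
                   extra = list(kind = "dual_energy_image"))
}

#' @rdname write_dect_tiff
#' @export
read_dect_tiff <- function(path) {
  r <- read_paged_tiff(path)
  dual_energy_image(r$pages[[1]], r$pages[[2]],
                    pixel_size = r$meta$pixel_size)
}

#' Write / read a basis as YAML
#'
#' @param basis A [basis2x2()].
#' @param path YAML path.
#' @return `path`, invisibly (writer); a [basis2x2()] (reader; the
#'   determinant is recomputed from the four entries).
#' @export
write_basis_yaml <- function(basis, path) {
  yaml::write_yaml(basis[c("mu1H", "mu2H", "mu1L", "mu2L")], path)
  invisible(path)
}

#' @rdname write_basis_yaml
#' @export
read_basis_yaml <- function(path) {
  v <- yaml::read_yaml(path)
  basis2x2(v$mu1H, v$mu2H, v$mu1L, v$mu2L)
}

#' Save / load a trained network
#'
#' Serializes the configuration, layer dimensions, weights and training
#' history with R's native serialization.
#'
#' @param network An `fcn_network`.
#' @param path Output path (`.rds`).
#' @return `path`, invisibly (writer); an `fcn_network` (reader).
#' @export
write_fcn <- function(network, path) {
  saveRDS(unclass(network), path)
  invisible(path)
}

#' @rdname write_fcn
#' @export
read_fcn <- function(path) {
  structure(readRDS(path), class = "fcn_network")
}
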