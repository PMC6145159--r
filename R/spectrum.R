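#' Parametric X-ray tube spectrum
#'
#' Builds a normalized polyenergetic spectrum with the bremsstrahlung shape
#' `w(E) proportional to (E_max - E) / E` (Kramers' law) on a binned energy
#' grid, with a low-energy cutoff emulating inherent filtration.  A single
#' bin gives a monoenergetic spectrum at the midpoint of the support.
#'
#' @param kvp Tube voltage in kVp, between 40 and 150; this is the maximum
#'   photon energy in keV.
#' @param n_bins Number of energy bins (>= 1).
#' @param cutoff_kev Low-energy cutoff in keV (default 20, photons below are
#'   absorbed by filtration).
#' @return A `spectrum` object with fields `energies` (bin centers, keV),
#'   `weights` (fluence fractions summing to 1) and `kvp`.
#' @export
make_spectrum <- function(kvp, n_bins = 50L, cutoff_kev = 20) {
  if (!is.numeric(kvp) || length(kvp) != 1L || kvp < 40 || kvp > 150)
    stop("`kvp` must lie in [40, 150]", call. = FALSE)
  stop_if_not_scalar_count(n_bins, "n_bins", 1L)
  if (cutoff_kev >= kvp) stop("`cutoff_kev` must be below `kvp`", call. = FALSE)
  edges <- seq(cutoff_kev, kvp, length.out = n_bins + 1L)
  centers <- (edges[-1L] + edges[-(n_bins + 1L)]) / 2
  w <- (kvp - centers) / centers
  if (n_bins == 1L) w <- 1
  w <- w / sum(w)
  structure(list(energies = centers, weights = w, kvp = kvp),
            class = "spectrum")
}

#' Monoenergetic spectrum at a single energy
#'
#' @param energy_kev Photon energy in keV.
#' @return A single-bin `spectrum` with all weight at `energy_kev`.
#' @export
mono_spectrum <- function(energy_kev) {
  structure(list(energies = energy_kev, weights = 1, kvp = energy_kev),
            class = "spectrum")
}

#' @export
print.spectrum <- function(x, ...) {
  cat(sprintf("<spectrum> %g kVp, %d bins, mean energy %.1f keV\n",
              x$kvp, length(x$energies), sum(x$energies * x$weights)))
  invisible(x)
}

#' Tabulated linear attenuation coefficients of the basis materials
#'
#' Energy-resolved linear attenuation per unit material coefficient for the
#' two basis materials, on a 20-140 keV grid with 5 keV steps.  The tissue
#' curve follows the energy dependence of water and the bone curve that of
#' cortical bone, so a transformed coefficient of 1 corresponds to ordinary
#' soft tissue / compact bone.  Queries are linearly interpolated and
#' clamped to the grid ends.
#'
#' @return An `attenuation_model` object: list with `energies` (keV) and a
#'   named list `mu` of per-material coefficient vectors (1/cm per unit
#'   coefficient).
#' @export
default_attenuation_model <- function() {
  e <- seq(20, 140, by = 5)
  # water-like, 1/cm per unit tissue coefficient
  tissue <- c(0.810, 0.615, 0.495, 0.416, 0.362, 0.323, 0.294, 0.272,
              0.255, 0.241, 0.229, 0.220, 0.211, 0.204, 0.198, 0.192,
              0.187, 0.182, 0.178, 0.174, 0.171, 0.167, 0.164, 0.161,
              0.159)
  # cortical-bone-like, 1/cm per unit bone coefficient
  bone <- c(7.68, 4.95, 3.41, 2.47, 1.86, 1.45, 1.17, 0.965, 0.815,
            0.701, 0.614, 0.545, 0.491, 0.447, 0.412, 0.383, 0.359,
            0.338, 0.321, 0.306, 0.293, 0.282, 0.272, 0.263, 0.256)
  structure(list(energies = e, mu = list(tissue = tissue, bone = bone)),
            class = "attenuation_model")
}

# mu(E) for one material, linear interpolation, flat beyond the grid.
mu_at <- function(model, material, energies) {
  if (!material %in% names(model$mu))
    stop(sprintf("unknown material '%s'", material), call. = FALSE)
  approx(model$energies, model$mu[[material]], xout = energies,
         rule = 2)$y
}

#' Spectrum-averaged effective attenuation coefficient
#'
#' Fluence-weighted mean of a material's attenuation curve over a spectrum.
#' For a monoenergetic spectrum this is exactly the tabulated value at that
#' energy.
#'
#' @param material `"tissue"` or `"bone"`.
#' @param spectrum A [make_spectrum()] object.
#' @param model An attenuation model, see [default_attenuation_model()].
#' @return Scalar effective attenuation (1/cm per unit coefficient).
#' @export
effective_mu <- function(material, spectrum,
                         model = default_attenuation_model()) {
  mu <- mu_at(model, material, spectrum$energies)
  sum(spectrum$weights * mu) / sum(spectrum$weights)
}
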