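#' dectsim: dual-energy CT material decomposition on a simulated fan-beam testbench
#'
#' A self-contained 2D fan-beam simulation environment for studying
#' projection-data-domain dual-energy material decomposition with
#' object-specific scatter correction, alongside the conventional
#' calibration-based data-domain decomposition and image-domain
#' decomposition, on analytic digital phantoms.
#'
#' @keywords internal
"_PACKAGE"

# Supported photon-energy band (keV). Attenuation model and spectra are only
# meaningful well below the pair-production regime; clinical CT lives here.
.E_MIN <- 10
.E_MAX <- 200

#' Klein-Nishina total cross-section shape
#'
#' Total Klein-Nishina cross section as a function of photon energy,
#' normalized so that `klein_nishina(100) == 1`. Used as the Compton basis
#' function of the two-basis (photoelectric + Compton) attenuation model.
#'
#' @param e Photon energy in keV (vectorized).
#' @return Dimensionless shape values, 1 at 100 keV.
#' @export
klein_nishina <- function(e) {
  stopifnot(is.numeric(e), all(e > 0))
  kn <- function(en) {
    eps <- en / 510.998950
    (1 + eps) / eps^2 * (2 * (1 + eps) / (1 + 2 * eps) - log(1 + 2 * eps) / eps) +
      log(1 + 2 * eps) / (2 * eps) - (1 + 3 * eps) / (1 + 2 * eps)^2
  }
  kn(e) / kn(100)
}

#' Uniform photon-energy grid
#'
#' @param e_min,e_max Grid bounds in keV. The lower bound must be at least
#'   10 keV; the upper bound is typically the tube voltage.
#' @param step Grid step in keV (default 1).
#' @return Numeric vector of energies with class `"energy_grid"`.
#' @export
energy_grid <- function(e_min = 10, e_max, step = 1) {
  stopifnot(step > 0, e_max > e_min)
  if (e_min < .E_MIN) stop("energy grid must start at or above 10 keV")
  if (e_max > .E_MAX) stop("energy grid exceeds supported band")
  e <- seq(e_min, e_max, by = step)
  structure(e, class = c("energy_grid", "numeric"), step = step)
}

#' Basis material
#'
#' A material parameterized by a photoelectric coefficient (its attenuation
#' contribution is `pe_coeff * E^-3`, E in keV) and a Compton coefficient
#' multiplying the Klein-Nishina total cross-section shape.
#'
#' @param name Material name.
#' @param density Mass density in g/cm^3 (metadata; the attenuation model is
#'   fully determined by `pe_coeff` and `kn_coeff`).
#' @param pe_coeff,kn_coeff Non-negative basis weights.
#' @return An object of class `"ct_material"`.
#' @export
ct_material <- function(name, density, pe_coeff, kn_coeff) {
  stopifnot(is.character(name), length(name) == 1L,
            is.numeric(density), density >= 0,
            pe_coeff >= 0, kn_coeff >= 0)
  structure(list(name = name, density = density,
                 pe_coeff = pe_coeff, kn_coeff = kn_coeff),
            class = "ct_material")
}

#' @export
print.ct_material <- function(x, ...) {
  cat(sprintf("ct_material '%s': density %.4g g/cm^3, pe %.4g, kn %.4g\n",
              x$name, x$density, x$pe_coeff, x$kn_coeff))
  invisible(x)
}

#' Fit a material's basis coefficients from two reference attenuation values
#'
#' Solves the 2x2 linear system so the two-basis model reproduces the two
#' tabulated linear attenuation coefficients exactly.
#'
#' @param name,density As for [ct_material()].
#' @param e1,mu1 First reference energy (keV) and attenuation (1/cm).
#' @param e2,mu2 Second reference point.
#' @return A `"ct_material"`.
#' @export
material_from_two_points <- function(name, density, e1, mu1, e2, mu2) {
  stopifnot(e1 != e2, mu1 >= 0, mu2 >= 0)
  a <- rbind(c(e1^-3, klein_nishina(e1)),
             c(e2^-3, klein_nishina(e2)))
  co <- solve(a, c(mu1, mu2))
  if (any(co < -1e-9))
    stop("two-point fit produced a negative basis coefficient for ", name)
  ct_material(name, density, pe_coeff = max(co[1], 0), kn_coeff = max(co[2], 0))
}

#' Load the reference material set
#'
#' Reads the packaged synthetic two-point attenuation reference table and fits
#' each material's photoelectric/Compton coefficients from its two anchor
#' energies. The table also carries a third tabulated value per material used
#' only for cross-checking the fit.
#'
#' @param path CSV path; defaults to the packaged table.
#' @return Named list of `"ct_material"` objects, with the raw table attached
#'   as attribute `"reference_table"`.
#' @export
load_reference_materials <- function(path = system.file("extdata", "materials_reference.csv",
                                                        package = "dectsim")) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  mats <- lapply(seq_len(nrow(tab)), function(i) {
    material_from_two_points(tab$material[i], tab$density[i],
                             tab$e1_kev[i], tab$mu1[i],
                             tab$e2_kev[i], tab$mu2[i])
  })
  names(mats) <- tab$material
  attr(mats, "reference_table") <- tab
  mats
}

.materials_cache <- new.env(parent = emptyenv())

#' Default material set
#'
#' Cached accessor for [load_reference_materials()].
#' @return Named list of materials.
#' @export
default_materials <- function() {
  if (is.null(.materials_cache$mats))
    .materials_cache$mats <- load_reference_materials()
  .materials_cache$mats
}

#' Linear attenuation coefficient of a material
#'
#' @param material A `"ct_material"`.
#' @param e Photon energies in keV; must lie within the supported 10-200 keV
#'   band.
#' @return mu in 1/cm (vectorized over `e`).
#' @export
material_mu <- function(material, e) {
  stopifnot(inherits(material, "ct_material"), is.numeric(e))
  if (any(e < .E_MIN | e > .E_MAX))
    stop("energy outside the supported 10-200 keV band")
  material$pe_coeff * e^-3 + material$kn_coeff * klein_nishina(e)
}

#' Convert attenuation to Hounsfield units
#'
#' `HU = 1000 * (mu - mu_water_ref) / mu_water_ref`; air maps to -1000 HU,
#' water to 0 HU.
#'
#' @param mu Attenuation values (1/cm), vectorized.
#' @param mu_water_ref Water attenuation at the same energy (1/cm, > 0).
#' @return Hounsfield units.
#' @export
hu_from_mu <- function(mu, mu_water_ref) {
  if (!is.numeric(mu_water_ref) || length(mu_water_ref) != 1L || mu_water_ref <= 0)
    stop("mu_water_ref must be a single positive number")
  1000 * (mu - mu_water_ref) / mu_water_ref
}
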