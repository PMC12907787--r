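#' Ground-truth calcium/water attenuation ratio curve
#'
#' Tabulates `mu_calcium(E) / mu_water(E)` over an energy range; the curve
#' is strictly decreasing for a calcium-like material against water, which
#' makes the effective-energy lookup well-posed.
#'
#' @param calcium,water Basis materials.
#' @param energies Energy samples in keV (default 30 to 140 keV in 0.1 keV
#'   steps).
#' @return Object of class `"ratio_curve"`.
#' @export
ratio_curve <- function(calcium = default_materials()$bone,
                        water = default_materials()$water,
                        energies = seq(30, 140, by = 0.1)) {
  r <- material_mu(calcium, energies) / material_mu(water, energies)
  if (!(all(diff(r) < 0) || all(diff(r) > 0)))
    stop("attenuation ratio curve is not strictly monotone")
  structure(list(energies = energies, ratio = r,
                 calcium = calcium$name, water = water$name),
            class = "ratio_curve")
}

#' Relative densities and their ratio from calibration images
#'
#' Computes the mean attenuation in the central-insert ROI of the all-water
#' and calcium-insert calibration images, expresses both as relative
#' densities against an energy-independent water reference, and forms their
#' ratio (the quantity matched against the ground-truth ratio curve to find
#' an effective energy).
#'
#' @param image_water_cfg,image_calcium_cfg `"ct_image"` objects in mu units
#'   reconstructed from same-kV scans of the two calibration configurations.
#' @param roi An [roi_circle()] inside the central insert.
#' @param mu_water_ref Energy-independent water reference attenuation
#'   (default mu_water at 70 keV).
#' @return List with `rho_w`, `rho_c`, `ratio`.
#' @export
compute_insert_ratio <- function(image_water_cfg, image_calcium_cfg, roi,
                                 mu_water_ref =
                                   material_mu(default_materials()$water, 70)) {
  rho_w <- roi_stats(image_water_cfg, roi)$mean / mu_water_ref
  rho_c <- roi_stats(image_calcium_cfg, roi)$mean / mu_water_ref
  list(rho_w = rho_w, rho_c = rho_c, ratio = insert_ratio(rho_w, rho_c))
}

#' Ratio of calcium to water relative density
#'
#' @param rho_w,rho_c Relative densities of the water-equivalent and calcium
#'   central inserts.
#' @return `rho_c / rho_w`.
#' @export
insert_ratio <- function(rho_w, rho_c) {
  stopifnot(rho_w > 0)
  rho_c / rho_w
}

#' Effective energy from an attenuation ratio
#'
#' Finds the energy at which the ground-truth ratio curve equals the
#' measured ratio, by monotone linear interpolation.
#'
#' @param ratio Measured calcium/water attenuation ratio.
#' @param curve A [ratio_curve()].
#' @return Effective energy in keV.
#' @export
find_effective_energy <- function(ratio, curve) {
  stopifnot(inherits(curve, "ratio_curve"))
  if (ratio < min(curve$ratio) || ratio > max(curve$ratio))
    stop("ratio outside the tabulated curve; no crossing exists")
  o <- order(curve$ratio)
  stats::approx(curve$ratio[o], curve$energies[o], xout = ratio)$y
}

#' Image-domain 2x2 decomposition matrix
#'
#' `D = [[mu_w(eps_LE), mu_c(eps_LE)], [mu_w(eps_HE), mu_c(eps_HE)]]`, the
#' basis matrix inverted per pixel by the image-domain decomposition.
#'
#' @param eps_le,eps_he Effective energies in keV (`eps_le < eps_he`).
#' @param water,calcium Basis materials.
#' @return Object of class `"decomposition_matrix"`.
#' @export
decomposition_matrix <- function(eps_le, eps_he,
                                 water = default_materials()$water,
                                 calcium = default_materials()$bone) {
  stopifnot(eps_le < eps_he)
  d <- rbind(c(material_mu(water, eps_le), material_mu(calcium, eps_le)),
             c(material_mu(water, eps_he), material_mu(calcium, eps_he)))
  if (abs(det(d)) < 1e-6 * sum(d^2))
    stop("decomposition matrix is near singular; effective energies too close")
  structure(list(eps_le = eps_le, eps_he = eps_he, D = d,
                 water = water$name, calcium = calcium$name),
            class = "decomposition_matrix")
}

#' @export
print.decomposition_matrix <- function(x, ...) {
  cat(sprintf("decomposition_matrix: eps_LE %.1f keV, eps_HE %.1f keV, det %.4g\n",
              x$eps_le, x$eps_he, det(x$D)))
  invisible(x)
}

#' Pixel-wise image-domain decomposition
#'
#' Applies the inverse of the 2x2 basis matrix to the stacked per-pixel
#' attenuation values of the LE and HE images (each interpreted at its
#' effective energy), yielding relative-density images of the two basis
#' materials.
#'
#' @param img_le,img_he `"ct_image"` objects in mu units on the same grid.
#' @param dm A [decomposition_matrix()].
#' @return List with `w` and `c` relative-density `"ct_image"` objects.
#' @export
decompose_pixelwise <- function(img_le, img_he, dm) {
  stopifnot(inherits(img_le, "ct_image"), inherits(img_he, "ct_image"),
            inherits(dm, "decomposition_matrix"),
            all(dim(img_le$pixels) == dim(img_he$pixels)))
  d <- dm$D
  dt <- det(d)
  fw <- (d[2, 2] * img_le$pixels - d[1, 2] * img_he$pixels) / dt
  fc <- (-d[2, 1] * img_le$pixels + d[1, 1] * img_he$pixels) / dt
  list(w = ct_image(fw, img_le$pixel_size, img_le$grid_offset, "density"),
       c = ct_image(fc, img_le$pixel_size, img_le$grid_offset, "density"))
}

#' Synthesize a virtual mono-energetic image
#'
#' Linearly combines the two basis-material relative-density images with
#' the basis attenuation coefficients at the requested energy:
#' `mu = f_w * mu_w(e) + f_c * mu_c(e)`, optionally converted to HU against
#' water at the same energy. Shared by the image-domain and data-domain
#' paths (the latter supplies density images reconstructed from length
#' sinograms).
#'
#' @param f_w,f_c Relative-density `"ct_image"` objects.
#' @param e Energy in keV.
#' @param water,calcium Basis materials.
#' @param units `"HU"` (default) or `"mu"`.
#' @return A `"ct_image"`.
#' @export
synthesize_vmi <- function(f_w, f_c, e, water = default_materials()$water,
                           calcium = default_materials()$bone,
                           units = c("HU", "mu")) {
  stopifnot(inherits(f_w, "ct_image"), inherits(f_c, "ct_image"),
            all(dim(f_w$pixels) == dim(f_c$pixels)))
  units <- match.arg(units)
  mu <- f_w$pixels * material_mu(water, e) + f_c$pixels * material_mu(calcium, e)
  if (units == "HU")
    ct_image(hu_from_mu(mu, material_mu(water, e)), f_w$pixel_size,
             f_w$grid_offset, "HU", meta = list(energy_kev = e))
  else
    ct_image(mu, f_w$pixel_size, f_w$grid_offset, "mu",
             meta = list(energy_kev = e))
}

#' Rescale a water-corrected image to its effective energy
#'
#' Vendor-style water-corrected reconstructions carry water at
#' `mu_w(e_ref)`; interpreting such an image as mono-energetic at its
#' effective energy amounts to the scale change
#' `mu(eps) = pixel * mu_w(eps) / mu_w(e_ref)`.
#'
#' @param image `"ct_image"` in mu units at the water reference scale.
#' @param eps Effective energy in keV.
#' @param water Water material.
#' @param e_ref Reference energy of the correction (default 70).
#' @return Rescaled `"ct_image"` in mu units.
#' @export
rescale_to_effective_energy <- function(image, eps,
                                        water = default_materials()$water,
                                        e_ref = 70) {
  stopifnot(inherits(image, "ct_image"))
  out <- image
  out$pixels <- image$pixels * material_mu(water, eps) / material_mu(water, e_ref)
  out$meta$effective_energy_kev <- eps
  out
}
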