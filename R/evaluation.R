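#' Circular region of interest
#'
#' @param center (x, y) in mm.
#' @param radius Radius in mm (default 10, the standard 20 mm insert ROI).
#' @return Object of class `"roi_spec"`.
#' @export
roi_circle <- function(center, radius = 10) {
  stopifnot(length(center) == 2L, radius > 0)
  structure(list(kind = "circle", center = as.numeric(center),
                 radius = radius),
            class = "roi_spec")
}

#' Ring-shaped region of interest
#'
#' Defaults reproduce the beam-hardening assessment ring around the bone
#' insert: inner radius 17.64 mm, thickness 4.9 mm.
#'
#' @param center (x, y) in mm (typically the bone-insert center).
#' @param inner_radius Inner radius in mm.
#' @param thickness Radial thickness in mm.
#' @return Object of class `"roi_spec"`.
#' @export
roi_ring <- function(center, inner_radius = 17.64, thickness = 4.9) {
  stopifnot(length(center) == 2L, inner_radius > 0, thickness > 0)
  structure(list(kind = "ring", center = as.numeric(center),
                 inner_radius = inner_radius, thickness = thickness),
            class = "roi_spec")
}

#' Logical pixel mask of an ROI
#'
#' Pixel-center containment rule. ROI centers are interpreted relative to
#' the reconstruction grid center, so ROIs defined for a centered phantom
#' stay on the inserts when a shifted phantom is reconstructed on a
#' compensating (equally shifted) grid.
#'
#' @param image A `"ct_image"`.
#' @param roi A `"roi_spec"`.
#' @return Logical matrix of the image's shape.
#' @export
roi_mask <- function(image, roi) {
  stopifnot(inherits(image, "ct_image"), inherits(roi, "roi_spec"))
  cc <- image_coords(image)
  xl <- cc$x - image$grid_offset[1]
  yl <- cc$y - image$grid_offset[2]
  r2 <- outer(yl - roi$center[2], xl - roi$center[1],
              function(dy, dx) dx^2 + dy^2)
  if (roi$kind == "circle") {
    r2 <= roi$radius^2
  } else {
    r2 >= roi$inner_radius^2 & r2 <= (roi$inner_radius + roi$thickness)^2
  }
}

#' ROI statistics
#'
#' @param image A `"ct_image"`.
#' @param roi A `"roi_spec"` within the image bounds.
#' @return List with `mean`, `sd`, `n_pixels`.
#' @export
roi_stats <- function(image, roi) {
  m <- roi_mask(image, roi)
  if (!any(m)) stop("ROI contains no pixel centers")
  v <- image$pixels[m]
  list(mean = mean(v), sd = stats::sd(v), n_pixels = sum(m))
}

#' Ring mean absolute error
#'
#' Mean over the ring pixels of the absolute difference from a ground-truth
#' value; absolute values prevent cancellation of over- and under-shoots.
#'
#' @param image A `"ct_image"`.
#' @param gt_value Ground-truth value in the image's units.
#' @param ring A ring `"roi_spec"`.
#' @return Mean absolute error.
#' @export
ring_mae <- function(image, gt_value, ring) {
  m <- roi_mask(image, ring)
  if (!any(m)) stop("ring contains no pixel centers")
  mean(abs(image$pixels[m] - gt_value))
}

#' Ground-truth Hounsfield value of a material
#'
#' @param material A `"ct_material"`.
#' @param e Energy in keV (vectorized).
#' @param water Water material defining 0 HU.
#' @return HU value(s).
#' @export
gt_hu <- function(material, e, water = default_materials()$water) {
  vapply(e, function(en)
    hu_from_mu(material_mu(material, en), material_mu(water, en)), numeric(1))
}

#' Noise versus energy curve of a VMI stack
#'
#' Synthesizes virtual mono-energetic images over an energy range from one
#' basis-image pair and reports the ROI standard deviation per energy and
#' the energy of the minimum (leftmost on ties).
#'
#' @param f_w,f_c Basis relative-density `"ct_image"` objects from one
#'   (noisy) scan pair.
#' @param roi An `"roi_spec"` (typically the water-insert ROI).
#' @param energies Energies in keV (default 30 to 140 keV in 5 keV steps).
#' @param water,calcium Basis materials.
#' @return List with `energies`, `sd_hu`, `argmin_kev`.
#' @export
noise_energy_curve <- function(f_w, f_c, roi, energies = seq(30, 140, by = 5),
                               water = default_materials()$water,
                               calcium = default_materials()$bone) {
  sds <- vapply(energies, function(e) {
    roi_stats(synthesize_vmi(f_w, f_c, e, water, calcium), roi)$sd
  }, numeric(1))
  list(energies = energies, sd_hu = sds,
       argmin_kev = energies[which.min(sds)])
}

#' Insert ROI specifications of the ACR-style module
#'
#' The five 20 mm diameter insert ROIs plus the beam-hardening ring around
#' the bone insert, at a given phantom offset.
#'
#' @param offset Phantom offset in mm.
#' @param grid_compensated If `TRUE` (the usual analysis setting), the
#'   reconstruction grid already compensates the offset and the ROIs stay at
#'   the centered positions.
#' @return Named list of `"roi_spec"` objects (`bone`, `polyethylene`,
#'   `acrylic`, `air`, `water_insert`, `ring`).
#' @export
acr_roi_specs <- function(offset = c(0, 0), grid_compensated = TRUE) {
  eff <- if (grid_compensated) c(0, 0) else offset
  centers <- acr_insert_centers(eff)
  rois <- lapply(centers, roi_circle, radius = 10)
  rois$ring <- roi_ring(centers$bone)
  rois
}

#' Accuracy versus energy for a set of insert ROIs
#'
#' Evaluates virtual mono-energetic images from one basis-image pair on an
#' energy grid and reports, per insert and energy, the ROI mean in HU, the
#' ground-truth HU, and the relative error. The relative error uses HU for
#' non-water materials and the attenuation coefficient for water (whose
#' ground-truth HU is 0).
#'
#' Relative errors are reported on the attenuation coefficient,
#' `100 * (mu_roi - mu_gt) / mu_gt`, for every insert: an HU-denominator
#' metric is undefined for water (ground truth 0 HU) and degenerates for
#' any insert whose ground-truth HU crosses zero inside the energy range
#' (acrylic does, near 35 keV, as real PMMA would).
#'
#' @param f_w,f_c Basis relative-density images.
#' @param rois Named list of circle `"roi_spec"` objects.
#' @param roi_materials Named list of `"ct_material"` matching `rois`.
#' @param energies Energies in keV (default 30 to 140 by 5).
#' @param water,calcium Basis materials.
#' @param method,position Optional labels copied into the output.
#' @return Data frame with columns `method`, `position`, `roi`,
#'   `energy_kev`, `mean_hu`, `sd_hu`, `gt_hu`, `rel_error_pct`.
#' @export
accuracy_energy_curves <- function(f_w, f_c, rois, roi_materials,
                                   energies = seq(30, 140, by = 5),
                                   water = default_materials()$water,
                                   calcium = default_materials()$bone,
                                   method = NA_character_,
                                   position = NA_character_) {
  stopifnot(all(names(rois) %in% c(names(roi_materials), "ring")))
  rows <- list()
  for (e in energies) {
    vmi <- synthesize_vmi(f_w, f_c, e, water, calcium)
    for (nm in setdiff(names(rois), "ring")) {
      st <- roi_stats(vmi, rois[[nm]])
      gt <- gt_hu(roi_materials[[nm]], e, water)
      # mu-relative error: 100 * (mu_roi - mu_gt) / mu_gt
      rel <- 100 * (st$mean - gt) / (1000 + gt)
      rows[[length(rows) + 1L]] <-
        data.frame(method = method, position = position, roi = nm,
                   energy_kev = e, mean_hu = st$mean, sd_hu = st$sd,
                   gt_hu = gt, rel_error_pct = rel)
    }
  }
  do.call(rbind, rows)
}
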