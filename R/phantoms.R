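#' Disk phantom element
#'
#' @param center Numeric (x, y) in mm, isocenter coordinates with y pointing
#'   up.
#' @param radius Radius in mm (> 0).
#' @param material A `"ct_material"`.
#' @param label Optional label (defaults to the material name).
#' @return Object of class `"ct_shape"` (kind `"disk"`).
#' @export
ct_disk <- function(center, radius, material, label = material$name) {
  stopifnot(length(center) == 2L, is.numeric(center), radius > 0,
            inherits(material, "ct_material"))
  structure(list(kind = "disk", center = as.numeric(center), radius = radius,
                 material = material, label = label),
            class = "ct_shape")
}

#' Axis-aligned ellipse phantom element
#'
#' @param center Numeric (x, y) in mm.
#' @param semi_axes Numeric (a, b) semi-axes in mm (> 0).
#' @param material A `"ct_material"`.
#' @param label Optional label.
#' @return Object of class `"ct_shape"` (kind `"ellipse"`).
#' @export
ct_ellipse <- function(center, semi_axes, material, label = material$name) {
  stopifnot(length(center) == 2L, length(semi_axes) == 2L, all(semi_axes > 0),
            inherits(material, "ct_material"))
  structure(list(kind = "ellipse", center = as.numeric(center),
                 semi_axes = as.numeric(semi_axes),
                 material = material, label = label),
            class = "ct_shape")
}

.shape_bounding_radius <- function(s) {
  if (s$kind == "disk") s$radius else max(s$semi_axes)
}

# is shape `a` entirely inside shape `b`? exact for disk-in-disk,
# boundary-sampled otherwise
.shape_inside <- function(a, b, n_test = 64L) {
  if (a$kind == "disk" && b$kind == "disk") {
    return(sqrt(sum((a$center - b$center)^2)) + a$radius <= b$radius + 1e-9)
  }
  th <- seq(0, 2 * pi, length.out = n_test + 1L)[-1L]
  pts <- if (a$kind == "disk") {
    cbind(a$center[1] + a$radius * cos(th), a$center[2] + a$radius * sin(th))
  } else {
    cbind(a$center[1] + a$semi_axes[1] * cos(th),
          a$center[2] + a$semi_axes[2] * sin(th))
  }
  all(.point_in_shape(pts, b))
}

.point_in_shape <- function(pts, s) {
  dx <- pts[, 1] - s$center[1]
  dy <- pts[, 2] - s$center[2]
  if (s$kind == "disk") dx^2 + dy^2 <= s$radius^2 + 1e-9
  else (dx / s$semi_axes[1])^2 + (dy / s$semi_axes[2])^2 <= 1 + 1e-9
}

.shapes_disjoint <- function(a, b) {
  d <- sqrt(sum((a$center - b$center)^2))
  d >= .shape_bounding_radius(a) + .shape_bounding_radius(b) - 1e-9
}

#' Analytic phantom
#'
#' A background shape plus an ordered list of inserts. Inserts must each lie
#' fully inside the background and be pairwise disjoint or strictly nested
#' (nested shapes replace their parent's material along the shared path, so
#' an annulus is expressed as an outer shape with an inner shape inside it).
#'
#' @param background A `"ct_shape"`.
#' @param inserts List of `"ct_shape"` objects.
#' @param offset Numeric (dx, dy) in mm applied to all shapes.
#' @return Object of class `"ct_phantom"`.
#' @export
ct_phantom <- function(background, inserts = list(), offset = c(0, 0)) {
  stopifnot(inherits(background, "ct_shape"), length(offset) == 2L)
  for (ins in inserts) {
    if (!inherits(ins, "ct_shape")) stop("inserts must be ct_shape objects")
    if (!.shape_inside(ins, background))
      stop(sprintf("insert '%s' is not fully inside the background", ins$label))
  }
  if (length(inserts) >= 2L) {
    for (i in seq_len(length(inserts) - 1L)) {
      for (j in seq(i + 1L, length(inserts))) {
        a <- inserts[[i]]; b <- inserts[[j]]
        ok <- .shapes_disjoint(a, b) || .shape_inside(a, b) || .shape_inside(b, a)
        if (!ok)
          stop(sprintf("inserts '%s' and '%s' overlap without nesting",
                       a$label, b$label))
      }
    }
  }
  structure(list(background = background, inserts = inserts,
                 offset = as.numeric(offset)),
            class = "ct_phantom")
}

#' @export
print.ct_phantom <- function(x, ...) {
  cat(sprintf("ct_phantom: background '%s' + %d inserts, offset (%g, %g) mm\n",
              x$background$label, length(x$inserts), x$offset[1], x$offset[2]))
  for (ins in x$inserts)
    cat(sprintf("  %-14s %s at (%7.2f, %7.2f)\n", ins$label, ins$kind,
                ins$center[1] + x$offset[1], ins$center[2] + x$offset[2]))
  invisible(x)
}

#' Shift a phantom
#'
#' @param phantom A `"ct_phantom"`.
#' @param offset Additional (dx, dy) in mm.
#' @return The shifted phantom.
#' @export
shift_phantom <- function(phantom, offset) {
  stopifnot(inherits(phantom, "ct_phantom"), length(offset) == 2L)
  phantom$offset <- phantom$offset + as.numeric(offset)
  phantom
}

# effective (offset-applied) shapes, background first
.phantom_shapes <- function(phantom) {
  sh <- c(list(phantom$background), phantom$inserts)
  lapply(sh, function(s) {
    s$center <- s$center + phantom$offset
    s
  })
}

#' ACR-style accreditation phantom, module A
#'
#' A 200 mm water-equivalent cylinder with five cylindrical inserts: bone,
#' polyethylene, acrylic and air (25 mm diameter) on a 60 mm radius at 45,
#' 135, 225 and 315 degrees, and a 50 mm diameter water insert at the center.
#' Optionally adds four small steel beads at the cardinal points (alignment
#' aids; off by default).
#'
#' @param offset (dx, dy) in mm applied to the whole phantom; a vertical
#'   shift of (0, 48) reproduces the off-centered scan position.
#' @param materials Named material list (defaults to the packaged set).
#' @param insert_radius Radius of the four small inserts in mm (default 12.5).
#' @param ring_radius Radial position of the four small inserts (default 60).
#' @param beads Add four 0.5 mm radius steel beads at the cardinal points.
#' @param fov_radius_mm Radius of the scan field of view used for the
#'   placement check (default 250).
#' @return A `"ct_phantom"`.
#' @export
make_acr_module_a <- function(offset = c(0, 0), materials = default_materials(),
                              insert_radius = 12.5, ring_radius = 60,
                              beads = FALSE, fov_radius_mm = 250) {
  if (sqrt(sum(offset^2)) + 100 > fov_radius_mm)
    stop("phantom placement outside the scan field of view")
  ang <- c(45, 135, 225, 315) * pi / 180
  mats <- c("bone", "polyethylene", "acrylic", "air")
  inserts <- lapply(seq_along(ang), function(i) {
    ct_disk(ring_radius * c(cos(ang[i]), sin(ang[i])), insert_radius,
            materials[[mats[i]]])
  })
  inserts <- c(inserts, list(ct_disk(c(0, 0), 25, materials$water,
                                     label = "water_insert")))
  if (beads) {
    for (a in c(0, 90, 180, 270) * pi / 180) {
      inserts <- c(inserts, list(
        ct_disk(92.5 * c(cos(a), sin(a)), 0.5, materials$steel,
                label = sprintf("bead_%d", round(a * 180 / pi)))))
    }
  }
  ct_phantom(ct_disk(c(0, 0), 100, materials$water, label = "body"),
             inserts, offset = offset)
}

#' Insert center positions of the ACR-style module
#'
#' @inheritParams make_acr_module_a
#' @return Named list of (x, y) centers in mm with the phantom offset applied.
#' @export
acr_insert_centers <- function(offset = c(0, 0), ring_radius = 60) {
  ang <- c(bone = 45, polyethylene = 135, acrylic = 225, air = 315) * pi / 180
  out <- lapply(ang, function(a) ring_radius * c(cos(a), sin(a)) + offset)
  out$water_insert <- c(0, 0) + offset
  out
}

#' Two-configuration multi-energy calibration phantom
#'
#' A 200 mm water-equivalent cylinder. `"all-water"` has no inserts
#' (water-in-water is homogeneous); `"central-calcium"` places one
#' 28.6 mm diameter calcium insert at the center; `"offset-calcium"` places
#' it at the 9 o'clock hole position (60 mm left of center).
#'
#' @param config One of `"all-water"`, `"central-calcium"`,
#'   `"offset-calcium"`.
#' @param materials Named material list; the calcium insert uses the
#'   bone-equivalent fixture (the calcium basis material).
#' @param offset Optional phantom offset in mm.
#' @return A `"ct_phantom"`.
#' @export
make_calibration_phantom <- function(config = c("all-water", "central-calcium",
                                                "offset-calcium"),
                                     materials = default_materials(),
                                     offset = c(0, 0)) {
  config <- match.arg(config)
  inserts <- switch(config,
    "all-water" = list(),
    "central-calcium" = list(ct_disk(c(0, 0), 14.3, materials$bone,
                                     label = "calcium")),
    "offset-calcium" = list(ct_disk(c(-60, 0), 14.3, materials$bone,
                                    label = "calcium")))
  ct_phantom(ct_disk(c(0, 0), 100, materials$water, label = "body"),
             inserts, offset = offset)
}

#' Uniform water cylinder
#'
#' @param diameter_mm Cylinder diameter in mm.
#' @param materials Named material list.
#' @param offset Optional offset in mm.
#' @return A `"ct_phantom"` with no inserts.
#' @export
make_water_cylinder <- function(diameter_mm, materials = default_materials(),
                                offset = c(0, 0)) {
  stopifnot(diameter_mm > 0)
  ct_phantom(ct_disk(c(0, 0), diameter_mm / 2, materials$water, label = "water"),
             offset = offset)
}

#' Elliptical abdomen surrogate phantom
#'
#' A simple anthropomorphic stand-in: a 400 x 300 mm fat outer ellipse with a
#' nested water interior and two bone disks, used for position-consistency
#' experiments. This is a synthetic surrogate, not a model of any commercial
#' phantom.
#'
#' @param offset Phantom offset in mm (e.g. `c(0, 40)` for the shifted scan).
#' @param materials Named material list.
#' @return A `"ct_phantom"`.
#' @export
make_abdomen_surrogate <- function(offset = c(0, 0),
                                   materials = default_materials()) {
  fat_ring <- ct_ellipse(c(0, 0), c(200, 150), materials$fat, label = "fat_ring")
  interior <- ct_ellipse(c(0, 0), c(180, 130), materials$water, label = "interior")
  bones <- list(ct_disk(c(-70, -70), 12, materials$bone, label = "bone_left"),
                ct_disk(c(70, -70), 12, materials$bone, label = "bone_right"))
  ct_phantom(fat_ring, c(list(interior), bones), offset = offset)
}
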