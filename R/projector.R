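#' Fan-beam scan geometry
#'
#' Third-generation 2D fan-beam geometry over a full 360 degree trajectory.
#' Defaults are a desk-scale half of the reference scanner geometry (720
#' projections, 368 channels); the full-scale values (2304 x 736) are
#' available by argument. The per-channel angular width is rescaled with the
#' channel count so the total fan angle (and hence the covered field of view)
#' is preserved.
#'
#' @param n_projections Projections per 360 degrees (default 720).
#' @param n_channels Detector channels (default 368).
#' @param source_to_detector Source-detector distance in mm (default 1085.6).
#' @param source_radius Source trajectory radius in mm (default 595).
#' @param channel_width_deg Angular width of one channel in degrees; default
#'   0.067864 * 736 / n_channels.
#' @return Object of class `"fan_geometry"`.
#' @export
fan_geometry <- function(n_projections = 720, n_channels = 368,
                         source_to_detector = 1085.6, source_radius = 595,
                         channel_width_deg = 0.067864 * 736 / n_channels) {
  stopifnot(n_projections >= 4, n_channels >= 4,
            source_radius > 0, source_to_detector > source_radius,
            channel_width_deg > 0)
  g <- structure(list(n_projections = as.integer(n_projections),
                      n_channels = as.integer(n_channels),
                      source_to_detector = source_to_detector,
                      source_radius = source_radius,
                      channel_width_deg = channel_width_deg),
                 class = "fan_geometry")
  if (fov_radius(g) < 125)
    stop("fan angle does not cover a 250 mm field of view")
  g
}

#' @export
print.fan_geometry <- function(x, ...) {
  cat(sprintf(paste0("fan_geometry: %d projections x %d channels, R %g mm, ",
                     "SDD %g mm, fan %.2f deg (FOV radius %.1f mm)\n"),
              x$n_projections, x$n_channels, x$source_radius,
              x$source_to_detector,
              x$n_channels * x$channel_width_deg, fov_radius(x)))
  invisible(x)
}

#' Fan angles of the detector channels
#'
#' @param geometry A `"fan_geometry"`.
#' @return Per-channel fan angle in radians, symmetric about the central ray.
#' @export
fan_angles <- function(geometry) {
  i <- seq_len(geometry$n_channels)
  (i - (geometry$n_channels + 1) / 2) * geometry$channel_width_deg * pi / 180
}

#' Source angles of the projections
#'
#' @param geometry A `"fan_geometry"`.
#' @return Source position angles in radians over `[0, 2*pi)`.
#' @export
projection_angles <- function(geometry) {
  2 * pi * (seq_len(geometry$n_projections) - 1) / geometry$n_projections
}

#' Field-of-view radius covered by the fan
#'
#' @param geometry A `"fan_geometry"`.
#' @return Radius in mm of the largest centered disk every ray family covers.
#' @export
fov_radius <- function(geometry) {
  geometry$source_radius * sin(max(abs(fan_angles(geometry))))
}

# ray table: source positions and unit directions for all projection/channel
# pairs, in projection-major layout (column p of a matrix indexed [chan, proj]
# flattened as chan fastest). Returns list of n_proj*n_chan vectors.
.ray_table <- function(geometry) {
  beta <- projection_angles(geometry)
  gamma <- fan_angles(geometry)
  np <- geometry$n_projections; nc <- geometry$n_channels
  sx <- geometry$source_radius * cos(beta)
  sy <- geometry$source_radius * sin(beta)
  phi <- outer(beta, gamma, function(b, g) b + pi + g)  # np x nc direction angle
  list(sx = rep(sx, times = nc), sy = rep(sy, times = nc),
       ux = as.numeric(cos(phi)), uy = as.numeric(sin(phi)),
       np = np, nc = nc)
}

# chord length (mm) of every ray through one shape; returns np x nc matrix
.shape_chords <- function(shape, rays) {
  dx <- rays$sx - shape$center[1]
  dy <- rays$sy - shape$center[2]
  if (shape$kind == "disk") {
    d <- dx * rays$uy - dy * rays$ux           # perpendicular distance
    h2 <- shape$radius^2 - d^2
    chord <- ifelse(h2 > 0, 2 * sqrt(pmax(h2, 0)), 0)
  } else {
    a <- shape$semi_axes[1]; b <- shape$semi_axes[2]
    qa <- (rays$ux / a)^2 + (rays$uy / b)^2
    qb <- 2 * (dx * rays$ux / a^2 + dy * rays$uy / b^2)
    qc <- (dx / a)^2 + (dy / b)^2 - 1
    disc <- qb^2 - 4 * qa * qc
    chord <- ifelse(disc > 0, sqrt(pmax(disc, 0)) / qa, 0)
  }
  matrix(chord, rays$np, rays$nc)
}

#' Per-material intersection lengths of all rays with a phantom
#'
#' Computes analytic chord lengths of every source-channel ray with each
#' phantom shape and applies the replacement rule: a shape's path length is
#' its own chord minus the chords of the shapes nested directly inside it, so
#' inserts replace (not add to) the material they sit in.
#'
#' @param phantom A `"ct_phantom"` fully inside the field of view.
#' @param geometry A `"fan_geometry"`.
#' @return Object of class `"material_lengths"`: a named list `lengths` of
#'   projections x channels matrices in cm (one per material), plus
#'   `materials` and `geometry`.
#' @export
path_lengths <- function(phantom, geometry) {
  stopifnot(inherits(phantom, "ct_phantom"), inherits(geometry, "fan_geometry"))
  shapes <- .phantom_shapes(phantom)
  ext <- max(vapply(shapes, function(s)
    sqrt(sum(s$center^2)) + .shape_bounding_radius(s), numeric(1)))
  if (ext > fov_radius(geometry) + 1e-6)
    stop("phantom extends outside the field of view")
  rays <- .ray_table(geometry)
  chords <- lapply(shapes, .shape_chords, rays = rays)
  n <- length(shapes)
  # parent of shape i = smallest other shape that contains it (0 = none)
  parent <- integer(n)
  for (i in seq_len(n)) {
    cand <- which(vapply(seq_len(n), function(j)
      j != i && .shape_inside(shapes[[i]], shapes[[j]]), logical(1)))
    if (length(cand))
      parent[i] <- cand[which.min(vapply(shapes[cand], .shape_bounding_radius,
                                         numeric(1)))]
  }
  lengths <- list()
  for (i in seq_len(n)) {
    net <- chords[[i]]
    kids <- which(parent == i)
    for (k in kids) net <- net - chords[[k]]
    net <- pmax(net, 0)
    mat <- shapes[[i]]$material$name
    lengths[[mat]] <- if (is.null(lengths[[mat]])) net else lengths[[mat]] + net
  }
  lengths <- lapply(lengths, function(m) m / 10)   # mm -> cm
  mats <- list()
  for (s in shapes) mats[[s$material$name]] <- s$material
  structure(list(lengths = lengths, materials = mats, geometry = geometry),
            class = "material_lengths")
}

#' Sinogram container
#'
#' @param values Projections x channels matrix of line-integral-domain values
#'   `g = -log` of the normalized detected intensity.
#' @param label `"LE"` or `"HE"`.
#' @param geometry The `"fan_geometry"` the data was sampled on.
#' @param meta Optional named list of provenance metadata.
#' @return Object of class `"ct_sinogram"`.
#' @export
ct_sinogram <- function(values, label, geometry, meta = list()) {
  stopifnot(is.matrix(values), inherits(geometry, "fan_geometry"),
            nrow(values) == geometry$n_projections,
            ncol(values) == geometry$n_channels)
  if (any(!is.finite(values))) stop("sinogram values must be finite")
  structure(list(values = values, label = label, geometry = geometry,
                 meta = meta),
            class = "ct_sinogram")
}

#' @export
print.ct_sinogram <- function(x, ...) {
  cat(sprintf("ct_sinogram %s: %d x %d, g in [%.3g, %.3g]\n", x$label,
              nrow(x$values), ncol(x$values), min(x$values), max(x$values)))
  invisible(x)
}

# transmitted fraction T (projections x channels) under a polychromatic
# response; chunked over projections to bound memory
.transmitted <- function(lengths, response, chunk = 64L) {
  stopifnot(inherits(lengths, "material_lengths"))
  geom <- lengths$geometry
  if (nrow(response$weights) != geom$n_channels)
    stop("response channel count does not match the geometry")
  e <- response$energies
  mu <- lapply(lengths$materials, material_mu, e = e)
  np <- geom$n_projections; nc <- geom$n_channels
  tt <- matrix(0, np, nc)
  for (p0 in seq(1L, np, by = chunk)) {
    p1 <- min(p0 + chunk - 1L, np)
    rows <- p0:p1
    acc <- matrix(0, length(rows) * nc, length(e))
    for (m in names(lengths$lengths)) {
      lm <- lengths$lengths[[m]][rows, , drop = FALSE]
      acc <- acc + tcrossprod(as.numeric(lm), mu[[m]])
    }
    wexp <- exp(-acc) * response$weights[rep(seq_len(nc), each = length(rows)), ]
    tt[rows, ] <- matrix(rowSums(wexp), length(rows), nc)
  }
  tt
}

#' Transmitted intensity under the polychromatic forward model
#'
#' @param lengths A `"material_lengths"`.
#' @param response A `"ct_response"` on the same geometry.
#' @return Projections x channels matrix of transmitted fractions in (0, 1].
#' @export
transmitted_intensity <- function(lengths, response) {
  .transmitted(lengths, response)
}

#' Polychromatic forward projection
#'
#' Evaluates the noise-free polychromatic Beer-Lambert model
#' `g = -log( sum_E W(E) exp(-sum_m mu_m(E) L_m) + s )` for every ray, where
#' `W` is the channel-dependent normalized energy response and `s` an
#' optional additive scatter intensity.
#'
#' @param lengths A `"material_lengths"`.
#' @param response A `"ct_response"` matching the geometry's channel count.
#' @param scatter Optional projections x channels matrix of additive scatter
#'   intensity (>= 0), or `NULL` for none.
#' @return A `"ct_sinogram"` labeled like the response.
#' @export
polychromatic_forward <- function(lengths, response, scatter = NULL) {
  tt <- .transmitted(lengths, response)
  if (!is.null(scatter)) {
    stopifnot(all(dim(scatter) == dim(tt)))
    if (any(scatter < 0)) stop("scatter must be non-negative")
    tt <- tt + scatter
  }
  if (any(tt <= 0)) stop("non-positive total intensity; cannot take -log")
  ct_sinogram(-log(tt), response$label, lengths$geometry)
}

#' Add Poisson counting noise to a sinogram
#'
#' Converts to the intensity domain, samples Poisson counts with
#' `photons_per_ray` incident photons, and log-transforms back. Sampled zero
#' counts are clipped to 0.5 counts so the log stays finite. With `n_repeats`
#' greater than one, that many independent noisy realizations are averaged in
#' the intensity domain, emulating repeat-and-average scan protocols.
#'
#' @param sinogram A `"ct_sinogram"`.
#' @param photons_per_ray Incident photons per ray (> 0).
#' @param seed Integer seed; the sampler is deterministic given the seed and
#'   restores the caller's RNG state.
#' @param n_repeats Number of averaged repeats (default 1).
#' @return A noisy `"ct_sinogram"`.
#' @export
add_poisson_noise <- function(sinogram, photons_per_ray, seed, n_repeats = 1L) {
  stopifnot(inherits(sinogram, "ct_sinogram"), photons_per_ray > 0,
            n_repeats >= 1L)
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(as.integer(seed))
  lam <- photons_per_ray * exp(-sinogram$values)
  big <- lam > 1e7    # normal approximation where rpois would overflow
  acc <- 0
  for (r in seq_len(n_repeats)) {
    counts <- lam
    counts[!big] <- stats::rpois(sum(!big), lam[!big])
    counts[big] <- lam[big] + sqrt(lam[big]) * stats::rnorm(sum(big))
    counts[counts < 0.5] <- 0.5
    acc <- acc + counts
  }
  out <- sinogram
  out$values <- -log(acc / (n_repeats * photons_per_ray))
  out$meta$noise <- list(photons_per_ray = photons_per_ray, seed = seed,
                         n_repeats = n_repeats)
  out
}
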