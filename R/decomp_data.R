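#' Training grid of basis-material lengths
#'
#' Inclusive uniform grids of water and calcium lengths whose cartesian
#' product (water outer, calcium inner) forms the training set for the
#' decomposition polynomials. Negative lengths are deliberately included so
#' the fitted polynomials cover materials that decompose with a negative
#' basis component (e.g. fat on a water/bone basis).
#'
#' @param w_range Water length interval in cm (default c(-2, 28)).
#' @param c_range Calcium length interval in cm (default c(-4, 5)).
#' @param step Grid step in cm (default 0.1).
#' @return Object of class `"length_grid"` with fields `w`, `c`, and `pairs`
#'   (two-column matrix, row-major over the product).
#' @export
length_grid <- function(w_range = c(-2, 28), c_range = c(-4, 5), step = 0.1) {
  stopifnot(step > 0, diff(w_range) > 0, diff(c_range) > 0)
  w <- seq(w_range[1], w_range[2], by = step)
  cc <- seq(c_range[1], c_range[2], by = step)
  structure(list(w = w, c = cc,
                 pairs = cbind(w = rep(w, each = length(cc)),
                               c = rep(cc, times = length(w)))),
            class = "length_grid")
}

# exponent table for bivariate polynomials of total degree <= degree
.poly_exponents <- function(degree, min_total = 0L) {
  kl <- expand.grid(k = 0:degree, l = 0:degree)
  kl <- kl[kl$k + kl$l <= degree & kl$k + kl$l >= min_total, , drop = FALSE]
  kl[order(kl$k + kl$l, kl$k), , drop = FALSE]
}

.poly_design <- function(gh, gl, exponents) {
  x <- matrix(1, length(gh), nrow(exponents))
  for (j in seq_len(nrow(exponents))) {
    k <- exponents$k[j]; l <- exponents$l[j]
    x[, j] <- (if (k > 0) gh^k else 1) * (if (l > 0) gl^l else 1)
  }
  x
}

# noise-free, scatter-free (g_he, g_le) for all grid pairs under one
# normalized spectral weight vector
.grid_measurements <- function(grid, energies, weights, mu_w, mu_c) {
  a <- outer(grid$pairs[, 1], mu_w) + outer(grid$pairs[, 2], mu_c)
  -log(as.numeric(exp(-a) %*% weights))
}

#' Fit the data-domain decomposition polynomials
#'
#' For every bowtie-thickness channel group (or the central group only),
#' simulates noise-free polychromatic measurements of all water/calcium
#' length pairs on the training grid through the known energy response, then
#' least-squares fits two bivariate polynomials (total degree `degree`,
#' default quintic) mapping normalized `(g_HE, g_LE)` to the water and
#' calcium lengths. The measurement pair is normalized to the unit square of
#' its fitted range before evaluation for Vandermonde conditioning.
#'
#' @param grid A [length_grid()].
#' @param response_le,response_he `"ct_response"` objects sharing the same
#'   channel grouping.
#' @param water,calcium Basis materials (defaults: packaged water and
#'   bone-equivalent calcium surrogate).
#' @param degree Total polynomial degree (default 5).
#' @param channel_binding `"per-group"` (default) or `"central"` (a single
#'   polynomial pair from the central channel's group, emulating a response
#'   assumed channel-independent).
#' @return Object of class `"decomp_polys"`.
#' @export
fit_decomposition_polynomials <- function(grid, response_le, response_he,
                                          water = default_materials()$water,
                                          calcium = default_materials()$bone,
                                          degree = 5,
                                          channel_binding = c("per-group",
                                                              "central")) {
  stopifnot(inherits(grid, "length_grid"), degree >= 1,
            inherits(response_le, "ct_response"),
            inherits(response_he, "ct_response"))
  channel_binding <- match.arg(channel_binding)
  if (!identical(response_le$groups, response_he$groups))
    stop("LE and HE responses must share the same channel grouping")
  groups <- response_le$groups
  mu_w_le <- material_mu(water, response_le$energies)
  mu_c_le <- material_mu(calcium, response_le$energies)
  mu_w_he <- material_mu(water, response_he$energies)
  mu_c_he <- material_mu(calcium, response_he$energies)
  exponents <- .poly_exponents(degree)
  group_ids <- if (channel_binding == "central") {
    central <- groups[ceiling(length(groups) / 2)]
    rep(central, 1L)
  } else seq_len(response_le$n_groups)
  fits <- vector("list", response_le$n_groups)
  for (gi in unique(group_ids)) {
    g_le <- .grid_measurements(grid, response_le$energies,
                               response_le$group_weights[gi, ], mu_w_le, mu_c_le)
    g_he <- .grid_measurements(grid, response_he$energies,
                               response_he$group_weights[gi, ], mu_w_he, mu_c_he)
    box <- list(he = range(g_he), le = range(g_le))
    uh <- (g_he - box$he[1]) / diff(box$he)
    ul <- (g_le - box$le[1]) / diff(box$le)
    x <- .poly_design(uh, ul, exponents)
    # the (g_HE, g_LE) cloud is a thin curved band, so the Vandermonde system
    # is ill-conditioned by nature; Householder QR handles it, but guard
    # against genuine rank collapse
    qr_x <- qr(x, LAPACK = TRUE)
    rdiag <- abs(diag(qr.R(qr_x)))
    if (min(rdiag) < 1e-13 * max(rdiag))
      stop("rank-deficient polynomial design; check measurement normalization")
    cw <- qr.coef(qr_x, grid$pairs[, 1])
    cc <- qr.coef(qr_x, grid$pairs[, 2])
    rw <- sqrt(mean((x %*% cw - grid$pairs[, 1])^2))
    rc <- sqrt(mean((x %*% cc - grid$pairs[, 2])^2))
    fits[[gi]] <- list(coef_w = cw, coef_c = cc, box = box,
                       rms_w = rw, rms_c = rc)
  }
  if (channel_binding == "central") {
    central <- groups[ceiling(length(groups) / 2)]
    for (gi in seq_len(response_le$n_groups)) fits[[gi]] <- fits[[central]]
  }
  structure(list(fits = fits, groups = groups, degree = degree,
                 exponents = exponents, channel_binding = channel_binding,
                 water = water$name, calcium = calcium$name),
            class = "decomp_polys")
}

#' @export
print.decomp_polys <- function(x, ...) {
  rms <- vapply(x$fits, function(f) c(f$rms_w, f$rms_c), numeric(2))
  cat(sprintf(paste0("decomp_polys: degree %d, %s binding, %d groups; ",
                     "max RMS residual %.4g cm (water) / %.4g cm (calcium)\n"),
              x$degree, x$channel_binding, length(x$fits),
              max(rms[1, ]), max(rms[2, ])))
  invisible(x)
}

#' Training residuals of fitted decomposition polynomials
#'
#' @param polys A `"decomp_polys"`.
#' @return Data frame with one row per channel group.
#' @export
decomposition_residuals <- function(polys) {
  data.frame(group = seq_along(polys$fits),
             rms_w = vapply(polys$fits, function(f) f$rms_w, numeric(1)),
             rms_c = vapply(polys$fits, function(f) f$rms_c, numeric(1)))
}

#' Apply the data-domain decomposition polynomials
#'
#' Elementwise evaluation of the fitted bivariate polynomial pair on
#' spatially aligned, scatter-subtracted LE/HE sinograms. Rays whose
#' normalized measurements fall outside the fitted domain box are evaluated
#' by polynomial continuation and counted in the outputs' metadata.
#'
#' @param le,he `"ct_sinogram"` objects (scatter already subtracted).
#' @param polys A `"decomp_polys"` fitted for the same responses.
#' @return List with `w` and `c`: `"ct_sinogram"` objects holding the water
#'   and calcium length estimates in cm.
#' @export
apply_decomposition <- function(le, he, polys) {
  stopifnot(inherits(le, "ct_sinogram"), inherits(he, "ct_sinogram"),
            inherits(polys, "decomp_polys"),
            all(dim(le$values) == dim(he$values)))
  lw <- le$values * 0
  lc <- lw
  n_out <- 0L
  for (gi in unique(polys$groups)) {
    cols <- which(polys$groups == gi)
    fit <- polys$fits[[gi]]
    gh <- as.numeric(he$values[, cols])
    gl <- as.numeric(le$values[, cols])
    uh <- (gh - fit$box$he[1]) / diff(fit$box$he)
    ul <- (gl - fit$box$le[1]) / diff(fit$box$le)
    n_out <- n_out + sum(uh < -0.02 | uh > 1.02 | ul < -0.02 | ul > 1.02)
    x <- .poly_design(uh, ul, polys$exponents)
    lw[, cols] <- x %*% fit$coef_w
    lc[, cols] <- x %*% fit$coef_c
  }
  out_w <- ct_sinogram(lw, le$label, le$geometry,
                       list(content = "water_length_cm",
                            extrapolated = n_out))
  out_c <- ct_sinogram(lc, le$label, le$geometry,
                       list(content = "calcium_length_cm",
                            extrapolated = n_out))
  list(w = out_w, c = out_c)
}

#' Fit conventional calibration-based decomposition polynomials
#'
#' Pools the rays of calibration scans (scatter included, no subtraction)
#' with their known water/calcium lengths and least-squares fits either the
#' cubic form `L = sum a_{k,l} g_HE^k g_LE^l` over `1 <= k+l <= 3` (nine
#' coefficients per material) or the constrained quartic form
#' `L_w = b1 (g_HE + g_LE) + sum_{k=2..4} b_k (g_HE - g_LE)^k`,
#' `L_c = b1 (g_HE - g_LE) + sum_{k=2..4} b_k (g_HE - g_LE)^k`
#' (four coefficients per material). Channel-to-channel energy-response
#' variation is deliberately disregarded (all rays pooled).
#'
#' @param calib_le,calib_he Lists of `"ct_sinogram"` calibration scans.
#' @param known_lengths List of `"material_lengths"` matching the scans.
#' @param variant `"cubic"` or `"constrained-quartic"`.
#' @param water,calcium Basis materials (used to pick the length arrays by
#'   material name; missing calcium in a scan counts as zero length).
#' @return Object of class `"conventional_polys"`.
#' @export
fit_conventional_polynomials <- function(calib_le, calib_he, known_lengths,
                                         variant = c("cubic",
                                                     "constrained-quartic"),
                                         water = default_materials()$water,
                                         calcium = default_materials()$bone) {
  variant <- match.arg(variant)
  stopifnot(length(calib_le) == length(calib_he),
            length(calib_le) == length(known_lengths))
  gh <- unlist(lapply(calib_he, function(s) as.numeric(s$values)))
  gl <- unlist(lapply(calib_le, function(s) as.numeric(s$values)))
  lw <- unlist(lapply(known_lengths, function(ml) {
    m <- ml$lengths[[water$name]]
    if (is.null(m)) stop("calibration scan lacks the water material")
    as.numeric(m)
  }))
  lc <- unlist(lapply(known_lengths, function(ml) {
    m <- ml$lengths[[calcium$name]]
    if (is.null(m)) m <- ml$lengths[[1]] * 0
    as.numeric(m)
  }))
  small <- sum(lc > 0 & lc < 0.5)
  if (small < 10)
    warning("small calcium lengths are poorly covered by the calibration scans")
  if (variant == "cubic") {
    exponents <- .poly_exponents(3, min_total = 1L)
    x <- .poly_design(gh, gl, exponents)
    cw <- qr.coef(qr(x), lw)
    cc <- qr.coef(qr(x), lc)
    fit <- list(exponents = exponents, coef_w = cw, coef_c = cc)
  } else {
    d <- gh - gl
    xw <- cbind(gh + gl, d^2, d^3, d^4)
    xc <- cbind(d, d^2, d^3, d^4)
    fit <- list(coef_w = qr.coef(qr(xw), lw), coef_c = qr.coef(qr(xc), lc))
  }
  res_w <- sqrt(mean((.conv_eval(gh, gl, fit, variant, "w") - lw)^2))
  res_c <- sqrt(mean((.conv_eval(gh, gl, fit, variant, "c") - lc)^2))
  structure(c(fit, list(variant = variant, rms_w = res_w, rms_c = res_c)),
            class = "conventional_polys")
}

.conv_eval <- function(gh, gl, fit, variant, which) {
  co <- if (which == "w") fit$coef_w else fit$coef_c
  if (variant == "cubic") {
    as.numeric(.poly_design(gh, gl, fit$exponents) %*% co)
  } else {
    d <- gh - gl
    x <- if (which == "w") cbind(gh + gl, d^2, d^3, d^4)
         else cbind(d, d^2, d^3, d^4)
    as.numeric(x %*% co)
  }
}

#' Apply conventional decomposition polynomials
#'
#' @param le,he Raw `"ct_sinogram"` objects (no scatter subtraction; the
#'   calibration embedded whatever scatter the calibration scans carried).
#' @param polys A `"conventional_polys"`.
#' @return List with `w` and `c` length sinograms in cm.
#' @export
apply_conventional <- function(le, he, polys) {
  stopifnot(inherits(polys, "conventional_polys"),
            all(dim(le$values) == dim(he$values)))
  gh <- as.numeric(he$values)
  gl <- as.numeric(le$values)
  lw <- matrix(.conv_eval(gh, gl, polys, polys$variant, "w"),
               nrow(le$values), ncol(le$values))
  lc <- matrix(.conv_eval(gh, gl, polys, polys$variant, "c"),
               nrow(le$values), ncol(le$values))
  list(w = ct_sinogram(lw, le$label, le$geometry,
                       list(content = "water_length_cm")),
       c = ct_sinogram(lc, le$label, le$geometry,
                       list(content = "calcium_length_cm")))
}
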