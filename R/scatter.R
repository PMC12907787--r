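#' Scatter model parameters
#'
#' Two free parameters per detector row: an amplitude `alpha` and a shape
#' exponent `beta`, with a fixed Gaussian kernel width `sigma` in detector
#' channels.
#'
#' @param alpha Amplitude (>= 0).
#' @param beta Shape exponent (> 0).
#' @param sigma Kernel width in channels (default 5).
#' @return Object of class `"scatter_params"`.
#' @export
scatter_params <- function(alpha, beta, sigma = 5) {
  stopifnot(is.finite(alpha), is.finite(beta), alpha >= 0, beta > 0, sigma > 0)
  structure(list(alpha = alpha, beta = beta, sigma = sigma),
            class = "scatter_params")
}

#' @export
print.scatter_params <- function(x, ...) {
  cat(sprintf("scatter_params: alpha %.4f, beta %.4f, sigma %g channels\n",
              x$alpha, x$beta, x$sigma))
  invisible(x)
}

# unit-sum Gaussian tap vector, truncated at 4 sigma
.gauss_taps <- function(sigma) {
  k <- seq(-ceiling(4 * sigma), ceiling(4 * sigma))
  w <- exp(-k^2 / (2 * sigma^2))
  list(k = k, w = w / sum(w))
}

# channel-direction Gaussian smoothing of a projections x channels matrix,
# edge-renormalized so constants are preserved; the banded kernel matrix is
# cached per (channel count, sigma) and applied with one BLAS multiply
.kernel_cache <- new.env(parent = emptyenv())

.smoothing_matrix <- function(nc, sigma) {
  key <- sprintf("%d_%g", nc, sigma)
  k <- .kernel_cache[[key]]
  if (is.null(k)) {
    taps <- .gauss_taps(sigma)
    k <- matrix(0, nc, nc)
    for (i in seq_along(taps$k)) {
      src <- seq_len(nc) + taps$k[i]
      ok <- src >= 1 & src <= nc
      k[cbind(src[ok], which(ok))] <- taps$w[i]
    }
    k <- sweep(k, 2, colSums(k), "/")
    .kernel_cache[[key]] <- k
  }
  k
}

.smooth_channels <- function(x, sigma) {
  x %*% .smoothing_matrix(ncol(x), sigma)
}

#' Scatter intensity profile
#'
#' Additive low-frequency scatter model
#' `s = alpha * Ibar * [G_sigma (*) I^beta] + alpha * Ibar * constant_frac`,
#' where `Ibar` is the per-projection mean primary intensity and `G_sigma`
#' is a unit-sum Gaussian kernel over detector channels. The optional
#' constant term supports a deliberately perturbed variant for
#' model-mismatch experiments.
#'
#' @param params A `"scatter_params"`.
#' @param primary Projections x channels matrix (or single-projection vector)
#'   of primary intensities in (0, 1].
#' @param sigma Kernel width override (defaults to `params$sigma`).
#' @param constant_frac Flat additive term as a fraction of `alpha * Ibar`
#'   (default 0).
#' @return Scatter intensity with the same shape as `primary`.
#' @export
scatter_profile <- function(params, primary, sigma = params$sigma,
                            constant_frac = 0) {
  stopifnot(inherits(params, "scatter_params"))
  vec <- is.null(dim(primary))
  x <- if (vec) matrix(primary, nrow = 1) else primary
  if (any(x <= 0) || any(x > 1 + 1e-9))
    stop("primary intensity must lie in (0, 1]")
  ibar <- rowMeans(x)
  s <- params$alpha * ibar * (.smooth_channels(x^params$beta, sigma) +
                                constant_frac)
  if (vec) as.numeric(s) else s
}

#' Water beam-hardening lookup table
#'
#' Tabulates, for every bowtie-thickness channel group of an energy
#' response, the strictly increasing map between the polychromatic water
#' value `g` and the water length `L` (including negative lengths), together
#' with the ideal mono-energetic line integral `mu_w(e_ref) * L`.
#'
#' @param response A `"ct_response"`.
#' @param water The water material.
#' @param e_ref Reference energy in keV (default 70).
#' @param l_range Water length range in cm (default c(-2, 40)).
#' @param l_step Table step in cm (default 0.1).
#' @return Object of class `"water_bhc_lookup"`.
#' @export
water_bhc_lookup <- function(response, water = default_materials()$water,
                             e_ref = 70, l_range = c(-2, 40), l_step = 0.1) {
  stopifnot(inherits(response, "ct_response"))
  lg <- seq(l_range[1], l_range[2], by = l_step)
  mu <- material_mu(water, response$energies)
  tabs <- lapply(seq_len(response$n_groups), function(gi) {
    w <- response$group_weights[gi, ]
    g <- -log(as.numeric(exp(-outer(lg, mu)) %*% w))
    if (any(diff(g) <= 0)) stop("water lookup is not strictly increasing")
    g
  })
  structure(list(l_grid = lg, g_tables = tabs, groups = response$groups,
                 e_ref = e_ref, mu_ref = material_mu(water, e_ref),
                 label = response$label),
            class = "water_bhc_lookup")
}

# linear interpolation with linear extrapolation from the end slopes;
# xtab strictly increasing
.interp_extrap <- function(xtab, ytab, x) {
  y <- stats::approx(xtab, ytab, xout = x, rule = 2)$y
  n <- length(xtab)
  lo <- x < xtab[1]
  hi <- x > xtab[n]
  if (any(lo)) {
    sl <- (ytab[2] - ytab[1]) / (xtab[2] - xtab[1])
    y[lo] <- ytab[1] + sl * (x[lo] - xtab[1])
  }
  if (any(hi)) {
    sl <- (ytab[n] - ytab[n - 1]) / (xtab[n] - xtab[n - 1])
    y[hi] <- ytab[n] + sl * (x[hi] - xtab[n])
  }
  y
}

#' Water beam-hardening correction
#'
#' Maps each (scatter-free) polychromatic value `g` to the ideal
#' mono-energetic water line integral `mu_w(e_ref) * L_w` by inverting the
#' per-channel-group water forward model. Values outside the tabulated range
#' are linearly extrapolated and counted in the returned object's metadata.
#'
#' @param sinogram A `"ct_sinogram"` with scatter already subtracted.
#' @param lookup A matching [water_bhc_lookup()].
#' @return Corrected `"ct_sinogram"` (mono-energetic water line-integral
#'   domain); `meta$bhc_extrapolated` counts out-of-table rays.
#' @export
water_bhc <- function(sinogram, lookup) {
  stopifnot(inherits(sinogram, "ct_sinogram"),
            inherits(lookup, "water_bhc_lookup"))
  v <- sinogram$values
  out <- v
  n_ex <- 0L
  for (gi in seq_along(lookup$g_tables)) {
    cols <- which(lookup$groups == gi)
    if (!length(cols)) next
    g <- v[, cols, drop = FALSE]
    gt <- lookup$g_tables[[gi]]
    n_ex <- n_ex + sum(g < gt[1] | g > gt[length(gt)])
    out[, cols] <- lookup$mu_ref *
      .interp_extrap(gt, lookup$l_grid, as.numeric(g))
  }
  res <- ct_sinogram(out, sinogram$label, sinogram$geometry, sinogram$meta)
  res$meta$bhc_extrapolated <- n_ex
  res
}

#' Emulated vendor water correction
#'
#' Builds a per-channel empirical map from raw measurements `g` (scatter and
#' beam hardening included) to the ideal mono-energetic water line integral,
#' from scans of centered water cylinders of known diameters, mirroring a
#' vendor pipeline calibrated to reconstruct a water phantom accurately.
#' Per channel, the projection-mean raw value of each cylinder is paired
#' with the known chord length and a monotone (Hyman) spline is fitted.
#'
#' @param scans List of `"ct_sinogram"` objects of centered water cylinders.
#' @param diameters_mm Cylinder diameters matching `scans`.
#' @param water Water material.
#' @param e_ref Reference energy in keV (default 70).
#' @return Object of class `"vendor_correction"`.
#' @export
calibrate_vendor_water_correction <- function(scans, diameters_mm,
                                              water = default_materials()$water,
                                              e_ref = 70) {
  stopifnot(length(scans) == length(diameters_mm), length(scans) >= 3)
  geom <- scans[[1]]$geometry
  gamma <- fan_angles(geom)
  d_iso <- geom$source_radius * abs(sin(gamma))   # ray distance to isocenter
  mu_ref <- material_mu(water, e_ref)
  nc <- geom$n_channels
  gbar <- vapply(scans, function(s) colMeans(s$values), numeric(nc))
  ltab <- vapply(diameters_mm, function(d) {
    r <- d / 2
    ifelse(d_iso < r, 2 * sqrt(pmax(r^2 - d_iso^2, 0)) / 10, 0)
  }, numeric(nc))
  maps <- vector("list", nc)
  for (i in seq_len(nc)) {
    x <- gbar[i, ]
    y <- mu_ref * ltab[i, ]
    o <- order(x)
    x <- x[o]; y <- y[o]
    if (any(diff(y) < -1e-9))
      stop("non-monotone calibration pairs on channel ", i)
    keep <- c(TRUE, diff(x) > 1e-9)
    x <- x[keep]; y <- y[keep]
    maps[[i]] <- list(x = x, y = y)
  }
  structure(list(maps = maps, e_ref = e_ref, mu_ref = mu_ref,
                 diameters_mm = diameters_mm,
                 label = scans[[1]]$label),
            class = "vendor_correction")
}

# evaluate one vendor channel map: monotone spline inside the calibrated
# range, linear continuation outside
.vendor_eval <- function(map, g) {
  n <- length(map$x)
  if (n == 1L) {
    # channel outside every calibration cylinder: only the zero-length
    # anchor exists; continue with unit slope (raw g is already close to
    # the mono water scale there)
    return(map$y[1] + (g - map$x[1]))
  }
  if (n >= 3 && all(diff(map$y) > 0)) {
    f <- stats::splinefun(map$x, map$y, method = "hyman")
    y <- f(pmin(pmax(g, map$x[1]), map$x[n]))
    lo <- g < map$x[1]; hi <- g > map$x[n]
    if (any(lo)) y[lo] <- map$y[1] + f(map$x[1], deriv = 1) * (g[lo] - map$x[1])
    if (any(hi)) y[hi] <- map$y[n] + f(map$x[n], deriv = 1) * (g[hi] - map$x[n])
    y
  } else {
    .interp_extrap(map$x, map$y, g)
  }
}

#' Apply the emulated vendor correction to a sinogram
#'
#' @param sinogram A raw `"ct_sinogram"` (scatter and hardening included).
#' @param correction A `"vendor_correction"` for the same label/geometry.
#' @return Corrected `"ct_sinogram"` in the mono-energetic water
#'   line-integral domain.
#' @export
apply_vendor_correction <- function(sinogram, correction) {
  stopifnot(inherits(sinogram, "ct_sinogram"),
            inherits(correction, "vendor_correction"))
  v <- sinogram$values
  out <- v
  for (i in seq_len(ncol(v)))
    out[, i] <- .vendor_eval(correction$maps[[i]], v[, i])
  ct_sinogram(out, sinogram$label, sinogram$geometry, sinogram$meta)
}

#' Subtract scatter from a sinogram
#'
#' With a known scatter matrix the subtraction is exact:
#' `g' = -log(exp(-g) - s)`. With model parameters, the primary intensity is
#' recovered by solving the fixed-point equation `I_p + s(I_p) = I_raw` with
#' a damped Picard iteration (the model computes scatter from the primary
#' intensity, so subtraction is a nonlinear inversion).
#'
#' @param sinogram A `"ct_sinogram"`.
#' @param params A `"scatter_params"`, or `NULL` when `scatter` is given.
#' @param scatter Optional known scatter intensity matrix.
#' @param sigma,constant_frac Model overrides forwarded to
#'   [scatter_profile()].
#' @param floor Intensity floor; corrected intensities below it are clipped
#'   (count reported in `meta$scatter_clipped`).
#' @param tol,max_iter Fixed-point iteration controls.
#' @param warm_start Optional primary-intensity matrix used to initialize
#'   the iteration.
#' @return Corrected `"ct_sinogram"`; the recovered primary intensity is
#'   attached as attribute `"primary"`.
#' @export
subtract_scatter <- function(sinogram, params = NULL, scatter = NULL,
                             sigma = NULL, constant_frac = 0, floor = 1e-6,
                             tol = 1e-10, max_iter = 400, warm_start = NULL) {
  stopifnot(inherits(sinogram, "ct_sinogram"))
  i_raw <- exp(-sinogram$values)
  if (!is.null(scatter)) {
    ip <- i_raw - scatter
  } else {
    stopifnot(inherits(params, "scatter_params"))
    if (is.null(sigma)) sigma <- params$sigma
    ip <- if (is.null(warm_start)) pmin(i_raw, 1) else warm_start
    lambda <- 0.5
    res_prev <- Inf
    for (it in seq_len(max_iter)) {
      s <- scatter_profile(params, pmin(pmax(ip, floor), 1), sigma = sigma,
                           constant_frac = constant_frac)
      r <- i_raw - ip - s
      res <- max(abs(r))
      if (res > res_prev) lambda <- lambda * 0.5
      res_prev <- res
      ip <- ip + lambda * r
      if (res < tol) break
    }
  }
  n_clip <- sum(ip < floor)
  ip <- pmax(ip, floor)
  out <- ct_sinogram(-log(pmin(ip, Inf)), sinogram$label, sinogram$geometry,
                     sinogram$meta)
  out$meta$scatter_clipped <- n_clip
  attr(out, "primary") <- ip
  out
}

#' Estimate object-specific scatter parameters
#'
#' Nelder-Mead simplex minimization of the mean-squared mismatch between a
#' vendor-emulation-corrected reference sinogram and the raw sinogram after
#' model-based scatter subtraction followed by water beam-hardening
#' correction. The iteration starts at `alpha = beta = 1` and stops when the
#' spread of the simplex in the parameters and in the cost are both below
#' `tol`.
#'
#' @param raw Raw `"ct_sinogram"` (with scatter).
#' @param reference Spatially aligned reference `"ct_sinogram"` (e.g. from
#'   [apply_vendor_correction()]).
#' @param lookup A [water_bhc_lookup()] for the same response.
#' @param init Initial `(alpha, beta)` (default `c(1, 1)`).
#' @param sigma Kernel width used by the estimation model (default 5).
#' @param tol Simultaneous tolerance on parameter and cost changes
#'   (default 1e-4).
#' @param max_iter Iteration cap (default 500).
#' @return A `"scatter_params"` with attributes `iterations`, `cost`, and
#'   `converged`.
#' @export
estimate_scatter_params <- function(raw, reference, lookup, init = c(1, 1),
                                    sigma = 5, tol = 1e-4, max_iter = 500) {
  stopifnot(inherits(raw, "ct_sinogram"), inherits(reference, "ct_sinogram"),
            all(dim(raw$values) == dim(reference$values)))
  warm <- new.env(parent = emptyenv())
  warm$ip <- NULL
  cost_fn <- function(p) {
    if (p[1] < 0 || p[2] <= 0.05) return(1e8 * (1 + sum(pmax(-p, 0))))
    sp <- scatter_params(p[1], p[2], sigma)
    sub <- subtract_scatter(raw, sp, tol = 1e-7, warm_start = warm$ip)
    warm$ip <- attr(sub, "primary")
    corr <- water_bhc(sub, lookup)
    mean((corr$values - reference$values)^2)
  }
  fit <- .nelder_mead(cost_fn, init, tol = tol, max_iter = max_iter)
  if (!fit$converged)
    warning("scatter estimation did not converge within ", max_iter,
            " iterations (cost ", format(fit$value), ")")
  out <- scatter_params(max(fit$par[1], 0), fit$par[2], sigma)
  attr(out, "iterations") <- fit$iterations
  attr(out, "cost") <- fit$value
  attr(out, "converged") <- fit$converged
  out
}

# Nelder-Mead with the classical reflect/expand/contract/shrink moves and a
# stopping rule on the simultaneous spread of parameters and cost values
.nelder_mead <- function(fn, init, tol = 1e-4, max_iter = 500, step = 0.2) {
  n <- length(init)
  simplex <- rbind(init, t(sapply(seq_len(n), function(i) {
    p <- init; p[i] <- p[i] + step; p
  })))
  fv <- apply(simplex, 1, fn)
  it <- 0L
  converged <- FALSE
  while (it < max_iter) {
    it <- it + 1L
    o <- order(fv)
    simplex <- simplex[o, , drop = FALSE]
    fv <- fv[o]
    if (max(abs(sweep(simplex, 2, simplex[1, ]))) < tol &&
        max(fv) - min(fv) < tol) {
      converged <- TRUE
      break
    }
    centroid <- colMeans(simplex[seq_len(n), , drop = FALSE])
    xr <- centroid + (centroid - simplex[n + 1, ])
    fr <- fn(xr)
    if (fr < fv[1]) {
      xe <- centroid + 2 * (centroid - simplex[n + 1, ])
      fe <- fn(xe)
      if (fe < fr) { simplex[n + 1, ] <- xe; fv[n + 1] <- fe }
      else { simplex[n + 1, ] <- xr; fv[n + 1] <- fr }
    } else if (fr < fv[n]) {
      simplex[n + 1, ] <- xr; fv[n + 1] <- fr
    } else {
      xc <- centroid + 0.5 * (simplex[n + 1, ] - centroid)
      fc <- fn(xc)
      if (fc < fv[n + 1]) { simplex[n + 1, ] <- xc; fv[n + 1] <- fc }
      else {
        for (i in seq(2, n + 1)) {
          simplex[i, ] <- simplex[1, ] + 0.5 * (simplex[i, ] - simplex[1, ])
          fv[i] <- fn(simplex[i, ])
        }
      }
    }
  }
  o <- order(fv)
  list(par = simplex[o[1], ], value = fv[o[1]], iterations = it,
       converged = converged)
}
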