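#' Reconstructed image container
#'
#' @param pixels Square 2D matrix; row 1 is the top of the image, y up.
#' @param pixel_size Pixel size in mm.
#' @param grid_offset (dx, dy) of the grid center in mm relative to the
#'   isocenter.
#' @param units One of `"mu"` (1/cm), `"density"` (relative density), `"HU"`.
#' @param meta Optional metadata list.
#' @return Object of class `"ct_image"`.
#' @export
ct_image <- function(pixels, pixel_size, grid_offset = c(0, 0), units = "mu",
                     meta = list()) {
  stopifnot(is.matrix(pixels), nrow(pixels) == ncol(pixels), pixel_size > 0,
            length(grid_offset) == 2L,
            units %in% c("mu", "density", "HU"))
  if (any(!is.finite(pixels))) stop("image pixels must be finite")
  structure(list(pixels = pixels, pixel_size = pixel_size,
                 grid_offset = as.numeric(grid_offset), units = units,
                 meta = meta),
            class = "ct_image")
}

#' @export
print.ct_image <- function(x, ...) {
  cat(sprintf("ct_image: %d x %d @ %g mm [%s], range [%.4g, %.4g]\n",
              nrow(x$pixels), ncol(x$pixels), x$pixel_size, x$units,
              min(x$pixels), max(x$pixels)))
  invisible(x)
}

#' Pixel-center coordinates of an image grid
#'
#' @param image A `"ct_image"` (or compatible list).
#' @return List with vectors `x` (per column) and `y` (per row, decreasing)
#'   in mm.
#' @export
image_coords <- function(image) {
  n <- nrow(image$pixels)
  half <- (n + 1) / 2
  list(x = (seq_len(n) - half) * image$pixel_size + image$grid_offset[1],
       y = (half - seq_len(n)) * image$pixel_size + image$grid_offset[2])
}

#' Rebin a 360-degree fan-beam sinogram to parallel geometry
#'
#' Resamples fan-beam data onto a uniform (parallel angle, radial offset)
#' grid by bilinear interpolation, using the relations `s = -R sin(gamma)`
#' and `theta = beta + gamma + pi/2`.
#'
#' @param sinogram A full-scan `"ct_sinogram"`.
#' @param n_angles Parallel view count over 180 degrees (default half the
#'   fan projection count).
#' @param n_radial Radial sample count (default the channel count).
#' @param s_max Radial half-range in mm (default the geometry's field-of-view
#'   radius).
#' @return Object of class `"parallel_sinogram"` with fields `values`
#'   (angles x radial), `theta` (radians), `s_mm`, `label`.
#' @export
rebin_fan_to_parallel <- function(sinogram,
                                  n_angles = sinogram$geometry$n_projections %/% 2L,
                                  n_radial = sinogram$geometry$n_channels,
                                  s_max = fov_radius(sinogram$geometry)) {
  stopifnot(inherits(sinogram, "ct_sinogram"))
  geom <- sinogram$geometry
  if (geom$n_projections < 90L)
    warning("coarse angular sampling; rebinned data may alias")
  rr <- geom$source_radius
  theta <- pi * (seq_len(n_angles) - 1) / n_angles
  s <- seq(-s_max, s_max, length.out = n_radial)
  gamma <- -asin(pmin(pmax(s / rr, -1), 1))
  gam_grid <- fan_angles(geom)
  dgam <- gam_grid[2] - gam_grid[1]
  dbeta <- 2 * pi / geom$n_projections
  # fractional channel index of each radial sample (constant across angles)
  fg <- (gamma - gam_grid[1]) / dgam + 1
  g0 <- floor(fg); wg <- fg - g0
  inside <- g0 >= 1 & g0 <= geom$n_channels - 1
  g0c <- pmin(pmax(g0, 1), geom$n_channels - 1)
  vals <- matrix(0, n_angles, n_radial)
  v <- sinogram$values
  np <- geom$n_projections
  for (j in seq_len(n_angles)) {
    beta <- (theta[j] - gamma - pi / 2) %% (2 * pi)
    fb <- beta / dbeta + 1
    b0 <- floor(fb); wb <- fb - b0
    b0i <- ((b0 - 1) %% np) + 1
    b1i <- (b0i %% np) + 1
    row <- (1 - wb) * ((1 - wg) * v[cbind(b0i, g0c)] + wg * v[cbind(b0i, g0c + 1)]) +
           wb       * ((1 - wg) * v[cbind(b1i, g0c)] + wg * v[cbind(b1i, g0c + 1)])
    row[!inside] <- 0
    vals[j, ] <- row
  }
  structure(list(values = vals, theta = theta, s_mm = s,
                 label = sinogram$label),
            class = "parallel_sinogram")
}

# band-limited spatial-domain ramp filter (sampling step ds in cm)
.ramp_kernel <- function(n, ds) {
  k <- seq(-(n - 1), n - 1)
  h <- numeric(length(k))
  h[k == 0] <- 1 / (4 * ds^2)
  odd <- k %% 2 != 0
  h[odd] <- -1 / (pi^2 * k[odd]^2 * ds^2)
  h
}

# frequency-domain apodization window on the FFT bin frequencies
.apod_window <- function(l, ds, apodization) {
  nu <- c(seq(0, l / 2), seq(-l / 2 + 1, -1)) / (l * ds)
  nyq <- 1 / (2 * ds)
  x <- pmin(abs(nu) / nyq, 1)
  switch(apodization,
         ramlak = rep(1, l),
         cosine = cos(pi * x / 2),
         hann   = 0.5 * (1 + cos(pi * x)))
}

#' Filtered backprojection of a parallel-beam sinogram
#'
#' Ramp-filtered (band-limited spatial-domain kernel, FFT convolution, with
#' a smooth frequency apodization emulating a moderately smooth quantitative
#' reconstruction kernel) pixel-driven backprojection with linear
#' interpolation, onto a centered or shifted pixel grid.
#'
#' @param psino A `"parallel_sinogram"`.
#' @param n_pixels Image side length in pixels (default 256).
#' @param pixel_size Pixel size in mm (default 1.0; 0.49 mm at full scale).
#' @param grid_offset (dx, dy) in mm of the reconstruction grid center, used
#'   to compensate deliberate phantom shifts.
#' @param apodization `"cosine"` (default), `"hann"`, or `"ramlak"`.
#' @return A `"ct_image"` in the units of the sinogram domain (attenuation
#'   line integrals reconstruct to 1/cm; length line integrals in cm
#'   reconstruct to relative density).
#' @export
fbp_reconstruct <- function(psino, n_pixels = 256, pixel_size = 1.0,
                            grid_offset = c(0, 0),
                            apodization = c("cosine", "hann", "ramlak")) {
  stopifnot(inherits(psino, "parallel_sinogram"))
  apodization <- match.arg(apodization)
  ns <- length(psino$s_mm)
  ds <- (psino$s_mm[2] - psino$s_mm[1]) / 10    # cm
  l <- 2^ceiling(log2(2 * ns))
  h <- .ramp_kernel(ns, ds)
  hpad <- c(h, numeric(l - length(h)))
  hf <- stats::fft(hpad) * .apod_window(l, ds, apodization)
  n_ang <- length(psino$theta)
  q <- matrix(0, n_ang, ns)
  for (j in seq_len(n_ang)) {
    p <- c(psino$values[j, ], numeric(l - ns))
    conv <- Re(stats::fft(stats::fft(p) * hf, inverse = TRUE)) / l
    q[j, ] <- ds * conv[ns:(2 * ns - 1)]
  }
  half <- (n_pixels + 1) / 2
  x <- (seq_len(n_pixels) - half) * pixel_size + grid_offset[1]
  y <- (half - seq_len(n_pixels)) * pixel_size + grid_offset[2]
  xm <- matrix(x, n_pixels, n_pixels, byrow = TRUE)
  ym <- matrix(y, n_pixels, n_pixels)
  img <- matrix(0, n_pixels, n_pixels)
  s1 <- psino$s_mm[1]
  dsm <- psino$s_mm[2] - psino$s_mm[1]
  for (j in seq_len(n_ang)) {
    sp <- xm * cos(psino$theta[j]) + ym * sin(psino$theta[j])
    fi <- (sp - s1) / dsm + 1
    i0 <- floor(fi)
    w <- fi - i0
    ok <- i0 >= 1 & i0 <= ns - 1
    i0[!ok] <- 1
    qj <- q[j, ]
    contrib <- (1 - w) * qj[i0] + w * qj[i0 + 1]
    contrib[!ok] <- 0
    img <- img + contrib
  }
  img <- img * pi / n_ang
  ct_image(img, pixel_size, grid_offset, units = "mu",
           meta = list(apodization = apodization, label = psino$label))
}

#' Rebin and reconstruct a fan-beam sinogram
#'
#' Convenience wrapper chaining [rebin_fan_to_parallel()] and
#' [fbp_reconstruct()].
#'
#' @param sinogram A `"ct_sinogram"`.
#' @param ... Passed to [fbp_reconstruct()].
#' @inheritParams rebin_fan_to_parallel
#' @return A `"ct_image"`.
#' @export
reconstruct_sinogram <- function(sinogram,
                                 n_angles = sinogram$geometry$n_projections %/% 2L,
                                 n_radial = sinogram$geometry$n_channels, ...) {
  fbp_reconstruct(rebin_fan_to_parallel(sinogram, n_angles, n_radial), ...)
}
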