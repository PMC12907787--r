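#' Read a testbench configuration file
#'
#' YAML key-value configuration merged over [dect_default_config()].
#'
#' @param path YAML file path.
#' @return Configuration list.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  over <- yaml::read_yaml(path)
  bad <- setdiff(names(over), names(dect_default_config()))
  if (length(bad))
    stop("unknown config key(s): ", paste(bad, collapse = ", "))
  .merge_config(dect_default_config(), over)
}

#' Write a configuration file
#'
#' @param config Configuration list.
#' @param path Output YAML path.
#' @return The path, invisibly.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

#' Deterministic configuration fingerprint
#'
#' A short hexadecimal fingerprint of the serialized configuration, used to
#' stamp output files with their provenance.
#'
#' @param config Configuration list.
#' @return Character fingerprint.
#' @export
config_fingerprint <- function(config) {
  txt <- paste(utils::capture.output(utils::str(config, digits.d = 15)),
               collapse = "\n")
  bytes <- utf8ToInt(txt)
  h1 <- 7; h2 <- 11
  for (b in bytes) {
    h1 <- (h1 * 131 + b) %% 2147483629
    h2 <- (h2 * 137 + b) %% 2147483587
  }
  sprintf("%08x%08x", h1, h2)
}

.write_array <- function(values, path, sidecar) {
  con <- file(paste0(path, ".bin"), "wb")
  on.exit(close(con))
  writeBin(as.numeric(t(values)), con, size = 8, endian = "little")
  sidecar$shape <- dim(values)
  sidecar$dtype <- "float64"
  sidecar$order <- "row-major"
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
}

.read_array <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  n <- prod(meta$shape)
  con <- file(paste0(path, ".bin"), "rb")
  on.exit(close(con))
  v <- readBin(con, "numeric", n = n, size = 8, endian = "little")
  list(values = matrix(v, meta$shape[1], meta$shape[2], byrow = TRUE),
       meta = meta)
}

#' Write a sinogram to the array container format
#'
#' Raw little-endian float64 binary (`<path>.bin`, row-major) plus a JSON
#' sidecar (`<path>.json`) carrying shape, label, and geometry.
#'
#' @param sinogram A `"ct_sinogram"`.
#' @param path Path stem (without extension).
#' @return The path stem, invisibly.
#' @export
write_sinogram <- function(sinogram, path) {
  stopifnot(inherits(sinogram, "ct_sinogram"))
  g <- sinogram$geometry
  .write_array(sinogram$values, path,
               list(kind = "sinogram", label = sinogram$label,
                    geometry = unclass(g),
                    meta = sinogram$meta[setdiff(names(sinogram$meta),
                                                 c("scatter",
                                                   "scatter_params"))]))
  invisible(path)
}

#' Read a sinogram from the array container format
#'
#' @param path Path stem used by [write_sinogram()].
#' @return A `"ct_sinogram"`.
#' @export
read_sinogram <- function(path) {
  a <- .read_array(path)
  gm <- a$meta$geometry
  geom <- fan_geometry(gm$n_projections, gm$n_channels, gm$source_to_detector,
                       gm$source_radius, gm$channel_width_deg)
  ct_sinogram(a$values, a$meta$label, geom, as.list(a$meta$meta))
}

#' Write an image to the array container format
#'
#' @param image A `"ct_image"`.
#' @param path Path stem (without extension).
#' @return The path stem, invisibly.
#' @export
write_image_bin <- function(image, path) {
  stopifnot(inherits(image, "ct_image"))
  .write_array(image$pixels, path,
               list(kind = "image", units = image$units,
                    pixel_size_mm = image$pixel_size,
                    grid_offset_mm = image$grid_offset, meta = image$meta))
  invisible(path)
}

#' Read an image from the array container format
#'
#' @param path Path stem used by [write_image_bin()].
#' @return A `"ct_image"`.
#' @export
read_image_bin <- function(path) {
  a <- .read_array(path)
  ct_image(a$values, a$meta$pixel_size_mm,
           unlist(a$meta$grid_offset_mm), a$meta$units, as.list(a$meta$meta))
}

#' Export an image as an 8-bit PNG with window/level
#'
#' @param image A `"ct_image"`.
#' @param path PNG path.
#' @param window,level Grayscale window width and center in the image's
#'   units (defaults: full range).
#' @return The path, invisibly.
#' @export
write_image_png <- function(image, path, window = NULL, level = NULL) {
  stopifnot(inherits(image, "ct_image"))
  px <- image$pixels
  if (is.null(window)) window <- diff(range(px))
  if (is.null(level)) level <- mean(range(px))
  if (window <= 0) window <- 1
  z <- pmin(pmax((px - level) / window + 0.5, 0), 1)
  grDevices::png(path, width = ncol(px), height = nrow(px))
  op <- graphics::par(mar = c(0, 0, 0, 0))
  graphics::image(t(z[nrow(z):1, ]), col = grDevices::gray.colors(256, 0, 1),
                  axes = FALSE, useRaster = TRUE)
  graphics::par(op)
  grDevices::dev.off()
  invisible(path)
}

#' Export an image as a 16-bit TIFF with window/level metadata
#'
#' Requires the optional `tiff` package.
#'
#' @inheritParams write_image_png
#' @return The path, invisibly.
#' @export
write_image_tiff <- function(image, path, window = NULL, level = NULL) {
  if (!requireNamespace("tiff", quietly = TRUE))
    stop("the 'tiff' package is required for TIFF export")
  px <- image$pixels
  if (is.null(window)) window <- diff(range(px))
  if (is.null(level)) level <- mean(range(px))
  if (window <= 0) window <- 1
  z <- pmin(pmax((px - level) / window + 0.5, 0), 1)
  tiff::writeTIFF(z, path, bits.per.sample = 16L)
  invisible(path)
}
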