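#' Simplified bremsstrahlung source spectrum
#'
#' Kramers-type tube spectrum `S(E) ~ (kV - E) * E` for `10 <= E <= kV`,
#' attenuated by configurable inherent aluminum-equivalent filtration.
#' Characteristic lines are intentionally not modeled.
#'
#' @param kv Tube voltage in kV.
#' @param grid An [energy_grid()]; defaults to 1 keV steps from 30 keV to kV.
#'   Energies below 30 keV are treated as fully absorbed by the inherent
#'   filtration: they carry a relative fluence of order 1e-9 after 2.5 mm of
#'   aluminum yet would dominate `exp(+mu L)` terms when the decomposition
#'   training grid includes negative material lengths.
#' @param inherent_al_cm Inherent filtration thickness in cm of aluminum
#'   (default 0.25 cm, i.e. 2.5 mm Al).
#' @param aluminum Material used for the filtration (defaults to the packaged
#'   aluminum fixture).
#' @return List with `energies` and unnormalized `fluence`.
#' @export
xray_spectrum <- function(kv, grid = NULL, inherent_al_cm = 0.25,
                          aluminum = default_materials()$aluminum) {
  stopifnot(kv > 30, kv <= .E_MAX)
  if (is.null(grid)) grid <- energy_grid(30, kv, 1)
  e <- as.numeric(grid)
  if (max(e) > kv) stop("energy grid exceeds tube voltage")
  s <- pmax(kv - e, 0) * e
  if (inherent_al_cm > 0)
    s <- s * exp(-material_mu(aluminum, e) * inherent_al_cm)
  list(energies = e, fluence = s)
}

#' Bowtie filter thickness profile
#'
#' Quadratic aluminum-equivalent thickness in the fan angle,
#' `t(gamma) = t0 + t2 * gamma^2`, with `t2` set so that the edge channels
#' receive `edge_factor` times the central filtration.
#'
#' @param gamma Fan angles of the channels in radians.
#' @param t0_cm Central thickness in cm (default 0.2 cm).
#' @param edge_factor Ratio of edge to central thickness (default 3).
#' @return Per-channel thickness in cm.
#' @export
bowtie_profile <- function(gamma, t0_cm = 0.2, edge_factor = 3) {
  stopifnot(t0_cm >= 0, edge_factor >= 1)
  gmax <- max(abs(gamma))
  t2 <- if (gmax > 0) t0_cm * (edge_factor - 1) / gmax^2 else 0
  t0_cm + t2 * gamma^2
}

#' Channel-dependent analytical energy response
#'
#' Builds the normalized per-channel spectral weighting used by the
#' polychromatic forward model: the product of the source spectrum, the
#' bowtie-filter transmission for that channel, and an energy-integrating
#' detector weighting `d(E) = E`, with every channel row normalized to sum
#' to one. Channels are additionally binned into groups of similar bowtie
#' thickness; per-group average responses support desk-scale per-group
#' fitting (beam-hardening lookup, decomposition polynomials).
#'
#' @param tube_kv Tube voltage (80 kV for the low-energy scan, 120 kV for the
#'   high-energy scan by default).
#' @param gamma Fan angles of the detector channels in radians (e.g. from
#'   [fan_angles()]).
#' @param grid Optional [energy_grid()].
#' @param bowtie_cm Optional per-channel bowtie thickness in cm; defaults to
#'   [bowtie_profile()] on `gamma`.
#' @param n_groups Number of bowtie-thickness groups (default 32).
#' @param label `"LE"` or `"HE"`; inferred from `tube_kv` when `NULL`.
#' @param inherent_al_cm,aluminum Passed to [xray_spectrum()].
#' @return Object of class `"ct_response"` with fields `label`, `kv`,
#'   `energies`, `weights` (channels x energies), `bowtie_cm`, `groups`
#'   (per-channel group index), `group_weights` (groups x energies).
#' @export
build_energy_response <- function(tube_kv, gamma, grid = NULL, bowtie_cm = NULL,
                                  n_groups = 32, label = NULL,
                                  inherent_al_cm = 0.25,
                                  aluminum = default_materials()$aluminum) {
  spec <- xray_spectrum(tube_kv, grid, inherent_al_cm, aluminum)
  e <- spec$energies
  n_chan <- length(gamma)
  if (is.null(bowtie_cm)) bowtie_cm <- bowtie_profile(gamma)
  if (length(bowtie_cm) != n_chan)
    stop("bowtie profile length must equal the channel count")
  if (is.null(label))
    label <- if (tube_kv <= 100) "LE" else "HE"
  mu_al <- material_mu(aluminum, e)
  base <- spec$fluence * e                       # source x detector d(E) = E
  w <- exp(-outer(bowtie_cm, mu_al)) * rep(base, each = n_chan)
  rs <- rowSums(w)
  if (any(rs <= 0)) stop("degenerate spectrum: a channel row is all zero")
  w <- w / rs
  n_groups <- min(n_groups, n_chan)
  groups <- .bin_by_value(bowtie_cm, n_groups)
  gw <- rowsum(w, groups)
  gw <- gw / rowSums(gw)
  structure(list(label = label, kv = tube_kv, energies = e, weights = w,
                 bowtie_cm = bowtie_cm, groups = groups,
                 group_weights = gw, n_groups = nrow(gw)),
            class = "ct_response")
}

# equal-width bins over the value range; returns integer codes 1..<=n_bins
.bin_by_value <- function(x, n_bins) {
  if (n_bins <= 1L || diff(range(x)) == 0) return(rep(1L, length(x)))
  br <- seq(min(x), max(x), length.out = n_bins + 1L)
  idx <- findInterval(x, br, rightmost.closed = TRUE, all.inside = TRUE)
  as.integer(factor(idx))   # drop empty bins, keep codes contiguous
}

#' @export
print.ct_response <- function(x, ...) {
  cat(sprintf("ct_response %s (%g kV): %d channels x %d energies, %d bowtie groups\n",
              x$label, x$kv, nrow(x$weights), length(x$energies), x$n_groups))
  cat(sprintf("  central-channel mean energy %.1f keV\n",
              response_mean_energy(x)[ceiling(nrow(x$weights) / 2)]))
  invisible(x)
}

#' Per-channel mean energy of an energy response
#'
#' @param response A `"ct_response"`.
#' @return Mean energy in keV per channel.
#' @export
response_mean_energy <- function(response) {
  as.numeric(response$weights %*% response$energies)
}

# response restricted to one row of weights (used for per-group physics)
.group_response <- function(response, group) {
  list(energies = response$energies,
       weights = response$group_weights[group, , drop = TRUE])
}
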