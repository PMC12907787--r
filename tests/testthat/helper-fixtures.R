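# Shared fixtures, built lazily and cached for the whole test session.
.fix <- new.env(parent = emptyenv())

fix_get <- function(name, builder) {
  if (is.null(.fix[[name]])) .fix[[name]] <- builder()
  .fix[[name]]
}

# tiny geometry: fast forward projections for algebraic checks
tiny_geometry <- function() {
  fix_get("tiny_geom", function() fan_geometry(180L, 92L))
}

# mid geometry: enough sampling for reconstruction-quality checks
mid_geometry <- function() {
  fix_get("mid_geom", function() fan_geometry(360L, 184L))
}

mats_fix <- function() default_materials()

# monoenergetic response: all weight on one energy, same object layout as
# build_energy_response
mono_response <- function(geometry, e0 = 70, kv = 120, label = "HE",
                          n_groups = 8L) {
  resp <- build_energy_response(kv, fan_angles(geometry), n_groups = n_groups,
                                label = label)
  i <- which(resp$energies == e0)
  stopifnot(length(i) == 1L)
  resp$weights[] <- 0
  resp$weights[, i] <- 1
  resp$group_weights[] <- 0
  resp$group_weights[, i] <- 1
  resp
}

tiny_responses <- function() {
  fix_get("tiny_resp", function() {
    g <- tiny_geometry()
    list(LE = build_energy_response(80, fan_angles(g), n_groups = 12L),
         HE = build_energy_response(120, fan_angles(g), n_groups = 12L))
  })
}

# small full setup used by pipeline-level tests (matched scatter so exact
# subtraction is available)
small_setup <- function() {
  fix_get("small_setup", function() {
    cfg <- dect_default_config(
      geometry = list(n_projections = 360L, n_channels = 184L),
      recon = list(n_pixels = 192L, pixel_size = 1.3),
      spectra = list(n_groups = 24L),
      scatter = list(mode = "matched"))
    dect_setup(cfg)
  })
}

small_acr_scans <- function() {
  fix_get("small_acr_scans", function() {
    setup <- small_setup()
    ph <- make_acr_module_a(c(0, 0), mats_fix())
    list(LE = simulate_phantom_scan(ph, setup, "LE"),
         HE = simulate_phantom_scan(ph, setup, "HE"))
  })
}

expect_rel_equal <- function(object, expected, rel_tol) {
  testthat::expect_lt(abs(object - expected), rel_tol * abs(expected))
}

# full default-scale runs shared by the acceptance criteria
acc_matched_run <- function() {
  fix_get("acc_matched", function() {
    cfg <- dect_default_config(scatter = list(mode = "matched"))
    setup <- dect_setup(cfg, vendor = FALSE)
    ph <- make_acr_module_a(c(0, 0), mats_fix())
    le <- simulate_phantom_scan(ph, setup, "LE")
    he <- simulate_phantom_scan(ph, setup, "HE")
    data_based_pipeline(le, he, setup, scatter_handling = "true-params")
  })
}

acc_mismatch_run <- function() {
  fix_get("acc_mismatch", function() {
    cfg <- dect_default_config()
    setup <- dect_setup(cfg)
    ph <- make_acr_module_a(c(0, 0), mats_fix())
    le <- simulate_phantom_scan(ph, setup, "LE")
    he <- simulate_phantom_scan(ph, setup, "HE")
    data_based_pipeline(le, he, setup, scatter_handling = "estimate")
  })
}
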