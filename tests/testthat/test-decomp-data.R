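test_that("length grid enumerates the documented training set", {
  grid <- length_grid(c(-2, 28), c(-4, 5), 0.1)
  expect_length(grid$w, 301L)
  expect_length(grid$c, 91L)
  expect_true(any(grid$w < 0))
  expect_true(any(grid$c < 0))
  expect_equal(nrow(grid$pairs), 301L * 91L)
  # row-major: water varies slowest
  expect_equal(grid$pairs[1:91, 1], rep(grid$w[1], 91))
  expect_equal(grid$pairs[1:91, 2], grid$c)
})

test_that("monoenergetic limit is exactly linear (degree 1 suffices)", {
  geom <- tiny_geometry()
  mats <- mats_fix()
  mono_le <- mono_response(geom, 55, kv = 80, label = "LE", n_groups = 4L)
  mono_he <- mono_response(geom, 75, kv = 120, label = "HE", n_groups = 4L)
  grid <- length_grid(c(-2, 28), c(-4, 5), 0.5)
  p1 <- fit_decomposition_polynomials(grid, mono_le, mono_he,
                                      mats$water, mats$bone, degree = 1)
  expect_lt(max(decomposition_residuals(p1)[, -1]), 1e-8)
})

test_that("quintic fit quality and residual monotonicity in degree", {
  resp <- tiny_responses()
  mats <- mats_fix()
  grid <- length_grid()
  res <- sapply(c(1, 3, 5), function(d) {
    p <- fit_decomposition_polynomials(grid, resp$LE, resp$HE,
                                       mats$water, mats$bone, degree = d)
    unlist(decomposition_residuals(p)[1, c("rms_w", "rms_c")])
  })
  # nested least squares: residuals shrink as the degree grows
  expect_true(all(diff(res["rms_w", ]) < 0))
  expect_true(all(diff(res["rms_c", ]) < 0))
  # quintic training residual under 0.05 cm for both materials
  expect_lt(res["rms_w", 3], 0.05)
  expect_lt(res["rms_c", 3], 0.05)
})

test_that("decomposition round-trips forward-simulated rays", {
  setup <- small_setup()
  mats <- mats_fix()
  geom <- setup$geometry
  polys <- setup$polys
  # build one sinogram pair holding known length pairs on a few rays
  cases <- rbind(c(17.5, 0.25), c(0, 0), c(20, 0), c(10, 2), c(5, -0.5))
  nray <- nrow(cases)
  g_of <- function(resp, lw, lc) {
    vapply(seq_len(resp$n_groups), function(gi) {
      w <- resp$group_weights[gi, ]
      -log(sum(w * exp(-material_mu(mats$water, resp$energies) * lw -
                         material_mu(mats$bone, resp$energies) * lc)))
    }, numeric(1))
  }
  vals_le <- matrix(0, nray, geom$n_channels)
  vals_he <- matrix(0, nray, geom$n_channels)
  for (i in seq_len(nray)) {
    vals_le[i, ] <- g_of(setup$responses$LE, cases[i, 1],
                         cases[i, 2])[setup$responses$LE$groups]
    vals_he[i, ] <- g_of(setup$responses$HE, cases[i, 1],
                         cases[i, 2])[setup$responses$HE$groups]
  }
  geom_n <- fan_geometry(nray, geom$n_channels,
                         geom$source_to_detector, geom$source_radius,
                         geom$channel_width_deg)
  le <- ct_sinogram(vals_le, "LE", geom_n)
  he <- ct_sinogram(vals_he, "HE", geom_n)
  polys_n <- polys
  lens <- apply_decomposition(le, he, polys_n)
  for (i in seq_len(nray)) {
    expect_lt(max(abs(lens$w$values[i, ] - cases[i, 1])), 0.05)
    expect_lt(max(abs(lens$c$values[i, ] - cases[i, 2])), 0.05)
  }
})

test_that("conventional polynomial forms have the printed term counts", {
  setup <- small_setup()
  mats <- mats_fix()
  phs <- lapply(c("central-calcium", "offset-calcium"),
                make_calibration_phantom, materials = mats)
  calib_le <- lapply(phs, simulate_phantom_scan, setup = setup, label = "LE")
  calib_he <- lapply(phs, simulate_phantom_scan, setup = setup, label = "HE")
  known <- lapply(phs, path_lengths, geometry = setup$geometry)
  cubic <- fit_conventional_polynomials(calib_le, calib_he, known, "cubic",
                                        mats$water, mats$bone)
  expect_length(cubic$coef_w, 9L)
  expect_length(cubic$coef_c, 9L)
  quart <- fit_conventional_polynomials(calib_le, calib_he, known,
                                        "constrained-quartic",
                                        mats$water, mats$bone)
  expect_length(quart$coef_w, 4L)
  expect_length(quart$coef_c, 4L)
})

test_that("conventional cubic is exact on monoenergetic scatter-free data", {
  geom <- tiny_geometry()
  mats <- mats_fix()
  mono_le <- mono_response(geom, 55, kv = 80, label = "LE")
  mono_he <- mono_response(geom, 75, kv = 120, label = "HE")
  phs <- lapply(c("central-calcium", "offset-calcium"),
                make_calibration_phantom, materials = mats)
  known <- lapply(phs, path_lengths, geometry = geom)
  calib_le <- lapply(known, polychromatic_forward, response = mono_le)
  calib_he <- lapply(known, polychromatic_forward, response = mono_he)
  fit <- suppressWarnings(
    fit_conventional_polynomials(calib_le, calib_he, known, "cubic",
                                 mats$water, mats$bone))
  lens <- apply_conventional(calib_le[[1]], calib_he[[1]], fit)
  expect_lt(max(abs(lens$w$values - known[[1]]$lengths$water)), 1e-6)
  expect_lt(max(abs(lens$c$values - known[[1]]$lengths$bone)), 1e-6)
})
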