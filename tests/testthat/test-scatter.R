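test_that("scatter profile algebra: zero amplitude, constants, linearity", {
  p <- scatter_params(1.5, 1)
  i_const <- rep(0.4, 64)
  expect_equal(scatter_profile(scatter_params(0, 1), i_const), rep(0, 64))
  # constant primary with beta = 1: unit-sum kernel preserves the constant
  expect_equal(scatter_profile(p, i_const), rep(1.5 * 0.4^2, 64),
               tolerance = 1e-12)
  i_var <- 0.05 + 0.9 * abs(sin(seq(0, 3, length.out = 64)))
  s1 <- scatter_profile(scatter_params(1, 0.9), i_var)
  s2 <- scatter_profile(scatter_params(2, 0.9), i_var)
  expect_equal(s2, 2 * s1, tolerance = 1e-12)
  expect_true(all(s1 >= 0))
})

test_that("scatter subtraction inverts the forward contamination", {
  scans <- small_acr_scans()
  raw <- scans$LE
  s_true <- raw$meta$scatter
  clean <- ct_sinogram(-log(exp(-raw$values) - s_true), "LE", raw$geometry)
  # known-matrix subtraction is exact
  sub <- subtract_scatter(raw, scatter = s_true)
  expect_lt(max(abs(sub$values - clean$values)), 1e-10)
  # zero scatter: identity
  sub0 <- subtract_scatter(clean, scatter = s_true * 0)
  expect_equal(sub0$values, clean$values)
  # g increases wherever scatter was removed
  expect_true(all((sub$values - raw$values)[s_true > 0] > 0))
  # parameter-based subtraction solves the nonlinear model inversion
  subp <- subtract_scatter(raw, raw$meta$scatter_params)
  expect_lt(max(abs(subp$values - clean$values)), 1e-6)
})

test_that("water beam-hardening correction round-trips known lengths", {
  geom <- tiny_geometry()
  mats <- mats_fix()
  resp <- tiny_responses()$LE
  lookup <- water_bhc_lookup(resp, mats$water, 70)
  # monoenergetic response at e_ref: correction is the identity
  mono <- mono_response(geom, 70, kv = 80, label = "LE", n_groups = 12L)
  lk_mono <- water_bhc_lookup(mono, mats$water, 70)
  L <- path_lengths(make_water_cylinder(180, mats), geom)
  g_mono <- polychromatic_forward(L, mono)
  corr <- water_bhc(g_mono, lk_mono)
  expect_lt(max(abs(corr$values - g_mono$values)), 1e-9)
  # polychromatic forward of L = 15 cm inverts to mu_ref * 15
  gv <- vapply(seq_len(resp$n_groups), function(gi) {
    w <- resp$group_weights[gi, ]
    -log(sum(w * exp(-material_mu(mats$water, resp$energies) * 15)))
  }, numeric(1))
  sino15 <- ct_sinogram(matrix(gv[resp$groups], geom$n_projections,
                               geom$n_channels, byrow = TRUE), "LE", geom)
  c15 <- water_bhc(sino15, lookup)
  expect_lt(max(abs(c15$values - material_mu(mats$water, 70) * 15)), 1e-3)
  # monotonicity
  np <- geom$n_projections
  g_lo <- water_bhc(ct_sinogram(matrix(1.0, np, geom$n_channels), "LE", geom),
                    lookup)
  g_hi <- water_bhc(ct_sinogram(matrix(1.5, np, geom$n_channels), "LE", geom),
                    lookup)
  expect_true(all(g_hi$values > g_lo$values))
})

test_that("vendor emulation reproduces held-out water line integrals within 1%", {
  mats <- mats_fix()
  mu_ref <- material_mu(mats$water, 70)
  # interpolation accuracy proper: scatter-free calibration and held-out
  geom <- tiny_geometry()
  resp <- tiny_responses()$LE
  diam <- c(100, 150, 200, 250, 300)
  scans <- lapply(diam, function(d)
    polychromatic_forward(path_lengths(make_water_cylinder(d, mats), geom),
                          resp))
  vend <- calibrate_vendor_water_correction(scans, diam, mats$water, 70)
  held <- polychromatic_forward(
    path_lengths(make_water_cylinder(225, mats), geom), resp)
  corr <- apply_vendor_correction(held, vend)
  d_iso <- geom$source_radius * abs(sin(fan_angles(geom)))
  l_true <- ifelse(d_iso < 112.5, 2 * sqrt(pmax(112.5^2 - d_iso^2, 0)) / 10, 0)
  ideal <- mu_ref * l_true
  inside <- l_true > 2
  rel <- abs(colMeans(corr$values)[inside] - ideal[inside]) / ideal[inside]
  expect_lt(max(rel), 0.01)
  # monoenergetic limit: the map is the mu_ref scale itself
  mono <- mono_response(geom, 70, kv = 80, label = "LE")
  scans_m <- lapply(diam, function(d)
    polychromatic_forward(path_lengths(make_water_cylinder(d, mats), geom),
                          mono))
  vend_m <- calibrate_vendor_water_correction(scans_m, diam, mats$water, 70)
  held_m <- polychromatic_forward(
    path_lengths(make_water_cylinder(225, mats), geom), mono)
  corr_m <- apply_vendor_correction(held_m, vend_m)
  expect_lt(max(abs(corr_m$values - held_m$values)), 1e-6)
  # applied to the ACR phantom, rays through bone are under-corrected
  # (water-only assumption breaks near dense inserts)
  acr <- polychromatic_forward(
    path_lengths(make_acr_module_a(c(0, 0), mats), geom), resp)
  acr_corr <- apply_vendor_correction(acr, vend)
  L <- path_lengths(make_acr_module_a(c(0, 0), mats), geom)
  ideal_acr <- mu_ref * (L$lengths$water + L$lengths$bone)
  bone_rays <- L$lengths$bone > 2
  resid <- acr_corr$values[bone_rays] - ideal_acr[bone_rays]
  expect_gt(mean(resid), 0)   # bone attenuates more than assumed water
})

test_that("scatter parameter estimation recovers matched-model truth", {
  setup <- small_setup()
  mats <- mats_fix()
  geom <- setup$geometry
  resp <- setup$responses$LE
  lookup <- setup$lookups$LE
  L <- path_lengths(make_acr_module_a(c(0, 0), mats), geom)
  tt <- transmitted_intensity(L, resp)
  truth <- scatter_params(2.0, 0.95)
  raw <- ct_sinogram(-log(tt + scatter_profile(truth, tt)), "LE", geom)
  clean <- ct_sinogram(-log(tt), "LE", geom)
  reference <- water_bhc(clean, lookup)   # ideal reference: no vendor error
  est <- estimate_scatter_params(raw, reference, lookup)
  expect_lt(abs(est$alpha - 2.0) / 2.0, 0.01)
  expect_lt(abs(est$beta - 0.95) / 0.95, 0.01)
  expect_true(attr(est, "converged"))
  # descent against the initial simplex point
  cost_at <- function(p) {
    sub <- subtract_scatter(raw, scatter_params(p[1], p[2]))
    mean((water_bhc(sub, lookup)$values - reference$values)^2)
  }
  expect_lte(attr(est, "cost"), cost_at(c(1, 1)))
  # zero-scatter input: the optimizer finds (near-)zero amplitude
  est0 <- estimate_scatter_params(clean, reference, lookup)
  expect_lt(est0$alpha, 0.02)
  # independent cross-check: stats::optim lands on the same optimum
  op <- stats::optim(c(1, 1), cost_at, method = "Nelder-Mead",
                     control = list(reltol = 1e-10))
  expect_lt(abs(op$par[1] - est$alpha), 0.02)
  expect_lt(abs(op$par[2] - est$beta), 0.01)
})

test_that("parameter recovery holds across the amplitude/shape grid", {
  mats <- mats_fix()
  geom <- tiny_geometry()
  resp <- tiny_responses()$LE
  lookup <- water_bhc_lookup(resp, mats$water, 70)
  L <- path_lengths(make_water_cylinder(220, mats), geom)
  tt <- transmitted_intensity(L, resp)
  clean_ref <- water_bhc(ct_sinogram(-log(tt), "LE", geom), lookup)
  grid <- expand.grid(alpha = c(0.5, 1.6, 3.0), beta = c(0.8, 0.95, 1.1))
  rel_err <- apply(grid, 1, function(p) {
    truth <- scatter_params(p[1], p[2])
    raw <- ct_sinogram(-log(tt + scatter_profile(truth, tt)), "LE", geom)
    est <- estimate_scatter_params(raw, clean_ref, lookup)
    max(abs(est$alpha - p[1]) / p[1], abs(est$beta - p[2]) / p[2])
  })
  expect_lt(stats::median(rel_err), 0.02)
})
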