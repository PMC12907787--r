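test_that("analytic chords: diameter, tangent, and replacement rule", {
  geom <- tiny_geometry()
  mats <- mats_fix()
  L <- path_lengths(make_water_cylinder(200, mats), geom)
  # the most central ray sees the chord predicted by its isocenter distance
  s <- geom$source_radius * abs(sin(fan_angles(geom)))
  d_min <- min(s)
  expect_equal(max(L$lengths$water), 2 * sqrt(100^2 - d_min^2) / 10,
               tolerance = 1e-9)
  # rays with |s| > 100 mm miss the phantom entirely
  missing <- which(s > 100 + 1e-6)
  expect_true(all(L$lengths$water[, missing] == 0))
  # a bone insert on the central axis replaces water along the ray
  ph <- ct_phantom(ct_disk(c(0, 0), 100, mats$water),
                   list(ct_disk(c(0, 0), 12.5, mats$bone)))
  L2 <- path_lengths(ph, geom)
  i <- which.max(L2$lengths$bone)
  expect_equal(L2$lengths$bone[i], 2 * sqrt(12.5^2 - d_min^2) / 10,
               tolerance = 1e-9)
  expect_equal(L2$lengths$water[i] + L2$lengths$bone[i],
               2 * sqrt(100^2 - d_min^2) / 10, tolerance = 1e-9)
})

test_that("polychromatic forward model limits and sublinearity", {
  geom <- tiny_geometry()
  mats <- mats_fix()
  resp <- tiny_responses()$LE
  # zero-length rays give exactly g = 0
  L <- path_lengths(make_water_cylinder(100, mats), geom)
  sino <- polychromatic_forward(L, resp)
  outside <- geom$source_radius * abs(sin(fan_angles(geom))) > 51
  expect_lt(max(abs(sino$values[, outside])), 1e-12)
  # monoenergetic limit is exactly linear in the lengths
  mono <- mono_response(geom, 70)
  g_mono <- polychromatic_forward(L, mono)
  expect_equal(g_mono$values,
               material_mu(mats$water, 70) * L$lengths$water,
               tolerance = 1e-12)
  # beam hardening: doubling the length less than doubles g
  L2 <- L; L2$lengths$water <- 2 * L$lengths$water
  g1 <- polychromatic_forward(L, resp)$values
  g2 <- polychromatic_forward(L2, resp)$values
  thick <- L$lengths$water > 5
  expect_true(all(g2[thick] < 2 * g1[thick]))
  # monotone in every material length
  expect_true(all(g2[thick] > g1[thick]))
})

test_that("Poisson noise is seeded, unbiased at high flux, and 1/N-scaled", {
  geom <- tiny_geometry()
  mats <- mats_fix()
  L <- path_lengths(make_water_cylinder(150, mats), geom)
  sino <- polychromatic_forward(L, mono_response(geom, 70))
  n1 <- add_poisson_noise(sino, 1e4, seed = 7)
  n2 <- add_poisson_noise(sino, 1e4, seed = 7)
  expect_identical(n1$values, n2$values)
  n3 <- add_poisson_noise(sino, 1e4, seed = 8)
  expect_false(identical(n1$values, n3$values))
  # noise-free limit
  hi <- add_poisson_noise(sino, 1e12, seed = 1)
  expect_lt(max(abs(hi$values - sino$values)), 1e-4)
  # delta-method variance of -log(Poisson/N) at g = 0 is 1/N
  zero <- ct_sinogram(matrix(0, geom$n_projections, geom$n_channels),
                      "LE", geom)
  nz <- add_poisson_noise(zero, 1e4, seed = 3)
  expect_lt(abs(stats::var(as.numeric(nz$values)) * 1e4 - 1), 0.1)
})

test_that("scan simulation stores the true scatter and respects the FOV", {
  setup <- small_setup()
  ph <- make_acr_module_a(c(0, 0), mats_fix())
  scan <- small_acr_scans()$LE
  expect_equal(dim(scan$meta$scatter), dim(scan$values))
  expect_true(all(scan$meta$scatter >= 0))
  expect_error(path_lengths(make_water_cylinder(600, mats_fix()),
                            setup$geometry),
               "field of view")
})
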