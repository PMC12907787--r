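test_that("rebinning: zero data, rotational symmetry, offset sinusoid", {
  geom <- mid_geometry()
  mats <- mats_fix()
  zero <- ct_sinogram(matrix(0, geom$n_projections, geom$n_channels),
                      "LE", geom)
  expect_true(all(rebin_fan_to_parallel(zero)$values == 0))
  # centered disk: every rebinned view is (nearly) the same profile
  L <- path_lengths(make_water_cylinder(160, mats), geom)
  par <- rebin_fan_to_parallel(polychromatic_forward(L, mono_response(geom, 70)))
  spread <- apply(par$values, 2, function(col) diff(range(col)))
  expect_lt(max(spread), 0.02 * max(par$values))
  # small offset insert traces a sinusoid of amplitude r0 in the radial bin
  ph <- ct_phantom(ct_disk(c(0, 0), 100, mats$air),
                   list(ct_disk(c(40, 0), 3, mats$bone)))
  parb <- rebin_fan_to_parallel(
    polychromatic_forward(path_lengths(ph, geom), mono_response(geom, 70)))
  peak_s <- parb$s_mm[apply(parb$values, 1, which.max)]
  fit_amp <- sqrt(mean(peak_s^2) * 2)
  expect_lt(abs(fit_amp - 40), 2)
  expect_lt(max(abs(peak_s)), 40 + 2)
})

test_that("FBP reconstructs a uniform disk to the known attenuation", {
  geom <- mid_geometry()
  mats <- mats_fix()
  L <- path_lengths(make_water_cylinder(160, mats), geom)
  img <- reconstruct_sinogram(polychromatic_forward(L, mono_response(geom, 70)),
                              n_pixels = 192, pixel_size = 1.3)
  cc <- image_coords(img)
  r <- outer(cc$y, cc$x, function(y, x) sqrt(x^2 + y^2))
  inner <- img$pixels[r < 50]
  mu70 <- material_mu(mats$water, 70)
  expect_lt(abs(mean(inner) - mu70) / mu70, 0.01)
  # linearity of the whole chain
  s1 <- polychromatic_forward(L, mono_response(geom, 70))
  s2 <- s1; s2$values <- 0.5 * s1$values
  i1 <- reconstruct_sinogram(s1, n_pixels = 96, pixel_size = 2.6)
  i2 <- reconstruct_sinogram(s2, n_pixels = 96, pixel_size = 2.6)
  expect_equal(i2$pixels, 0.5 * i1$pixels, tolerance = 1e-12)
})

test_that("shifted phantom with compensating grid matches centered recon", {
  # full sampling density: the 2 HU bound is a statement about the method,
  # not about coarse-grid interpolation error
  geom <- fan_geometry()
  mats <- mats_fix()
  mono <- mono_response(geom, 70)
  mu_w <- material_mu(mats$water, 70)
  ph0 <- make_acr_module_a(c(0, 0), mats)
  ph1 <- make_acr_module_a(c(0, 48), mats)
  img0 <- reconstruct_sinogram(polychromatic_forward(path_lengths(ph0, geom),
                                                     mono),
                               n_pixels = 256, pixel_size = 1)
  img1 <- reconstruct_sinogram(polychromatic_forward(path_lengths(ph1, geom),
                                                     mono),
                               n_pixels = 256, pixel_size = 1,
                               grid_offset = c(0, 48))
  rois <- acr_roi_specs()
  for (nm in c("bone", "polyethylene", "acrylic", "air", "water_insert")) {
    m0 <- roi_stats(img0, rois[[nm]])$mean
    m1 <- roi_stats(img1, rois[[nm]])$mean
    # compare in HU against the water reference
    expect_lt(abs(hu_from_mu(m1, mu_w) - hu_from_mu(m0, mu_w)), 2, label = nm)
  }
})
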