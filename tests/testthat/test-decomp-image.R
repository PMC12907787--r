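test_that("relative-density ratio reproduces the worked examples", {
  expect_equal(round(insert_ratio(1.0053, 2.1429), 4), 2.1316)
  expect_equal(round(insert_ratio(1.0035, 1.8446), 4), 1.8382)
  expect_equal(insert_ratio(0.998, 0.998), 1)
})

test_that("effective-energy lookup is self-consistent and ordered", {
  curve <- ratio_curve()
  r64 <- curve$ratio[curve$energies == 64.0]
  expect_equal(find_effective_energy(r64, curve), 64.0, tolerance = 1e-6)
  # uniqueness: the monotone curve crosses any interior ratio exactly once
  r_mid <- mean(range(curve$ratio))
  crossings <- sum(diff(sign(curve$ratio - r_mid)) != 0)
  expect_equal(crossings, 1L)
  # a larger ratio (more photoelectric contrast) maps to a lower energy
  e_hi <- find_effective_energy(r_mid * 1.1, curve)
  e_lo <- find_effective_energy(r_mid * 0.95, curve)
  expect_lt(e_hi, e_lo)
  expect_error(find_effective_energy(max(curve$ratio) * 1.5, curve),
               "no crossing")
})

test_that("pixelwise decomposition inverts the basis exactly", {
  mats <- mats_fix()
  dm <- decomposition_matrix(55, 75, mats$water, mats$bone)
  n <- 8
  mk <- function(v) ct_image(matrix(v, n, n), 1, units = "mu")
  # water basis vector
  dec_w <- decompose_pixelwise(mk(material_mu(mats$water, 55)),
                               mk(material_mu(mats$water, 75)), dm)
  expect_equal(dec_w$w$pixels, matrix(1, n, n), tolerance = 1e-12)
  expect_equal(dec_w$c$pixels, matrix(0, n, n), tolerance = 1e-12)
  # calcium basis vector
  dec_c <- decompose_pixelwise(mk(material_mu(mats$bone, 55)),
                               mk(material_mu(mats$bone, 75)), dm)
  expect_equal(dec_c$w$pixels, matrix(0, n, n), tolerance = 1e-12)
  expect_equal(dec_c$c$pixels, matrix(1, n, n), tolerance = 1e-12)
  # linearity
  a <- 0.3; b <- 1.4
  p1 <- list(le = 0.21, he = 0.17); p2 <- list(le = 0.35, he = 0.24)
  d1 <- decompose_pixelwise(mk(p1$le), mk(p1$he), dm)
  d2 <- decompose_pixelwise(mk(p2$le), mk(p2$he), dm)
  d12 <- decompose_pixelwise(mk(a * p1$le + b * p2$le),
                             mk(a * p1$he + b * p2$he), dm)
  expect_equal(d12$w$pixels, a * d1$w$pixels + b * d2$w$pixels,
               tolerance = 1e-12)
  expect_error(decomposition_matrix(64, 64.000001), "singular")
})

test_that("VMI synthesis anchors water, vacuum, and the inversion identity", {
  mats <- mats_fix()
  n <- 6
  f1 <- ct_image(matrix(1, n, n), 1, units = "density")
  f0 <- ct_image(matrix(0, n, n), 1, units = "density")
  expect_equal(synthesize_vmi(f1, f0, 85, mats$water, mats$bone)$pixels,
               matrix(0, n, n))
  expect_equal(synthesize_vmi(f0, f0, 85, mats$water, mats$bone)$pixels,
               matrix(-1000, n, n))
  # image-based path: VMI at eps_LE reproduces the LE image to machine
  # precision (D^-1 then recombination at a basis energy)
  dm <- decomposition_matrix(58, 79, mats$water, mats$bone)
  set.seed(42)
  le <- ct_image(matrix(runif(n * n, 0.1, 0.5), n, n), 1, units = "mu")
  he <- ct_image(matrix(runif(n * n, 0.1, 0.4), n, n), 1, units = "mu")
  dec <- decompose_pixelwise(le, he, dm)
  vmi_le <- synthesize_vmi(dec$w, dec$c, 58, mats$water, mats$bone,
                           units = "mu")
  expect_equal(vmi_le$pixels, le$pixels, tolerance = 1e-12)
  vmi_he <- synthesize_vmi(dec$w, dec$c, 79, mats$water, mats$bone,
                           units = "mu")
  expect_equal(vmi_he$pixels, he$pixels, tolerance = 1e-12)
})

test_that("data- and image-based decompositions agree in the mono limit", {
  # with monoenergetic LE/HE responses both reduce to the same exact linear
  # algebra, so the VMIs must agree pixel-for-pixel to < 1 HU
  geom <- mid_geometry()
  mats <- mats_fix()
  e_le <- 55; e_he <- 75
  mono_le <- mono_response(geom, e_le, kv = 80, label = "LE", n_groups = 4L)
  mono_he <- mono_response(geom, e_he, kv = 120, label = "HE", n_groups = 4L)
  ph <- make_acr_module_a(c(0, 0), mats)
  L <- path_lengths(ph, geom)
  sle <- polychromatic_forward(L, mono_le)
  she <- polychromatic_forward(L, mono_he)
  # data-based: decompose rays, reconstruct densities
  grid <- length_grid(step = 0.5)
  polys <- fit_decomposition_polynomials(grid, mono_le, mono_he,
                                         mats$water, mats$bone, degree = 1)
  lens <- apply_decomposition(sle, she, polys)
  fw_d <- reconstruct_sinogram(lens$w, n_pixels = 128, pixel_size = 1.95)
  fc_d <- reconstruct_sinogram(lens$c, n_pixels = 128, pixel_size = 1.95)
  vmi_d <- synthesize_vmi(fw_d, fc_d, 65, mats$water, mats$bone)
  # image-based: reconstruct mu images, decompose pixels
  img_le <- reconstruct_sinogram(sle, n_pixels = 128, pixel_size = 1.95)
  img_he <- reconstruct_sinogram(she, n_pixels = 128, pixel_size = 1.95)
  dm <- decomposition_matrix(e_le, e_he, mats$water, mats$bone)
  dec <- decompose_pixelwise(img_le, img_he, dm)
  vmi_i <- synthesize_vmi(dec$w, dec$c, 65, mats$water, mats$bone)
  expect_lt(max(abs(vmi_d$pixels - vmi_i$pixels)), 1)
})
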