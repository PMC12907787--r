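# experiment-level checks run on a deliberately coarse geometry: they verify
# plumbing and reproducibility, not reconstruction quality
tiny_cfg <- function(...) {
  dect_default_config(
    geometry = list(n_projections = 180L, n_channels = 92L),
    recon = list(n_pixels = 96L, pixel_size = 2.6),
    spectra = list(n_groups = 8L),
    eval = list(energies = c(50, 70, 100)),
    ...)
}

test_that("zero simulated scatter makes the ablation difference vanish", {
  cfg <- tiny_cfg(scatter = list(mode = "none"))
  setup <- dect_setup(cfg)
  res <- run_scatter_ablation(cfg, setup = setup)
  # with no scatter simulated, correction and omission coincide (the
  # estimator finds alpha ~ 0); the residual spurious amplitude at the cost
  # floor moves the coarse-grid VMIs by at most a few HU
  for (e in c("50", "70"))
    expect_lt(max(abs(res$diff[[e]]$pixels)), 3)
  expect_equal(nrow(res$profile), 96L)
})

test_that("simulated scatter produces visible shading when uncorrected", {
  cfg <- tiny_cfg(scatter = list(mode = "mismatch"))
  setup <- dect_setup(cfg)
  res <- run_scatter_ablation(cfg, setup = setup)
  # omitting the correction must shift the water background by > 5 HU
  # somewhere (shading/cupping)
  expect_gt(max(abs(res$diff[["70"]]$pixels[roi_mask(res$diff[["70"]],
                                                     roi_circle(c(0, -60), 10))])),
            5)
})

test_that("experiment outputs are reproducible from config plus seed", {
  cfg <- tiny_cfg(scatter = list(mode = "matched"))
  setup <- dect_setup(cfg)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  run_accuracy_experiment(cfg, setup = setup, positions = "centered",
                          methods = "data", out_dir = d1)
  run_accuracy_experiment(cfg, setup = setup, positions = "centered",
                          methods = "data", out_dir = d2)
  expect_identical(readBin(file.path(d1, "metrics.csv"), "raw", 1e6),
                   readBin(file.path(d2, "metrics.csv"), "raw", 1e6))
})

test_that("position-consistency profiles overlap on the abdomen surrogate", {
  # full sampling density over the wide (500 mm) field of view: the 6 HU
  # overlap bound concerns the method, not coarse-grid interpolation noise
  cfg <- dect_default_config(
    recon = list(n_pixels = 256L, pixel_size = 1.95),
    decomp = list(w_range = c(-2, 45), step = 0.2),
    scatter = list(mode = "matched"))
  setup <- dect_setup(cfg)
  res <- run_position_consistency(cfg, setup = setup)
  expect_lt(res$max_abs_diff_hu, 6)
})

test_that("estimated scatter correction removes most of the water-background bias", {
  # self-consistent (matched-model) scatter: estimate + subtract must cut
  # the downstream reconstructed HU bias in the water background by >= 80%
  # relative to omitting the correction
  cfg <- tiny_cfg(scatter = list(mode = "matched"))
  setup <- dect_setup(cfg)
  mats <- mats_fix()
  ph <- make_acr_module_a(c(0, 0), mats)
  le <- simulate_phantom_scan(ph, setup, "LE")
  he <- simulate_phantom_scan(ph, setup, "HE")
  with_corr <- data_based_pipeline(le, he, setup)
  without <- data_based_pipeline(le, he, setup, scatter_handling = "none")
  # scatter-free reference isolates the scatter-induced bias from the
  # (scale-dependent) discretization floor shared by all three chains
  le0 <- simulate_phantom_scan(ph, setup, "LE", scatter_mode = "none")
  he0 <- simulate_phantom_scan(ph, setup, "HE", scatter_mode = "none")
  clean <- data_based_pipeline(le0, he0, setup, scatter_handling = "none")
  bg <- roi_circle(c(0, -60), 10)
  wmean <- function(res) {
    roi_stats(synthesize_vmi(res$f_w, res$f_c, 70, mats$water, mats$bone),
              bg)$mean
  }
  ref <- wmean(clean)
  expect_lt(abs(wmean(with_corr) - ref), 0.2 * abs(wmean(without) - ref))
})
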