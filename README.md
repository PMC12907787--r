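# dectsim

A self-contained 2D fan-beam simulation testbench for **projection-data-domain
dual-energy CT (DECT) material decomposition** with object-specific scatter
correction, compared against image-domain decomposition and conventional
calibration-based data-domain decomposition — entirely on analytic digital
phantoms, with no scanner data required.

It is aimed at CT-physics researchers and algorithm developers who want to
study *why* DECT attenuation values (virtual mono-energetic images, VMIs) go
wrong — beam hardening, scatter, bowtie-induced channel dependence,
off-center positioning — under conditions where the entire forward model is
known and every error source can be switched on and off.

## The methods

Every measurement follows the polychromatic Beer–Lambert model

    g_mi = -log{ Σ_E W_mi(E) · exp(-Σ_mat μ_mat(E) · L_mat,i) + s_mi }

with per-channel normalized energy response `W` (Kramers spectrum × aluminum
bowtie × energy-integrating detector), analytic ray–disk path lengths `L`,
and additive scatter `s`. Materials use the photoelectric + Klein–Nishina
two-basis model `μ(E) = a·E⁻³ + b·f_KN(E)`, calibrated per material from a
committed two-point attenuation table.

**Data-domain path (the method under study):** scatter is modeled per scan by
two free parameters (amplitude α, shape β; Gaussian kernel of 5 channels) and
estimated by Nelder–Mead against a vendor-emulation water-corrected
reference; after subtraction, the ray pair `(g_HE, g_LE)` is mapped to water
and calcium lengths by two bivariate quintic polynomials fitted per
bowtie-thickness channel group from the known energy response over a length
grid that includes negative lengths ([-2, 28] cm water, [-4, 5] cm calcium,
0.1 cm steps). Filtered backprojection (fan-to-parallel rebinning, apodized
ramp) of the length sinograms gives basis-density images; a VMI at energy E
is `f_w·μ_w(E) + f_c·μ_c(E)` in HU.

**Image-domain comparator:** effective energies ε_LE/ε_HE are identified
from a two-configuration calibration phantom via the ground-truth ratio
curve `μ_Ca(E)/μ_w(E)`, and the 2×2 basis matrix at those energies is
inverted per pixel.

**Conventional comparator:** cubic (nine terms per material) or constrained
quartic (four terms) polynomials fitted from calibration scans with scatter
left in.

## Worked example

Simulate the ACR-style accreditation module (200 mm water cylinder with
bone/polyethylene/acrylic/air/water inserts), run the full data-domain
pipeline — scatter generated with a deliberately perturbed model (kernel
width 8 + flat floor) and estimated with the σ = 5 model, so the estimator
faces realistic model error — and evaluate the 70 keV VMI:

```r
library(dectsim)
setup <- dect_setup(dect_default_config())

phantom <- make_acr_module_a(offset = c(0, 0))
scan_le <- simulate_phantom_scan(phantom, setup, "LE")
scan_he <- simulate_phantom_scan(phantom, setup, "HE")

res <- data_based_pipeline(scan_le, scan_he, setup)
str(res$diagnostics$LE)
#> List of 4
#>  $ alpha     : num 0.0521
#>  $ beta      : num 0.853
#>  $ iterations: int 46
#>  $ cost      : Named num 1.55e-05

vmi  <- synthesize_vmi(res$f_w, res$f_c, 70)
rois <- acr_roi_specs()
mats <- default_materials()
for (nm in c("bone", "polyethylene", "acrylic", "air", "water_insert")) {
  st <- roi_stats(vmi, rois[[nm]])
  gt <- gt_hu(mats[[sub("_insert", "", nm)]], 70)
  cat(sprintf("%-13s %8.1f HU   (ground truth %8.1f HU)\n", nm, st$mean, gt))
}
#> bone             966.7 HU   (ground truth    985.8 HU)
#> polyethylene     -74.5 HU   (ground truth    -78.5 HU)
#> acrylic          124.6 HU   (ground truth    124.4 HU)
#> air             -982.2 HU   (ground truth   -998.9 HU)
#> water_insert      -1.8 HU   (ground truth      0.0 HU)
ring_mae(vmi, 0, rois$ring)
#> [1] 3.9
```

The few-HU deviations are what remains after the object-specific correction
under model-mismatch scatter; with matched-model scatter (set
`scatter = list(mode = "matched")` and `scatter_handling = "true-params"`)
the same chain reconstructs every insert to within ~1 HU of ground truth and
the air insert to −997.4 HU at 70 keV. `run_accuracy_experiment()`,
`run_scatter_ablation()`, `run_conventional_comparison()` and
`run_position_consistency()` script the full studies (both phantom
positions, scatter-omission ablation, conventional-vs-proposed comparison,
abdomen-surrogate consistency) and write metrics CSV/JSON plus image panels.

A thin command-line wrapper over the same functions ships in
`inst/cli/dectsim.R`:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli/dectsim.R", package="dectsim"))')" \
    experiment accuracy --seed 1 --out-dir runs/accuracy
```

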