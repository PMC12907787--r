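seed: 1
e_ref: 70.0
geometry:
  n_projections: 720
  n_channels: 368
  source_to_detector: 1085.6
  source_radius: 595.0
spectra:
  le_kv: 80.0
  he_kv: 120.0
  inherent_al_cm: 0.25
  bowtie_t0_cm: 0.2
  bowtie_edge_factor: 3.0
  n_groups: 32
scatter:
  mode: mismatch
  alpha_le: 0.05
  beta_le: 0.9421
  alpha_he: 0.06
  beta_he: 0.9554
  sigma: 5.0
  mismatch_sigma: 8.0
  mismatch_constant: 0.01
noise:
  enabled: no
  photons_le: 200000.0
  photons_he: 120000.0
  n_repeats: 1
recon:
  n_pixels: 256
  pixel_size: 1.0
  apodization: cosine
decomp:
  degree: 5
  w_range:
  - -2.0
  - 28.0
  c_range:
  - -4.0
  - 5.0
  step: 0.1
  channel_binding: per-group
vendor:
  diameters_mm:
  - 100.0
  - 150.0
  - 200.0
  - 250.0
  - 300.0
eval:
  energies:
  - 30.0
  - 35.0
  - 40.0
  - 45.0
  - 50.0
  - 55.0
  - 60.0
  - 65.0
  - 70.0
  - 75.0
  - 80.0
  - 85.0
  - 90.0
  - 95.0
  - 100.0
  - 105.0
  - 110.0
  - 115.0
  - 120.0
  - 125.0
  - 130.0
  - 135.0
  - 140.0
phantom:
  offset:
  - 0.0
  - 0.0
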