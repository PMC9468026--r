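# smcoloc

Analysis toolkit for **two-color single-molecule sandwich immunoassays**
read out by TIRF microscopy. In such an assay, fluorophore-labeled capture
antibodies (cAbs, one channel) and detection antibodies (dAbs, the other
channel) are imaged as diffraction-limited spots in stitched two-channel
frames; a true binding event is a dAb spot whose registered coordinates
fall within 1.5 px of a cAb spot. Counting *colocalized* pairs suppresses
the non-specific dAb background, and normalizing by the per-field cAb count
corrects for heterogeneous antibody surface loading — together these make
picomolar protein quantification robust in complex matrices.

The package is aimed at assay developers and microscopists who need the
full computational chain, testable without any raw-data download:

* **Synthetic data** — a two-color TIRF frame generator with known ground
  truth (`sim_config()`, `simulate_fov()`, `simulate_titration()`,
  `simulate_bead_frames()`): Langmuir-occupancy binding, Poisson dye
  labeling, non-specific background, Gaussian PSF, Poisson + read noise,
  and a true inter-channel affine.
* **Spot detection** (`detect_spots()`) — Gaussian denoising (σ = 0.8 px),
  background removal by grayscale morphological reconstruction, `asinh`
  intensity mapping, and regional-maxima selection at
  `median + 1.2 sd`; plus the 75-px field-quality filter (`qc_filter()`).
* **Registration** (`match_beads()`, `estimate_affine()`,
  `average_transforms()`) — mutual nearest-neighbor bead pairing and
  least-squares affine estimation, averaged over bead frames.
* **Colocalization** (`colocalize()`, `normalize_counts()`,
  `aggregate_counts()`) — one-to-one pairing at the 1.5 px criterion,
  cAb-normalized statistics, per-condition CVs.
* **Quantification** (`fit_langmuir()`, `invert_langmuir()`,
  `compute_lod()`, `bootstrap_maple()`) — calibration by the Langmuir
  isotherm

  `signal = B_max · c / (K_d + c)`,

  limit of detection `LOD = ȳ_blank + 3 σ_blank` converted through the
  inverse `c = K_d · y / (B_max − y)` with three-term error propagation,
  and out-of-bag bootstrap quantification error
  `MAPLE = 100%/n · Σ |log c_true − log c_pred| / |log c_true|`.
* **Classification** (`fit_logistic()`, `roc_auc()`,
  `bootstrap_classification()`) — unregularized logistic scoring with
  stratified out-of-bag bootstrap ROC/AUC.
* **False-colocalization model** (`analytic_false_rate()`,
  `calibrate_density()`, `simulate_false_rate()`) — closed form
  `100·(1 − exp(−ρπr²))` per 100 non-specific events and a toroidal
  Monte-Carlo of the same quantity.
* **Pipeline** (`run_pipeline()`, `read_frames()`/`write_frames()` for
  16-bit multi-page TIFF, JSON transforms, YAML/JSON run configs) —
  seed-reproducible end-to-end runs with CSV/JSON outputs and a manifest.

## Worked example

A fully synthetic titration at the standard ladder (0, 10, 100, 300, 1000,
20000 pM; 8 fields of view per concentration at the full 512 × 512
geometry), with registration estimated from simulated bead frames:

```r
library(smcoloc)
res <- run_pipeline(list(
  seed = 1,
  sim = list(concentrations = c(0, 10, 100, 300, 1000, 20000),
             fovs_per_concentration = 8,
             config = list(spot_amplitude = 150, min_separation_px = 4)),
  quantification = list(n_boot = 500)))

res$calibration
#> Langmuir calibration (normalized_coloc): Kd = 399.9 +/- 24 pM, Bmax = 0.6087 +/- 0.01
res$lod
#> LOD: signal 0.004899 -> 3.245 +/- 1 pM
sprintf("MAPLE: %.1f%% +/- %.1f%%", res$maple$maple_mean, res$maple$maple_sd)
#> "MAPLE: 6.4% +/- 1.8%"
```

The generator's truth was `kd = 404` pM with a saturation plateau
(`bmax_fraction`) of 0.65: the fitted `Kd = 399.9 ± 24` pM recovers the
dissociation constant within one standard error, and `Bmax = 0.609`
reflects the plateau times the pair-recovery rate. The LOD says blank
normalized-colocalized counts plus three standard deviations correspond to
3.2 pM, with ±1 pM propagated from the fit and blank uncertainties. MAPLE
estimates that quantifying an unknown field of view from this calibration
mis-states `log` concentration by ~6% on average. Per-concentration CVs of
the normalized colocalized counts (in `res$summary`) drop from ~0.48 at
10 pM to ~0.07 at saturation.

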