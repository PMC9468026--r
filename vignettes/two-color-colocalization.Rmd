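---
title: "Methods: two-color single-molecule colocalization immunoassay analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: two-color single-molecule colocalization immunoassay analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The assay and the statistical problem

A sandwich immunoassay read out at the single-molecule level images two
spectrally distinct fluorophores by TIRF microscopy: capture antibodies
(cAbs) tethered to the coverslip in one channel, detection antibodies (dAbs)
in the other. Every field of view (FOV) is a stitched 16-bit frame, capture
channel in the left half and detection channel in the right half. A true
binding event is a sandwich: a dAb spot whose registered position falls
within 1.5 px of a cAb spot. Two nuisance processes dominate raw counts:
dAbs adsorbed non-specifically to the surface, and FOV-to-FOV heterogeneity
of the cAb surface loading. Colocalization filters the first; dividing
counts by the per-FOV cAb count (`normalized_coloc = coloc / cab`) corrects
the second. Everything downstream — Langmuir calibration, limit of
detection (LOD), bootstrap quantification error, ROC/AUC classification —
operates on these per-FOV counts.

All coordinates are continuous, 0-based, `x` = column and `y` = row, origin
at the center of the top-left pixel, and spot positions are always reported
in the half-image frame of their channel.

## Synthetic data as the testbed

No public raw-image accession accompanies the assay, so the package ships a
generator (`sim_config()`, `simulate_fov()`, `simulate_titration()`,
`simulate_bead_frames()`) whose defaults are fixed once and define the
conditions every test runs under:

* geometry 512 x 512 px stitched (each channel 256 x 512 px = 25.6 x 51.2 µm
  at 100 nm/px), isotropic Gaussian PSF with sigma 1.2 px;
* 150–300 cAbs per FOV, uniformly placed;
* occupancy: each cAb is bound with probability
  `bmax_fraction * c / (kd + c)` with `kd = 404` pM and
  `bmax_fraction = 0.65` — the saturation plateau below 1 stands in for
  incompletely active or incompletely labeled antibody;
* 40 non-specific dAbs per FOV in expectation (Poisson, uniform positions);
* degree of labeling (DOL): dyes per antibody ~ Poisson(4), within the
  characterized 3–5 range; a zero-dye antibody is invisible, which the
  ground-truth tables make explicit via per-spot dye counts;
* camera: peak signal 60 counts per dye, background 100 counts, Poisson shot
  noise on signal plus background, Gaussian read noise sd 2 counts,
  quantized to 16 bits. EM-gain excess noise is not modeled;
* misregistration: a near-identity affine (0.1° rotation, 0.1% scale,
  (1.5, −1.0) px shift) maps detection coordinates to the capture frame;
* binding jitter: a bound dAb sits at its cAb position plus a displacement
  whose *radial* standard deviation is `jitter_sd_px = 0.5` px (per-axis
  sd `0.5/sqrt(2)`). The radial reading is deliberate: it keeps a true pair
  within the 1.5 px criterion with probability 0.9999, whereas a per-axis
  reading of 0.5 px would only reach 0.989.

What the generator does **not** emulate: photobleaching and blinking, FRET
between the channels, fluid-exchange kinetics, clustered or hard-core cAb
placement beyond an optional minimum-separation option, EMCCD excess noise,
and optical aberrations beyond a global affine. Tests passing on this
generator therefore demonstrate the correctness of the *computations*, not
performance on real microscope data.

Determinism: every simulation accepts an integer seed and identical seeds
give bit-identical frames and ground truth; per-FOV seeds inside
`simulate_titration()` are derived arithmetically from the dataset seed and
stay below 2^31.

## Spot detection

`detect_spots()` processes one half-image at a time (so the two channels
never share statistics) in four printed-protocol stages:

1. **Denoise** — Gaussian filter, kernel sd 0.8 px, separable implementation
   with half-sample reflection at borders (constants pass through exactly).
2. **Background subtraction** — grayscale morphological reconstruction by
   dilation under the smoothed image. The default seed is the image minimum
   everywhere except at the (reflection-padded) border: the reconstruction
   rises to whatever level is reachable from the border without descending,
   which removes smooth illumination gradients *exactly* while
   diffraction-limited peaks — unreachable without a dip — keep their full
   prominence. The classical h-dome seeding (`method = "hdome"`,
   seed `smoothed − h`) is also provided; it was not adopted as the default
   because it caps every peak's dome at `h`, while camera-noise maxima keep
   their full relief (up to ~4.5 noise sd), which destroys the separation
   that the intensity threshold relies on. The 8 px reflection padding
   exists so spots touching the physical border are not flooded away; its
   only requirement is to exceed the spot radius.
3. **Intensity mapping** — `asinh(v / s)`, strictly monotone, with
   `s = 4 sd(v)` (floored at one count). The large scale keeps the mapping
   close to linear through the bulk of the intensities and compresses only
   the extreme tail; a small scale (e.g. a MAD-based one) makes the
   transform logarithmic, which shrinks the gap between spot maxima and
   noise maxima faster than it shrinks the noise spread and measurably
   harms exact counting.
4. **Selection** — 8-connected regional maxima (connected equal-valued
   plateaus count once, at their centroid; border maxima are eligible),
   kept when their transformed intensity is at least
   `median + 1.2 sd`. The statistics are computed over the *maxima
   intensity population* of the transformed half-image rather than over all
   pixels. This choice is load-bearing: pixel statistics put the cut at
   ~1.2 noise sd, far below the extreme-value tail of noise maxima, and
   admit hundreds of false detections per half-frame at any setting of the
   other parameters we tried; the maxima population is bimodal (noise
   relief versus spot prominence), so the same printed `median + 1.2 sd`
   rule lands in the gap and adapts to exposure.

Known limitation: with very few true spots (fewer than roughly 15 per
half-image) the maxima population is dominated by noise and the adaptive
threshold under-cuts; sparse detection-channel frames at low analyte
concentration therefore over-count. The per-FOV statistics stay usable
because the noise floor is common to all conditions, but absolute counts
from very sparse frames should be treated with care (or re-run with an
explicit `scale`/`threshold_multiplier`).

The quality filter (`qc_filter()`) discards a FOV when the mean `y` of its
capture spots is more than 75 px from the vertical middle — the signature
of bubbles or dust crowding spots to one side. On clean simulated FOVs the
suite checks that nothing is discarded (the real-data expectation is below
1%).

## Channel registration

Fiducial beads visible in both channels give per-frame correspondences:
`match_beads()` uses *mutual* nearest neighbors (exact all-pairs search —
a KD-tree would only accelerate it, and its leaf size cannot change the
result) with a 5 px gate, preventing many-to-one pairs that one-directional
matching allows. `estimate_affine()` solves the homogeneous least-squares
problem `dst ≈ T src` — identical to the closed-form matrix-inverse
solution at exactly three non-collinear pairs, and its natural
generalization beyond. Per-frame transforms are combined by `average_transforms()`
as the element-wise matrix mean, which is the convention for pooling
near-identity transforms; no per-frame outlier rejection is applied.
Collinear or under-determined geometries raise errors rather than
returning garbage.

One interpretation note: with 0.2 px bead jitter the *mapped-point* error
at the field center is the meaningful registration error (about 0.015 px
with 5 frames x 50 beads). The raw translation column of the matrix is the
mapped *origin*, which sits far outside the bead cloud's centroid and
amplifies rotation/scale noise by the lever arm; the acceptance suite
asserts the center-point error.

## Colocalization and normalization

`colocalize()` maps detection spots through the registration transform and
pairs them with capture spots one-to-one: candidate pairs within the radius
(default 1.5 px) are sorted by distance (ties broken by capture then
detection index, for determinism) and accepted greedily when both members
are free. One-to-one matching enforces `coloc ≤ min(cab, dab)` — one
sandwich per capture antibody — and the suite checks it against an
independent brute-force enumeration. `normalize_counts()` adds
`coloc/cab` and `dab/cab`; FOVs with zero capture spots are flagged invalid
and excluded from aggregation instead of raising. `aggregate_counts()`
reports mean, sample standard deviation (n−1) and CV per statistic and
group.

## Calibration, LOD, and quantification error

`fit_langmuir()` fits `signal = bmax * c / (kd + c)` by unweighted
nonlinear least squares (Levenberg–Marquardt; start `kd = median(c)`,
`bmax = max(signal)`; both parameters bounded positive), with standard
errors from the Jacobian-based covariance. The inverse used everywhere is

```
c = kd * y / (bmax - y)
```

The printed form of the inverse in the source protocol,
`(counts − Kd)/(Bmax − counts)`, is dimensionally and algebraically
inconsistent with the isotherm, while the error-propagation partial
derivatives printed alongside it are exactly those of `kd*y/(bmax − y)`;
the package therefore implements the latter and treats the former as a
typographical slip. Signals at or above `bmax` invert to `Inf` with a
warning; negative signals clamp to zero concentration with a warning.

`compute_lod()` is definitional: `lod_signal = mean(blanks) + 3 sd(blanks)`,
converted to concentration through the inverse, with uncertainty from the
three-term quadrature propagation (covariance cross-terms dropped, matching
the printed form):

```
sigma_lod^2 = (kd*y/(bmax-y)^2 * sigma_bmax)^2
            + (y/(bmax-y)     * sigma_kd  )^2
            + (kd*bmax/(bmax-y)^2 * sigma_y)^2
```

The suite verifies this against a 1e5-draw Monte-Carlo propagation in the
small-sigma regime (agreement within 10%).

`bootstrap_maple()` estimates quantification error out-of-bag: resample the
FOVs with replacement, fit, invert the fit for the FOVs never drawn, and
score

```
MAPLE = 100%/n * sum |log(true) - log(pred)| / |log(true)|
```

MAPLE is invariant to the logarithm base (the suite checks this
numerically) but not to concentration units; the package fixes pM so
`log(true) > 0` over the pM–nM working range. Zero-concentration FOVs take
part in resampling and fitting but are excluded from the score (their log
is undefined). When an out-of-bag signal is zero the predicted
concentration is zero and the log guard makes the contribution very large:
MAPLE is only meaningful when per-FOV counts at the lowest concentrations
are mostly nonzero (full-geometry FOVs; at quarter-size test geometry the
statistic inflates, which is the statistic being honest about an assay
floor, not a bug). Bootstrap iterations whose resample cannot support a
fit (empty out-of-bag set, all-zero signals, fewer than three distinct
non-zero concentrations, or a failed fit) are redrawn and counted.

## Classification

`fit_logistic()` is the unregularized single-feature logistic MLE (IRLS via
`glm`; the printed loss with labels in {0,1} is read as the standard logit
loss over labels mapped to {−1,+1} — the printed expression is not a proper
loss function). Perfect separation is reported with a warning; scores still
rank, so ROC/AUC remain valid. `roc_auc()` thresholds at every distinct
score with ties grouped and integrates by trapezoid; for a monotone model
this equals the Mann–Whitney rank statistic, which the suite checks by
exhaustive pairwise comparison and against an independent ROC
implementation. `bootstrap_classification()` resamples each class with
replacement (stratified, so training always holds both classes), tests
out-of-bag, and summarizes the AUC sample distribution by median and
quartiles. FOVs are pooled across coverslips before resampling.

## False-colocalization model

A non-specific dAb landing within the cutoff `r` of at least one cAb is a
false positive. With cAbs as a uniform Poisson process at density `rho`,
the analytic rate per 100 events is `100 (1 − exp(−rho π r²))` — quadratic
in `r` at low coverage, which is what drives the printed progression
4.5 → ~1 → ~0 per 100 as the cutoff shrinks 200 → 100 → 10 nm. Because the
physical surface density behind the printed operating point is not stated,
`calibrate_density()` anchors it: solve for `rho` such that 200 nm gives
4.5 per 100 (0.3664 µm⁻²). `simulate_false_rate()` redoes the experiment by
Monte-Carlo on a 50 x 50 µm *toroidal* plane — wrap-around distance removes
edge bias so the estimate converges to the infinite-plane closed form —
with the cAb count drawn Poisson at the calibrated density and ≥1e6 uniform
dAb draws. `scripts/acceptance.R` reports the two non-anchor operating
points (100 nm and 10 nm), rounded to the nearest integer as the protocol
prints them.

## Pipeline and problem sizes

`run_pipeline()` composes the stages end-to-end on simulated data
(registration from detected bead spots, detection, QC, colocalization,
normalization, per-concentration aggregation, calibration, LOD, bootstrap
MAPLE), writes CSV/JSON outputs plus a manifest when `out_dir` is set, and
is byte-reproducible given a seed. A single-color arm
(`colocalization$enabled = FALSE`, `signal_kind = "absolute"`) mirrors the
comparison analyses.

The test suite runs the image-level checks on quarter-size 256 x 256
frames with 40–60 spots and `spot_amplitude = 150` (every visible spot at
peak SNR ≥ 10 over the shot-noise floor) — the detection-exactness
property (≥ 99% of FOVs counted exactly, sub-pixel median localization) is
checked over 200 such FOVs; calibration recovery uses the printed ladder
(10 pM–20 nM, 16 FOVs per concentration, truth kd = 404 pM, bmax = 645)
with homoscedastic noise of sd 5% of `bmax` over 100 replicates — the
homoscedastic reading matches the unweighted least-squares error model, so
the reported standard errors are calibrated; with multiplicative 5% noise
the same fit is heteroscedastic and 2-sigma coverage drops to ~76%, a
property of unweighted fitting rather than of this implementation.
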