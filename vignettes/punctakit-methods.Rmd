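---
title: "Quantifying biomolecular condensates with punctakit: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying biomolecular condensates with punctakit: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(punctakit)
```

## The scientific problem

Many proteins and RNAs demix inside cells by liquid-liquid phase separation
(LLPS), forming membrane-less condensates. Under a fluorescence microscope
a labeled condensate-forming biomolecule appears as bright foci — *puncta*
— against the dimmer *light phase* that surrounds them. The physics of the
underlying interactions is summarized by a small set of per-cell
quantities:

* the **dense phase** DP and **light phase** LP — mean labeled-biomolecule
  signal (or concentration, after calibration) inside and outside puncta
  within one region of interest (ROI; a nucleus or a cell);
* the **partition coefficient** \(K_p = \mathrm{[DP]}/\mathrm{[LP]}\);
* the **Gibbs free energy of transfer**
  \(\Delta G_{Tr} = -RT\,\ln K_p\), with
  \(R = 1.9872\times10^{-3}\ \mathrm{kcal\,mol^{-1}\,K^{-1}}\), so
  \(\Delta G_{Tr}\) is in kcal/mol and is negative when partitioning into
  puncta is favorable;
* the **volume fraction** \(F_{vol}\) (total puncta volume over ROI
  volume) and **mole fraction** \(F_{mol}\) (integrated intensity inside
  puncta over the integrated ROI intensity).

punctakit computes these from 3D multi-channel z-stacks, end to end: data
staging, ROI segmentation, puncta detection and segmentation, feature
measurement, thermodynamic derivation, and mixed-effects comparison of
conditions. A synthetic-stack generator with exact ground truth makes
every stage testable without microscopy data.

## Image model and containers

A `multichannel_stack` holds intensities indexed `(z, y, x, channel)` with
physical voxel spacing (defaults throughout emulate a high-resolution
confocal acquisition: 0.11 µm xy pixels, 0.2 µm z steps). 2D images are
z-extent-1 stacks so that one code path serves both; "volumes" are then
areas. Segmentations are `label_volume` objects: integer arrays where 0 is
background and each positive label is one ROI or punctum, aligned to the
stack. Measurement tables are tibbles whose column names follow the
standard per-ROI and per-punctum schemas (expanded per channel), so they
are drop-in inputs for downstream scripts.

TIFF output is plain multipage TIFF (channel-first page order) readable in
FIJI; mask channels carry the label IDs so images can be cross-referenced
with the tables. Because baseline TIFF has no z-spacing or channel-name
tags and the R TIFF bindings expose no free-text description tag, the
physical metadata travels in a JSON sidecar next to each file. Integer
data up to 65535 are stored losslessly as 16-bit; anything else falls back
to 32-bit float.

## ROI segmentation

ROI segmentation is backend-pluggable: any function that maps a channel
volume to per-layer 2D labels (or a 3D label array) can stand in, so a
deep-learning segmenter can be wired in without touching the rest of the
pipeline. The built-in classical backend — Gaussian smoothing (default
0.25 µm), a single global Otsu threshold, connected components — needs no
model weights and is what the test-suite exercises. A global threshold is
deliberate: per-layer thresholds hallucinate objects in layers that
contain only noise.

Post-processing implements the two steps that matter regardless of
backend:

* **2D→3D merging** (`merge_layers_3d`): objects in adjacent z-layers are
  linked into one 3D ROI when their xy overlap, measured as intersection
  over the *smaller* object's area, reaches 0.5. Linking is transitive
  along chains of adjacent layers and never bridges a z gap. The overlap
  criterion is the package's choice; the source protocol states only that
  per-layer ROIs "are combined in three dimensions".
* **small-ROI removal** (`remove_small_rois`): in 3D mode an ROI is
  dropped when its voxel count is below the volume of a sphere of diameter
  `remove_small_diam_fraction × diameter` (π d³/6); in 2D mode the
  criterion is the maximal single-layer area against the matching disk.
  The volume criterion intentionally also removes ROIs that barely
  protrude into the field of view. ROIs touching the xy border are kept by
  default, with `drop_edge_rois()` as the opt-in exclusion.

## Puncta detection

Candidate centers come from a multiscale Laplacian-of-Gaussian (LoG)
detector. A target blob size \(s\) (µm) maps to per-axis Gaussian sigmas
\(\sigma_{axis} = (s/\mathrm{spacing}_{axis})/(2\sqrt{D})\) voxels (D =
number of spatial dimensions), the scale at which the scale-normalized
response of a ball of diameter \(s\) is maximal; anisotropic voxels are
handled by the per-axis division. `num_sigma` scales are linearly spaced
between `minsize_um` and `maxsize_um`. The response is the negated,
per-axis scale-normalized Laplacian of the smoothed volume, so bright
blobs are positive peaks and a constant image maps to zero.

Two conventions matter and are worth stating explicitly:

* **Intensity normalization.** Volumes are rescaled to unit maximum before
  the transform, so `threshold_detection` and the LoG-space segmentation
  thresholds are dimensionless and independent of camera bit depth. The
  recommended starting value (0.001) is a low floor; on noisy data the
  practical operating point is found by the calibration procedure below.
* **Scale-space maxima.** A center must be a 26-neighborhood spatial
  maximum at its own scale *and* dominate the 3×3×3-dilated responses of
  the adjacent scales — the standard 4D maxima rule. Without the dilation,
  small-scale edge maxima inside large blobs survive and duplicate
  centers.

Of two blobs (spheres of radius \(\sigma\sqrt{D}\) in physical units)
whose overlap fraction — lens volume over the smaller sphere — reaches
`overlap`, the smaller is removed; the default 1 removes only completely
overlapping blobs.

Centers are then filtered by contrast to the ROI background: keep a center
only if its raw intensity is at least `threshold_background` times the
applicable background. The background of an ROI is the
`background_percentile` (default 50, the median) of its voxel intensities;
with `global_background = TRUE` a single value — the
`global_background_percentile` (default 95) of the per-ROI values — is
applied everywhere, which desensitizes dim cells and is the right choice
only when expression is uniform. Centers outside every ROI are tested
against the global value, which is always available once ROIs exist;
`threshold_background = 0` disables the filter.

## Puncta segmentation

Foreground selection is mode-dependent:

* **mode 0** — LoG response above the absolute `threshold_segmentation`;
* **mode 1** — LoG response above `threshold_segmentation` times the ROI's
  background *in LoG space*; that background is the
  `background_percentile` of the absolute max-over-scales response inside
  the ROI. Computing it on the same response surface that is thresholded
  keeps the multiplicative threshold coherent (the protocol does not pin
  down the LoG-space statistic); the threshold scale therefore differs
  from tools that normalize differently.
* **mode 2** — raw intensity above `threshold_segmentation` times the
  ROI's raw background.

Modes 1–2 require ROI masks; under a per-ROI background, voxels outside
all ROIs take the global value. Foreground is partitioned among the
surviving centers by a seeded 3D watershed (priority flood, 26-connected)
on the negated response (modes 0–1) or negated intensity (mode 2).
Foreground components containing no seed are discarded, which can remove
further puncta beyond the center filters. Two refinements keep segmented
volumes faithful to blob size:

* **per-scale flooding** (LoG modes): each punctum is thresholded and
  flooded on the response at its *own detected scale*, smaller scales
  first; the max-over-scales response would carry a support roughly six
  times a blob's volume.
* **blob-boundary ceiling** (`blob_boundary_fraction`, default 0.25): a
  blob's flood stops at the isoline at 0.25 of its own peak response. For
  a solid sphere probed at the matching scale the boundary sits at about a
  quarter of the central response (computed from the noise-free radial
  profile on a fine grid), while the positive LoG core extends well past
  the boundary; without the ceiling, volumes inflate ~2.5-fold. Setting
  the fraction to 0 restores a plain flood. Real condensates are not
  perfect spheres, so this constant is a model-based default, not a fitted
  quantity.

`filter_puncta` optionally removes puncta whose equivalent-sphere radius
exceeds `maxrad_um` and/or trims punctum voxels outside every ROI.

## Measurements

`measure_puncta` emits one row per punctum and channel: intensity-weighted
center of mass (0-based voxel coordinates, x fastest), volume in pixels
and µm³, enclosing ROI (by center of mass — deterministic even for
straddling puncta; 0 means background, and then the border distance is 0),
anisotropy-aware distance to the ROI border, per-channel mean/integrated
intensities, and pairwise Pearson (two-sided p from the t statistic on
n − 2 df) plus mutual information across channels. `measure_rois` emits
the per-ROI row: geometry, per-channel intensity statistics inside the ROI
and in the image background, intensity entropy, channel-pair correlation
statistics, per-puncta-channel aggregates, the dense/light-phase means and
integrated intensities (inside/outside that channel's puncta, within the
ROI — so inside + outside equals the ROI total exactly), and pairwise
puncta-mask overlap coefficients (intersection over union). Entropy and
mutual information use base-2 logarithms over 256 equal-width bins
spanning each variable's observed range; the bin count is a recorded
parameter since no estimator is canonical. Undefined statistics (an ROI
fully covered by puncta, zero-variance correlations) are missing values,
never zeros, and CSVs serialize them as empty cells.

## Thermodynamics

`fit_calibration` fits intensity = slope × concentration + intercept by
ordinary least squares on images of known fluorophore dilutions and
returns `factor_conc = 1/slope` (µM per intensity unit), warning when
r² < 0.99 since the conversion is only meaningful in the linear regime.
`compute_thermodynamics` then derives, per ROI, DP and LP (optionally in
µM), \(K_p\), \(\Delta G_{Tr}\), \(F_{vol}\) = total puncta volume / ROI
volume (bounded by 1; the package uses the whole-ROI denominator rather
than the puncta-free remainder — the two are interconvertible), and
\(F_{mol}\). \(K_p\) and \(\Delta G_{Tr}\) are invariant to the
calibration factor, which cancels in the ratio. Temperature is a required
input (Kelvin) with no default. ROIs without puncta yield missing values.

## Condition comparison

`compare_conditions` fits a random-intercept model with the biological
condition as fixed effect and the image position (technical replicate) as
random effect: `lmer` for continuous outcomes (after an optional log
transform), `glmer` with Poisson family and log link for counts
(auto-detected, overridable via `y_count`). The design assumes one
biological replicate per condition with positions as technical replicates.
Pairwise contrasts use Wald statistics from the fixed-effects covariance;
the reference distribution is a t with between-cluster degrees of freedom
(positions minus conditions) for the linear model — plain normal quantiles
are anti-conservative with tens of positions — and the asymptotic normal
for the Poisson model (Laplace approximation, recorded in the result).
With a single observation per position the random intercept is confounded
with the residual and the fit falls back to the fixed-effects model, which
it must match in that limit. The first included condition is the reference
level; `tidy()` and `glance()` give tabular access and the result prints a
plain-text narrative.

## The synthetic-data generator

`simulate_stack` builds a noiseless intensity model first: random
ellipsoidal nuclei (axis ratio ≤ ~1.35, so the 2D→3D merging path is
genuinely exercised) with per-nucleus expression drawn from
`expression_range`; spherical puncta of radius `puncta_radius_um` placed
uniformly inside each nucleus with a margin of the punctum radius plus
max(3 × `psf_sigma_um`, 0.25 µm), so every planted sphere and its blurred
support lies fully inside the nucleus and the sphere-volume ground truth
is exact; puncta voxels carry `partition_ratio × LP`. The model is blurred
by an isotropic Gaussian PSF approximation (default σ 0.08 µm), corrupted
by scaled-Poisson photon noise (`observed = g·Poisson(signal/g)`, default
gain 5) plus Gaussian read noise (sd 2), and rounded to non-negative
integer camera counts. Defaults give a peak-signal SNR of ≈ 10
(\(\mathrm{SNR} = \sqrt{\mathrm{peak}/g}\)). All truth quantities
(per-nucleus DP, LP, \(K_p\), \(F_{vol}\), \(F_{mol}\); per-punctum
centers and radii) are computed from the noiseless model, never
re-measured from the noisy image; one master seed drawn through a single
generator makes output bit-reproducible.

What the generator does *not* emulate — and therefore what passing tests
do not demonstrate about real data: non-uniform nucleoplasm texture,
chromatin exclusion, a realistic (anisotropic, diffraction-shaped) PSF,
bleaching, aberrant cells, and puncta touching the nuclear envelope.

## Worked protocol example: recovering planted partition ratios

The package's own validation study mirrors how a scientist would tune the
pipeline on a new acquisition:

1. **Conditions.** Stacks of 32 × 160 × 160 voxels (0.2/0.11 µm spacing),
   2 nuclei, 6 puncta each of radius 0.4–0.6 µm, planted ratios
   ρ ∈ {2, 5, 10}. The generator's noise specification is a *peak* SNR of
   ≈ 10, so expression scales as 500/ρ counts across ratios.
2. **Calibration of analysis parameters** (once, per the protocol's
   setup-and-inspect step): the target size range is set to the known
   puncta size (`minsize_um = 0.6`, `maxsize_um = 1.5`);
   `threshold_detection = 0.12` and mode-0
   `threshold_segmentation = 0.15` sit above the LoG noise floor measured
   on matched negative-control simulations (noise maxima reach ≈ 0.1 on
   the unit-max scale at ρ = 2); `threshold_background = 1.5` stays below
   the weakest planted contrast (ρ = 2).
3. **Result.** Median recovered \(K_p\) over 10 seeds falls within 20% of
   each planted ratio (the acceptance suite asserts exactly this; typical
   errors are ≈ 4% at ρ = 2, ≈ 10% at ρ = 5, ≈ 17% at ρ = 10 — residual
   bias comes from partial-volume dilution at blob edges, which grows with
   contrast).

At the pipeline's defaults (ρ = 5, full-size 128 × 256 × 256 stacks) the
detector achieves recall and precision 1.0 with sub-voxel center error,
and median per-punctum volume within ~5% of the planted spheres.

Problem sizes in the test-suite (tiny 24 × 96 × 96 fixtures for unit
tests; one full-size stack, 10 seeds per ratio for recovery; a
1000-replicate null simulation for the type-I check) are the package's
chosen validation design.

## Numerical choices and degenerate inputs

* Watershed floods ascending height with FIFO tie-breaking, so results are
  order-independent and reproducible; labels follow seed order.
* Otsu's threshold uses a 256-bin histogram; blank volumes yield empty
  segmentations rather than thresholded noise.
* Percentiles use R's default (type 7, linear interpolation): the 95th
  percentile of two ROI backgrounds {10, 100} is 95.5.
* Mirror boundary conditions for Gaussian smoothing; replicate-edge second
  differences for the Laplacian.
* Empty center sets, blank channels, ROIs without puncta and
  fully-covered ROIs are all defined outcomes (empty masks or missing
  values), not errors; genuinely infeasible requests (nuclei that cannot
  pack into the image) fail loudly.

## Known limitations

* The classical ROI backend assumes blob-like, well-separated objects on a
  dark background; touching nuclei are not split (a deep-learning backend
  plugged into `segment_rois` is the intended remedy on real data).
* The blob-boundary ceiling assumes roughly spherical puncta; strongly
  aspherical condensates will be under-segmented at their extremities.
* Mode-1 thresholds are tied to this package's LoG normalization and are
  not numerically interchangeable with other implementations.
* \(F_{mol}\) uses fluorescence as a proxy for molecule counts, inheriting
  every caveat of the intensity-to-concentration calibration (pH,
  crowding, saturation).
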