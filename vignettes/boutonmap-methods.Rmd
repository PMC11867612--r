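---
title: "Bouton quantification: model, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bouton quantification: model, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(boutonmap)
```

## What is being measured

Purkinje-cell (PC) axon terminals in brainstem sections appear as ~1 µm
fluorescent puncta. Two channels are acquired per field: a vGAT immunolabel
marking every GABAergic presynaptic bouton, and a synaptophysin-tdTomato
reporter expressed only in PCs. The pipeline answers three quantitative
questions per anatomical region: how many GABAergic boutons, what fraction
are PC boutons, and what is the areal PC-bouton density — plus, downstream,
whether the probability of evoking a PC-IPSC in a recorded neuron rises
with the local PC-bouton density.

Stacks are thin (five 0.3 µm z-steps = 1.5 µm at 0.3611 µm XY pixels), so
all densities are *areal* (boutons/µm² of section plane); the stack is
treated as one optical section. All geometry is handled in physical µm, so
the 0.83:1 z:xy voxel anisotropy is respected everywhere distances matter.

## The measurement chain and its parameters

| Parameter | Default | Role |
|---|---|---|
| `background_diameter_um` | 50 | FWHM of the Gaussian background estimate |
| `threshold_k` | 1 | threshold = ROI median + k·SD |
| `roi_side_px` | 50 | side of the three reference squares |
| `bouton_diameter_um` | 1.0 | seed separation and matched-filter scale |
| `bouton_smooth_sigma_um` | 0.25 | matched-filter σ (= diameter/4) |
| `match_radius_um` | 0.7 | colocalization center-to-center radius |
| `tdt_min_separation_um` | 0.5 | reporter regional-maximum separation |
| `bin_size_um` | (144, 144, 4) | density-map voxel |
| `qc_grid_spacing_um` | 350 | registration-QC reference grid |

**Background.** The 50 µm "diameter" is interpreted as the kernel FWHM
(σ = diameter / 2√(2 ln 2)); imaging software conventionally parameterizes
Gaussian backgrounds by a width of this order, and the choice is exposed as
configuration. Filtering is 2D per plane — a 50 µm kernel has no meaning
across a 1.5 µm stack. Edge pixels use renormalized kernels, so the
operator is linear and preserves constants exactly (both are tested).

**Threshold.** The per-image threshold is the pooled median + k·SD (sample
SD, n−1) over square reference ROIs. The source procedure chose ROIs "of
various densities" by hand; the unattended default spreads three 50-px
squares along the horizontal midline so laterally varying fields contribute
ROIs of different punctum content. k is configurable because the original
thresholds were manually adjusted per image and only approximately one SD
above the median.

**Punctum isolation.** The watershed is *provided with* a 1 µm bouton
diameter; whether that acts as a seed-distance constraint or a smoothing
scale is not recoverable, so both interpretations are implemented and on by
default: candidate seeds are local maxima of the matched-filtered
(σ = diameter/4) corrected channel, greedily thinned so surviving seeds are
≥ 1 µm apart in physical distance (ties broken by lowest z, y, x index for
determinism), then a marker-based Meyer watershed on the inverted intensity
floods the suprathreshold mask. Setting `bouton_smooth_sigma_um = 0`
recovers the pure seed-distance reading. The matched filter matters in
practice: without it, `median + 1·SD` sits low enough that, over ~1.3
million voxels, shot-noise excursions seed spurious two-voxel objects
whenever the reference ROIs happen to catch few puncta.

Object centroids are weighted by intensity *above the isolation threshold*.
Weighting by raw intensity lets the broad suprathreshold skirt shared with
neighbours drag centroids by over a µm, which silently breaks the 0.7 µm
colocalization radius; excess-intensity weighting localizes to ~0.2 µm
(about half a pixel) on rendered test spots.

**Colocalization and classification.** Every local maximum of the lightly
smoothed (σ = 0.25 µm) reporter channel is a candidate — no intensity
cutoff, because separating signal from noise is the job of the next step.
Each bouton takes the intensity of the nearest maximum within 0.7 µm
(strictly ≤); unmatched boutons fall back to the maximum reporter value
inside their own voxel mask and *stay in the pooled histogram*. That
choice is deliberate: the classification threshold is the valley of a
bimodal distribution, and the noise mode must be populated for a valley to
exist. The valley is located on a kernel-density estimate (Gaussian kernel,
Silverman bandwidth) between the two highest modes; raw-histogram bin
minima are noisy and the KDE agrees with them in the well-separated limit.
If the KDE is unimodal the code falls back to Otsu's threshold and flags
the report — a unimodal histogram means either no reporter-positive boutons
or a miscalibrated channel, and silent continuation would be worse.
Classification requires both the spatial match and intensity strictly above
the valley; at least 50 pooled intensities are required, with an error
advising pooling across sections below that.

**Registration and QC.** Sections are registered to a 2D label-map atlas by
least squares on landmark pairs; the default similarity model (rotation +
isotropic scale + translation, closed-form SVD solution) matches what
manual contour alignment can express, with affine optional. The quality
metric is the displacement |T(p) − p| of a regular 350 µm grid across the
atlas bounds (about 50–70 points on a section-sized field), reported as
mean ± sample SD. The grid is anchored at the bounds origin to make the
metric deterministic. Note the metric conflates true warp with residual
alignment error — it is reported exactly as defined, and interpretation is
left to the user. Fit residuals are reported as per-coordinate RMS.

**Density maps and summaries.** PC boutons are binned into half-open
144 × 144 × 4 µm³ voxels anchored at the atlas origin (a point exactly on
an edge belongs to the higher bin); grids from several sections are
averaged as a plain per-bin mean of counts. Region summaries use the
imaged-field region area as the density denominator (the alternative —
full atlas region area — is not computable from a single field of view).
Boutons mapping outside every region are reported under background id 0,
never dropped, so region counts always partition the table.

**Ephys linkage.** `responded` is an input column: detecting an evoked
IPSC from raw traces has no stated numeric criterion and is out of scope.
Nonresponders contribute 0 pA to the all-cell mean amplitude, which makes
the identity `mean_all = fraction × mean_responders` exact and is the only
convention under which a statement like "average of all cells 1.4 pA with
2/40 responders" is coherent. The probability-vs-density curve uses Wilson
95% intervals (well-behaved at 0/n and n/n) over quantile bins (5 by
default; the original bin edges are unstated). The responding/nonresponding
density comparison defaults to the Mann–Whitney test with tie-corrected
normal approximation — no test is named in the source — with an exact
enumeration/permutation route available and the method recorded in the
result.

## The synthetic world

`scene_config()` states the world the tests assume; its defaults are fixed
once and not tuned per test:

* 512 × 512 × 5 voxels at (0.3611, 0.3611, 0.3) µm — the stated acquisition
  geometry (~185 × 185 × 1.5 µm).
* Three rectangular regions with (vGAT density, PC fraction) = (0.02, 0.7),
  (0.01, 0.25), (0.002, 0.05) — the dense / intermediate / sparse regimes
  spanning the reported per-region range (~0.001–0.05 boutons/µm²,
  fractions 0–0.85).
* Boutons are anisotropic Gaussian spots of FWHM 1.0 µm rendered in
  physical µm on the voxel lattice (no optical PSF model); per-bouton peak
  amplitudes are log-normal.
* Reporter intensities are bimodal by construction: PC boutons draw peaks
  from log-normal(median 100 a.u., σlog 0.35), non-PC boutons from
  log-normal(median 10 a.u., σlog 0.4) — separated modes whose overlap at
  the geometric-mean cut is < 2%. Dim axon clutter (0.005/µm², noise-mode
  amplitudes) adds spurious reporter maxima.
* Channel 0 rides on a smooth illumination field (bilinear interpolation of
  a coarse Gaussian lattice, 50 µm correlation length, mean 30 a.u.).
* Camera model: Poisson on (signal/gain) times gain, then Gaussian read
  noise, clipped at 0. Defaults gain 0.5, read SD 1.5 a.u.

No intensity statistics for reporter-negative boutons are reported in the
source, so the noise/signal amplitudes above are chosen for testability: a
punctum-to-background peak contrast of ~10:1, typical of antibody-labeled
confocal material, and shot-noise-limited detection. What a green recovery
test establishes is therefore that the *procedure* is correctly implemented
and stable under realistic Poisson statistics, region geometry and
anisotropy — not that it would meet the same tolerances on tissue with
autofluorescence, spectral bleed-through, or out-of-focus structure, none
of which are modeled. Ground-truth region membership is the region at the
true centroid; boutons may straddle borders.

The ephys generator places cells uniformly over the grid and links response
probability to the local density through a logistic model
(`plogis(beta0 + beta1·d)`); responder amplitudes are log-normal with
median 50 pA (the scale of small evoked PC-IPSCs), σlog 0.8.

## Numerical choices and degenerate inputs

* Local maxima require ≥ all 26 neighbours and > at least one, so constant
  plateaus (including all-zero images) yield no peaks; plateau rims are
  merged by the separation rule.
* Greedy suppression and the watershed both break ties deterministically
  (intensity order, then lowest z, y, x; FIFO in the flooding queue), so
  identical inputs give bit-identical outputs.
* `subtract_background` clips at 0; corrected images are always within
  [0, original].
* Half-open binning is guarded against floating-point edge jitter with a
  1e-9 µm tolerance.
* Mann–Whitney returns p = 1 when the tie-corrected variance vanishes
  (e.g. identical multisets).
* `render_scene` refuses configurations whose expected bouton count
  exceeds 10⁶ (desk-scale guard).

## Known limitations

* The 2-voxel minimum object size and the 26-neighbour maximum rule are
  resolution-dependent heuristics; at coarser sampling they would need
  revisiting.
* Densities are areal; the 1.5 µm stack is treated as a single section, so
  no attempt is made at volumetric (per µm³) density.
* The registration model is global similarity/affine — no nonrigid warp —
  and the displacement QC measures the transform itself, not residual
  tissue distortion.
* Recovery on the default scene runs ~3–5% below truth (merged sub-µm
  pairs and valley-tail misclassification); the acceptance bands (±10%
  counts, ±5 points fraction, ±15% density) absorb this bias, and it is
  visible in the tests rather than hidden by calibration.
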