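---
title: "Partial-volume CT volumetry: method, phantom emulation and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Partial-volume CT volumetry: method, phantom emulation and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ctvolumetry)
```

## The measurement problem

CT volumetry of objects with finely convoluted surfaces is hard for any
boundary-based method: partial-volume averaging blurs the interface over
several voxels, and the apparent boundary moves with the display window, the
segmentation threshold and the slice thickness. When, however, the object and
its surroundings are each of *uniform* density, no boundary needs to be
found. A region of interest (ROI) that encloses the whole object plus some
surrounding material has a mean density equal to the occupancy-weighted
average of the two material densities,

$$\bar{HU} = f\,HU_{obj} + (1-f)\,HU_{bkg},$$

so the object's area fraction inside the ROI is

$$f = \frac{\bar{HU} - HU_{bkg}}{HU_{obj} - HU_{bkg}},$$

and summing over the $N$ slices that contain any part of the object gives
the volume

$$V = \frac{T}{1000}\sum_{i=1}^{N} A_i f_i \quad [\mathrm{cm^3}],$$

with $T$ the slice thickness (mm) and $A_i$ the ROI area (mm²). The accuracy
index is the signed relative error $100\,(V - V_{ref})/V_{ref}$. These three
formulas are `objectFraction()`, `totalVolume()` and `relativeError()`. The
classical validation object for this method is a conglomerate of small
acrylic (PMMA) beads, about 120 HU, embedded in petroleum jelly, about
−150 HU — densities chosen to approximate parenchymal organ tissue and fat.

Two modelling commitments follow directly from the algebra and are worth
stating up front:

* **Fractions are not clamped to [0, 1].** Noise makes per-slice $f_i$ stray
  slightly outside; clamping would rectify the noise and bias $V$ upward.
  The number of out-of-range slices is kept as a diagnostic
  (`outOfRangeSlices()`).
* **Adding pure background to an ROI changes nothing (noise-free).**
  Appending $k$ background pixels rescales $A$ and shifts $\bar{HU}$ so that
  the product $A f$ is invariant. Over-inclusive ROIs and over-inclusive
  slice ranges are therefore harmless in the noise-free limit, and only
  interact with noise, density heterogeneity and miscalibration. This
  invariance is the central testable property of the ROI layer.

## The digital phantom

`packBeads()` builds the ground truth: random sequential addition of
non-overlapping spheres (tangency allowed within 1e−6 mm) with a settling
bias toward the lower centre of the box, emulating beads heaped in a scooped
bed of jelly. The physical reference object is a pack of roughly 750 beads
of 3.2–6.4 mm diameter with a displacement volume of 35.5 cm³. The diameter
*distribution* of that object is unknown; a uniform distribution over the
range would give about 48 cm³ for 750 beads, so the default mix
(`defaultBeadMix()`) is a discrete distribution skewed toward the small
diameters, calibrated once so that a 750-bead pack lands at 35.5 ± 2 cm³.
Ground truth is always `analyticVolume()` — the exact sphere-volume sum of
the realized pack — never the nominal 35.5.

`voxelize()` applies the mixture equation per voxel: occupancy is estimated
by regular sub-voxel sampling (default 4³ points per voxel; the sampling
error is below 0.5% even for the smallest beads and is tracked by analytic
oracle tests), and $HU = o\,HU_{obj} + (1-o)\,HU_{bkg}$. The default grid
mirrors a 14 cm reconstruction FOV on a 512 matrix (0.2734375 mm pixels)
with 0.625 mm native slices. Grid dimensions are padded up to multiples of
18 in-plane and 8 through-plane so that every downstream block average
(2.5 mm and 5 mm axial reslicing; 18 × 0.2734375 mm ≈ 4.92 mm reformat
slices) divides the grid exactly.

The acquisition emulators are deliberately simple, linear operators:

* `reslice()` — non-overlapping block mean along the stacking axis. No
  helical slice-sensitivity profile is modelled; thickness must be an
  integer multiple of the native spacing, which keeps the operator exactly
  mean-preserving.
* `addNoise()` — i.i.d. zero-mean Gaussian noise, seeded. Real CT noise is
  spatially correlated and kernel-shaped; white noise is a known
  simplification and makes every noise-related test a clean statistical
  statement.
* `edgeEnhance()` — in-plane unsharp mask,
  $out = in + s\,(in - G_\sigma(in))$, default $s = 1.5$, $\sigma = 0.8$ mm.
  The Gaussian rows are renormalized after truncation, so a flat field is
  reproduced exactly and all effect is confined to edges — the qualitative
  signature of sharp ("Lung"-type) reconstruction kernels, which alter CT
  numbers and noise texture near boundaries.
* `reformat()` — pure axis permutation (coronal/sagittal), followed by
  reslicing along the new stacking axis.
* `resamplePixels()` — in-plane area-weighted averaging onto a coarser grid
  spanning the same extent, emulating 30 cm and 50 cm FOV reconstructions as
  pixel-size ratios (×30/14, ×50/14) rather than re-reconstruction.

Slice indices are 1-based throughout, following R convention.

## ROIs and calibration

`autoMixtureROI()` emulates the freehand mixture ROI: the slice's
ground-truth object support dilated by a metric margin (default 2 mm — wide
enough to absorb through-plane blur at 5 mm slices, narrow enough to keep
the background share low), which by construction contains every object
pixel plus a rim of pure background. The dilation uses a mm-radius
elliptical structuring element so it remains correct on reformatted slices
with anisotropic in-plane spacing. An ROI touching the grid edge is an
error: it would include pixels outside the phantom and violate the
two-material premise. `scaleROI()` grows an ROI into background-only pixels
until a target area factor is reached, emulating deliberately oversized
ROIs; because the construction algorithm of the human freehand ROI is
unknowable, both are stated emulations, not reproductions.

`calibrateMaterials()` mirrors the workstation procedure: one ~10 cm²
background ROI, and small discs interior to ten beads on the slice where
each bead's cross-section is largest (disc radius capped at 0.58 of the
bead radius, shrunk so every covered voxel footprint lies inside the bead).
The object density is the unweighted mean of per-ROI means — the ten-bead
procedure — not a pooled pixel mean. ROI SDs use the population (divide-by-n)
convention; the choice affects diagnostics only, never the volume.
Calibration is performed on the thin-slice volume with low-noise
emulation, as in practice; for the edge-enhanced variant the densities are
re-measured on kernel-filtered thin slices, since such kernels shift the
apparent material densities.

## The robustness grid

`runExperimentGrid()` reruns the whole pipeline — pack, voxelize, calibrate,
transform, ROI, measure, invert, integrate, score — for each named
variation: standard (axial, 5 mm, low noise), 0.625 and 2.5 mm slices,
quadrupled noise (SD 22.3 HU), edge-enhancing kernel, coronal and sagittal
reformats, ×30/14 and ×50/14 pixel coarsening, and doubled mixture ROIs.
Noise is injected after reslicing to the output thickness, and each
replicate seed produces an independent phantom and noise realization. The
surrounding jelly rim defaults to 14 mm so that doubled ROIs have
background to grow into, as the physical jelly block extends well beyond
the bead cluster.

Problem sizes: the default (`quick = TRUE`) experiments use a 120-bead pack
in a 42 × 42 × 30 mm box (≈ 5.7 cm³ of beads) on a ≈ 270 × 270 × 56 native
grid — chosen as the smallest configuration that still averages dozens of
beads per slice and tens of mixture slices per volume; `quick = FALSE`
restores the full 750-bead, 70 × 70 × 45 mm scale. Accuracy at the two
scales is indistinguishable in our runs because the estimator's error terms
(voxelization bias, calibration sampling error, ROI noise) shrink or stay
constant with object count.

```{r, eval = FALSE}
grid <- experimentGrid(seeds = 1:3, quick = TRUE)
res <- runExperimentGrid(grid)
res[, c("variation", "mean_volume_cm3", "mean_relative_error_pct")]
```

What the simulation does and does not show: the emulator contains no
adherent micro-bubbles of air, no beam hardening, no helical interpolation
and no correlated noise, so its noise-free error is essentially the
voxelization bias (≪ 1%) and its noisy error stays far below the empirical
accuracy bounds reported for the physical experiment (within 3% axial, < 4%
reformatted). The physical residual of a few percent is attributed to
sub-visible air on the bead surfaces — a systematic density deficit the
simulator deliberately does not inject. Passing the simulation bounds
therefore validates the estimator and its implementation, not the absence
of such physical confounders in real scans. The edge-kernel emulation
reproduces the direction and ranking of the kernel effect (largest error,
object density reads high because small-bead interiors are brightened by
overshoot) but not the printed magnitude of any particular scanner kernel.

## Sensitivity to reference densities

`scenarioGrid()` perturbs the calibrated densities by ±2, ±5 and ±10 HU in
four classes (object only, background only, opposite sign, same sign) and
recomputes the volume from the *recorded* per-slice measurements — the same
recomputation a workstation user would perform. The closed form

$$\frac{V'}{V} = \frac{(\bar{HU}-HU_{bkg}-\delta_{bkg})/(HU_{obj}+\delta_{obj}-HU_{bkg}-\delta_{bkg})}{(\bar{HU}-HU_{bkg})/(HU_{obj}-HU_{bkg})}$$

is the test oracle. Two consequences verified by the property tests: the
effect is antisymmetric in $\delta$ to first order, and misspecifying the
density of the material occupying the larger share of the ROI (here the
background) produces the larger volume error.

## Numerical choices and degenerate inputs

* Equal material densities, empty ROIs/measurement sets, non-positive
  thickness or reference volumes, non-integer reslice factors, upsampling
  requests, and perturbations that collapse the two densities are all
  explicit errors, not silent results.
* All computation is double precision end to end; presentation rounding
  (0.1 cm³, 0.1%) happens only in the report layer of the command-line
  tool.
* Reproducibility: every stochastic stage (packing, noise, bead selection)
  takes an explicit seed, and sub-seeds for pipeline stages are derived
  deterministically, so a grid run is reproducible byte for byte.
* Polygon ROIs are rasterized by the pixel-centre even-odd rule, making the
  brute-force point-in-polygon oracle exact; raster area converges to
  polygon area as the grid is refined.

## Known limitations

Two-material mixtures only — no multi-material unmixing, histogram analysis
or segmentation, by design. The method requires both compartments to be
homogeneous; heterogeneity enters the emulation only through additive
noise. DICOM series reading is not included (NIfTI is the volume format;
`rescaleToHU()` covers the stored-value mapping); the bead container is an
axis-aligned box; and scanner physics beyond the linear operators above is
out of scope.
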