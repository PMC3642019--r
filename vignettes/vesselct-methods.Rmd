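---
title: "Simulated phase-contrast CT of vasculature: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulated phase-contrast CT of vasculature: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`vesselct` implements a complete in-silico counterpart of a synchrotron
micro-CT study of contrast-perfused ocular vasculature: phantom generation,
projection simulation, filtered back-projection (FBP) reconstruction,
grid-based vessel segmentation, microvessel-density quantification via the
angiographic score, and group-level statistics. Because real projection data
of this kind are rarely public, every stage is exercised end-to-end on
synthetic specimens whose ground truth is known exactly; the generator is the
oracle against which the analysis chain is validated.

## The imaging model

A specimen is modelled as a set of cylindrical vessel segments filled with a
radio-opaque agent, embedded in a non-attenuating background. The voxelized
attenuation field $\mu(\mathbf{x})$ (units: per µm) is projected under the
Beer–Lambert law on a parallel-beam geometry:

$$ I_\theta(r, t) \;=\; F(r, t)\, \exp\!\Big(-\!\int \mu \, ds\Big), $$

where $F$ is the flat-field (beam) profile, $t$ the detector column, $r$ the
detector row (vertical axis), and the integral runs along the ray at rotation
angle $\theta$. The default geometry mirrors the emulated acquisition:
180 projections at 0°–179° in 1° steps, a 9 µm detector pitch, and four
vertically stepped acquisition groups 4 mm apart (`CT1`, the fundus end,
through `CT4`). Beam energy (22 keV) and propagation distance (700 mm) are
carried as metadata only — see *Phase contrast* below.

Key phantom parameters:

* `contrast_per_um` (default 0.007/µm): lumen attenuation. A 210 µm vessel
  then transmits ≈ 23% at peak, typical of a barium-perfused vessel at hard
  X-ray energies; an 18 µm (2-pixel) vessel produces a ≈ 12% dip.
* `voxel_size_um` (default 9): matches the detector pitch, so one voxel
  projects onto one detector pixel.
* Sub-voxel vessels (diameter < 1 voxel) are guaranteed a one-voxel-wide
  footprint with attenuation scaled by the lumen/voxel area fraction. Without
  this rule the smallest calibre class of interest (18 µm ≈ 2 px; thinner
  segments can occur at branch tips) would vanish from the phantom entirely,
  making the detection-limit experiments meaningless.
* Vessel trees branch dyadically with per-level diameters fixed by the user
  (defaults 200/110/95/80/40 µm, the calibre ladder of a level-4 retinal
  arterial tree); children never exceed their parent's radius and always
  start at its end, which the constructor enforces.

### Phase contrast

Propagation-based phase contrast is modelled *phenomenologically*: in
`phase` mode the simulator subtracts $\lambda \nabla^2 \log I$ (5-point
discrete Laplacian, replicate-padded) from each projection. This produces
the characteristic dark/bright fringe pair at vessel edges while leaving the
total transmitted intensity essentially unchanged (the Laplacian integrates
to ~0). The default $\lambda = 0.5$ (flat-field intensity units per unit
log-intensity Laplacian) roughly doubles the peak contrast of a 2-pixel
vessel — the gain needed for edge enhancement to move the detection limit by
about one calibre class, which is the qualitative behaviour this model
exists to reproduce. A full Fresnel wave-optics treatment is deliberately
out of scope: the analysis chain only consumes the edge-enhancement
phenomenology, not the physics that produces it.

### Noise and detector model

Noise is Poisson (photon budget `photons` per pixel at unit intensity) plus
optional Gaussian read noise, applied after the optical model. An optional
isotropic Gaussian point-spread function (`psf_sigma_px`) emulates
scintillator/CCD blur; it defaults to 0 so that closed-form contracts (chord
profiles, rectangular FWHM) hold exactly, and is switched on (0.8 px) in the
detectability studies where a pixel-sharp detector would be unrealistically
favourable to the morphological-opening step. Background (flat-field) frames
are simulated twice per scan — nominally pre- and post-scan — with the same
noise treatment.

## Reconstruction

Per-slice reconstruction follows the classical chain:

1. **Normalization**: $-\log(I/I_0)$ with $I_0$ the mean of the two
   background frames. Non-positive intensities (possible under read noise or
   strong edge enhancement) are replaced by the smallest positive value in
   their 3×3 neighbourhood and counted in the log. Attenuation is clipped at
   a configurable floor of 0.
2. **Sinogram assembly**: row $r$ of every projection, ordered by angle.
3. **Rotation-axis estimation**: for parallel beams the 180° projection is
   the mirror of the 0° projection about the axis column. The axis offset is
   found by mirroring the largest-angle row (179° stands in for the absent
   180° frame under the 0–179° convention) about candidate positions on a
   0.1-column grid and minimizing the L2 distance to the 0° row. Induced
   offsets of ±5 columns are recovered to better than 0.2 columns; the 1°
   angular mismatch contributes an error well below that for smooth objects.
4. **FBP**: Ram-Lak ramp filtering by default (the filter's exact
   band-limited real-space kernel is transformed, avoiding the DC bias of a
   naive $|f|$ ramp), with optional Shepp-Logan or Hann apodization;
   back-projection with linear interpolation; output scaled so slices are in
   the same per-pixel attenuation units as the phantom. A noiseless 128²
   cylinder reconstructs with NRMSE ≈ 0.06 inside the lumen, and the
   implementation agrees with an independently coded brute-force
   back-projector to 10⁻⁶ relative RMS.
5. **Background equalization**: specimen thickness varies along the vertical
   axis, so the background gray level drifts between slices. The background
   is estimated as the 256-bin histogram mode inside a central annulus
   (radii 0.55–0.85 of the half-width, configurable) assumed to lie outside
   the vessel support, and the slice is shifted so that level maps to a
   fixed mid-gray (0.5). A shift is used rather than a rescale so relative
   vessel contrast is untouched. Negative reconstructed values are *kept*
   until segmentation: clipping would skew the gray-level histogram that
   Otsu thresholding relies on.

## Segmentation

Scoring windows are 200 × 200-pixel regions of interest divided into 25
blocks of 40 × 40 pixels. Segmentation is:

1. a global Otsu threshold (256-bin histogram over the ROI's own min–max
   range) as initialization;
2. per-block Otsu refinement, with each block's threshold clamped to within
   `clamp` (default 0.1) times the ROI value range of the global threshold.
   The clamped refinement is a reproducible surrogate for manually adjusting
   each block's threshold against its local histogram; the clamp prevents
   runaway thresholds in vessel-free blocks. A minimum-contrast guard marks
   blocks whose gray-level spread is below `min_contrast` (default 0.2) of
   the ROI spread as all-background, so Otsu cannot hallucinate vessels in
   flat blocks. `clamp = 0` reproduces pure global thresholding exactly.
3. morphological **opening** (erosion then dilation) with a 3 × 3 square
   structuring element, which removes noise specks smaller than the element
   while preserving structures ≥ 3 px wide. The operation is sometimes
   described operationally as "dilate, then erode"; since the stated purpose
   is noise removal — which is what opening does, whereas closing fills
   holes — opening is the implemented default, with a `closing` flag
   available for comparison experiments.

Polarity is explicit: vessels are *darker* than background on projection
films and *brighter* on reconstructed slices.

## Quantification

* **Angiographic score**: vessel pixels divided by total pixels in the ROI —
  an exact counting ratio.
* **Sampling scheme**: 3 view angles (0°, 90°, 180°) × 3 films × 3 random,
  non-overlapping ROIs per film = 27 scores per acquisition group. Only one
  projection exists per angle, so the three "films" for a nominal angle are
  the projection at that angle plus its two immediate angular neighbours
  (e.g. 89°/90°/91°), preserving both the sample count and the intent of
  averaging out angular variation; 180° maps to the 179° projection.
  ROI placement is uniform within the vessel-bearing bounding box (known
  from ground truth in simulations) and uses rejection sampling with
  whole-film restarts, erroring with the maximum feasible count when the
  requested number cannot fit.
* **Diameter measurement**: full width at half depth of a line profile,
  extracted with bilinear interpolation at 1-px spacing. The background
  level is the median of the outer 20% of profile samples; the dominant
  extremum (dip or peak, per polarity) defines the depth; the two half-depth
  crossings are located by linear interpolation, yielding fractional pixel
  counts. Diameter is `pixel_count × pitch` exactly, reported at two
  significant figures (so 7.8 px × 9 µm → 70 µm). For saturated (strongly
  absorbing) vessels the intensity-domain FWHM approaches the geometric
  diameter, which is why the half-depth rule is a reasonable reading of
  cursor-based measurements on real films; profiles of *weakly* absorbing
  cylinders have FWHM $\sqrt{3}/2$ of the true diameter, a known limitation
  of any width-at-threshold rule.
* **Detection limit**: the smallest tube diameter in an ascending sweep
  whose segmented projection mask recovers ≥ 50% of the ground-truth shadow
  pixels, decided on the median of 3 matched-noise replicates. Opening is
  not applied in this particular measurement: it would erase the 2-pixel
  shadows whose detectability the sweep is designed to probe.

## Study designs built into the package

**Density-recovery study.** Vertical tubes on a square lattice give every
spacing-aligned scoring window exactly the designed lumen area fraction
$\pi r^2 / s^2$, making the generator an exact oracle for score recovery.
The lattice radius is calibrated so the *rasterized* disk covers the
designed fraction of voxels (the analytic radius alone is off by a few
percent at these disk sizes). The standard run uses four groups at designed
fractions 0.27/0.22/0.16/0.25 — a fundus-to-iris density gradient with its
minimum anterior to the equator — at 256² slices, spacing 20 px,
photon budget 5000, and recovers each group mean within ±0.015.

**Contrast-mode twin study** (`mode_twin_study`). The same dilute-contrast
microvessel specimen (30 tubes of 18–36 µm, 0.004/µm attenuation) is imaged
in absorption and in phase mode under matched noise (photon budget 50,
≈ 14% relative noise; PSF 0.8 px) and scored identically. The conditions
put the absorption-mode detection limit in the tens of micrometres, the
regime a detectability comparison is about; there the phase-mode score
exceeds the absorption score and the phase-mode detection limit is at or
below the absorption one, consistently across seeds and layouts. Outside
that regime the comparison genuinely inverts: when every vessel is already
well above the absorption detection limit, edge enhancement *narrows*
threshold-based masks (it concentrates signal toward vessel cores and
brightens the flanks) and can lower the score. That inversion is a property
of automated threshold segmentation, worth knowing before applying scores
across contrast modes.

**Statistics.** Group summaries are mean ± sample SD over the 27 scores.
Between-group comparison is all pairwise two-sample tests — Welch's t by
default, Mann–Whitney as an option — assembled into a symmetric p-value
matrix with unit diagonal and */** stars at 0.05/0.01. No multiple-testing
correction is applied by default (Bonferroni and friends are available via
`p_adjust`), matching common practice in the application area. Null
calibration over 1000 seeded replicates shows 5 ± 2% rejections at
α = 0.05 for both tests, and synthetic groups drawn at the built-in density
gradient flag the low-density group at ** against both high-density groups
in ≈ 100% of replicates.

## Numerical choices and degenerate inputs

* Angles are 0–179° inclusive; 180° is excluded as redundant with 0° for a
  parallel beam.
* Otsu on a constant image raises a "degenerate histogram" error; a constant
  *ROI* yields an all-background mask; a constant *block* falls back to the
  global threshold (logged).
* `equalize_background` on a constant slice warns and returns the input.
* Axis estimation on an all-zero sinogram errors ("no signal").
* The between-class-variance surface is nearly flat near its maximum, so two
  correct Otsu implementations can disagree by several bins while agreeing
  on the objective to < 0.1%; tests compare objectives, not thresholds.
* All randomness flows through explicit seeds; the full pipeline is a pure
  function of (configuration, seed), and reruns are byte-identical.
* Image stacks are written as multi-page 32-bit TIFF with an affine scale
  recorded in the JSON sidecar, so round-trips are exact to float32
  precision.

## Problem sizes

Simulated studies run at 64²–256² transverse grids with a handful of slice
rows — vertical tubes make slices redundant, so a few rows per group carry
the same information as a tall stack. These sizes keep every validation
study comfortably reproducible on a laptop while leaving all algorithmic
paths identical to a full-size run (the per-slice chain is embarrassingly
parallel over rows).

## What the synthetic specimens do and do not show

The generator emulates: branching calibre ladders, contrast-filled lumens,
flat-field nonuniformity, Poisson/read noise, detector blur, vertically
stepped acquisition groups, and phase-contrast edge enhancement. It does not
emulate: contrast-agent sedimentation and the vessel breakpoints it causes,
scatter, polychromatic beams, surrounding soft-tissue texture, or motion.
Passing the recovery studies therefore shows the *analysis chain* is
unbiased under its stated model, not that scores from real specimens are
free of preparation artefacts — on real data the segmentation's behaviour
near breakpoints and texture would need separate validation.
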