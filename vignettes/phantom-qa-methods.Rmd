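---
title: "Geometric-accuracy QA for preclinical MRI: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Geometric-accuracy QA for preclinical MRI: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phantomqa)
```

## The measurement problem

Small-bore (preclinical) MRI scanners are routinely used to quantify lesion
volumes in rodent models, yet their geometric accuracy is rarely monitored.
Gradient miscalibration scales the image along each gradient axis, so a
measured length `L` relates to the true length `L0` by `L = L0 (1 + e/100)`
with a per-axis *linear scaling error* `e` (percent). A volume measured by
segmenting and counting voxels inherits all three axis errors plus
resolution effects. `phantomqa` implements a complete phantom-based QA
pipeline around these quantities: a parametric phantom model, a scan
simulator with exactly known implanted errors, sub-pixel dimension and
volume measurement, error statistics, and 2D deformation mapping.

The central analytic relationship is the volumetric error predicted from
per-direction scaling errors alone,

$$pe_V \;=\; 100\,\frac{(e_x + 100)(e_y + 100)(e_z + 100)}{10^6} \;-\; 100,$$

computed from the medians of the per-direction errors. The gap between a
measured volumetric error and $pe_V$ isolates what scaling cannot explain:
partial volume, thresholding behaviour and noise.

## The phantom model

The phantom is a fluid-filled cuboid with caliper-verified internal
dimensions 12.80 x 8.45 x 12.80 mm (x, y, z; y vertical) and a central
compartment shaped as a cylindrical frustum whose ground-truth volume is
153.14 mm^3^. The fill solution is doped to a transverse relaxation time of
T2 = 53.1 ms; plastic, tape and air carry no signal.

Published geometry does not fix the frustum's radii or height, so the
package adopts one consistent parameterization and treats it as ground
truth everywhere:

* frustum axis along y, wide end down, hanging from the interior ceiling
  with its open base sealed by a tape slab (0.2 mm thick, 6.0 mm lateral
  extent);
* height = interior_y - tape = 8.25 mm, radius ratio r_top / r_bottom
  = 0.8, and r_bottom = 2.695306 mm solved analytically so that
  `frustum_volume()` equals 153.14 mm^3^ to better than 0.01 mm^3^;
* a 1.2 mm plastic wall around the cavity. A much thinner wall would be
  invisible through a 1 mm slice (its through-slice contrast dilutes
  below the segmentation threshold) and is implausible for an
  injection-molded part; 1.2 mm leaves the compartment resolvable in every
  protocol used here.

Because the wall's maximal lateral extent is r_bottom + wall = 3.9 mm,
vertical (y) measurement profiles are placed 15 % of the interior width
from the left interior edge (4.48 mm from centre), clear of both wall and
tape; this also matches the practice of measuring the height along the
side of the phantom.

## The scan simulator and what it does (not) emulate

`simulate_scan()` produces multi-slice 2D magnitude stacks for six
sequence presets (`"a"`...`"f"`; the shared standard protocol `"a"` uses a
19.2 mm FOV, 256 x 256 matrix, 1 mm slices). The signal model is a
deliberate two-tissue T2-weighted idealization:
`S = occupancy * exp(-TE_eff / T2)` for solution, zero for solids and air.
There is no Bloch simulation, no RARE echo-train blurring, no k-space
artefact model (ghosting, Gibbs ringing, susceptibility, eddy currents):
passing tests therefore demonstrate the *geometric* fidelity of the
measurement chain, not robustness to every artefact of real data.

Key design choices:

* **Distortion acts on coordinates, before sampling.** Scaling errors,
  smooth nonlinear fields (B-spline lattice or Gaussian bump, bounded at
  0.3 mm by default) and frequency-axis shifts warp the sampling
  coordinates of the phantom model, so the implanted ground truth is
  exact: a +2 % x-error makes every x-length exactly 1.02 times larger.
* **Analytic partial volume.** Per-voxel occupancy is computed
  analytically — exact box-filter interval overlaps for every
  axis-aligned face, and a linear ramp over the normal-projected filter
  support for the curved frustum surface. A supersampled counting scheme
  quantizes occupancy in steps of 1/s and would bias sub-pixel edge
  localization by up to ~0.03 mm; the analytic model leaves residual
  dimension errors below 0.005 mm. (The label-volume rasterizer,
  `rasterize_phantom()`, does use supersampled majority voting — labels
  are categorical and serve as ground-truth masks, not as the signal.)
  Voxel footprints are scaled by the implanted per-axis factors, keeping
  pure scaling exact.
* **Noise and bias.** Rician noise `sqrt((I + n1)^2 + n2^2)` with
  `sigma = plateau / SNR`; SNR is a free parameter (the study this mirrors
  reports none per centre). An optional multiplicative second-order
  polynomial per slice stands in for receive-coil inhomogeneity; full
  N4-style bias correction is out of scope.
* **Slice stacks default to odd counts** so a slice passes through the
  phantom middle, as a real protocol's slice-positioning instructions
  prescribe. Volume results are sensitive to half-slice misalignment —
  a real and documented effect of 2D volumetry.

`simulate_ct()` produces the empty-phantom reference volume (solid bright,
air dark) at <= 0.1 mm isotropic resolution with the same analytic
partial-volume model.

## Measurement

**Dimensions.** On the most central slice containing the phantom, a 5-line
band of intensity profiles is averaged, lightly smoothed with a 1-pixel
Gaussian, and the distance between the outermost crossings of the 50 %
plateau-to-background contrast is interpolated linearly to sub-pixel
precision. The smoothing exists because the partial-volume edge ramp is
exactly one pixel wide: without it one of the two interpolation samples
sits on the clamped plateau and the edge shifts by up to ~0.1 px. The edge
criterion itself (50 % relative threshold, linear interpolation) is a
documented stand-in for an unpublished interactive tool, validated by the
Bland-Altman/Dice harness rather than asserted as a reproduction.

**T2 mapping** (for the multi-echo preset `"c"`): per-voxel log-linear
regression of `ln S` on TE, truncating each voxel's echo train at the
first sample at or below the noise floor, with the optional Rician power
correction `sqrt(S^2 - 2 sigma^2)` when the noise level is known. The map
is then inverted (`max - I`) to restore solution-bright contrast before
the standard measurement.

**Compartment volume.** Per-slice thresholding at 50 % between background
and a *local* plateau estimated from the previous slice's footprint
(median intensity), propagated outward from the most central slice and
keeping the connected component of maximal overlap. Three guards make the
rule behave like a careful reader of a semi-automated tool:

* the local plateau is floored at half the global plateau, so a vanishing
  boundary-slice contrast cannot drag the threshold into the background;
* a slice is abandoned once its footprint contrast falls below 8 % of the
  global contrast (the compartment is no longer discernible; the failure
  boundaries for the default geometry sit near 5 % and 10 %);
* propagation stops beyond the compartment's equatorial in-plane
  half-width — the compartment is rotationally symmetric about y, so its
  through-slice extent equals that half-width, and without this bound
  thresholding can tunnel through the dark wall where a slice straddles
  its far side.

This rule reproduces, structurally, the reported behaviour of 2D
volumetry: boundary slices are included at dimmed thresholds, so measured
volumes exceed the prediction from scaling errors alone, and thicker
slices overestimate more (the acceptance script computes ~+9.5 % at 1 mm
and ~+4.4 % at 0.5 mm slices on the default geometry).

**CT calibration** mirrors the ground-truth procedure: Gaussian smoothing
at FWHM 81.2 um, then a single threshold solved (monotone root finding)
so the binarized mask reproduces the sum of the caliper dimensions, with
per-axis residuals reported; interior extents are measured with sub-voxel
interpolation on lines placed at 33 % of each dimension from centre
(clear of wall and tape). The compartment is the enclosed air component
per y-slice, excluding any component touching the volume border.

## Statistics

Errors are plain percent deviations; summaries use medians and
type-7 (linearly interpolated) quantiles. The Mann-Whitney U statistic is
implemented from rank sums — `U_a` counts pairs `a < b` plus half-ties and
both orientations are reported, since published tables print only one —
with an exact p-value (null distribution of U) when there are no ties and
`n_a n_b <= 400`, otherwise a tie-corrected, continuity-corrected normal
approximation. Tests cross-check it against exhaustive pair counting and
`stats::wilcox.test`. Bland-Altman limits use the n-1 standard deviation;
Dice of two empty masks is defined as 1 with a warning. No multiplicity
correction is applied: the design involves a single planned test at
two-sided 0.05.

The replication harness (`read_qa_workbook()` / `replicate_results()`)
normalizes a deposited measurement workbook (XLSX, or a directory of CSV
sheets with the same column layout) to a long table and recomputes the
headline statistics next to their published reference values. The
workbook's exact sheet structure is not documented anywhere accessible, so
the reader matches columns by name synonyms and fails with a schema
listing when a layout is unrecognized.

## Deformation mapping

The Fig-3-style workflow is: intensity normalization (background 0,
plateau 1), rigid alignment to a reference slice (multi-start Nelder-Mead
on mean squared difference, 1 px pre-blur to widen the capture range),
bicubic resolution matching where needed, then a free-form cubic B-spline
deformation optimized with analytic gradients (L-BFGS-B) under a bending
penalty (`lambda = 0.01`, second differences of the control lattice,
default spacing 8 px). The field starts at zero, so the residual never
exceeds the rigid-stage residual; hitting the iteration cap returns the
best field with a warning. The per-pixel Euclidean magnitude
`sqrt(dx^2 + dy^2)` is the distortion map. This is an
equivalent-contract stand-in for consistent elastic registration plugins,
not a reimplementation; recovery of implanted fields is validated only
where image gradients exist (object edges), which is the physically
available information.

## Problem sizes and determinism

All randomness flows through explicit integer seeds; rerunning any study
with the same configuration is bit-identical. The test-suite and
acceptance problem sizes are chosen to exercise the full protocol while
staying desk-sized: dimension scans use three slices (the measurement only
consumes the central slice), volume stacks cover the compartment plus
margin (13 slices at 1 mm, 23 at 0.5 mm), CT calibration runs at the full
34.5 um in the acceptance script and at 60 um in the unit tests, and the
noisy recovery checks use SNR 20 with ten seeded replicates.

## Known limitations

* The frustum geometry, wall thickness, tape extent and orientation are a
  documented parameterization consistent with the published interior
  dimensions and ground-truth volume, not measured values.
* The simulator's artefact inventory is deliberately small; conclusions
  about susceptibility, ghosting or echo-train blurring cannot be drawn
  from it.
* The segmentation rule's boundary-slice behaviour was designed to mirror
  the reported inclusion behaviour of interactive volumetry; other rules
  (e.g. a strict 50 % through-slice occupancy criterion) yield smaller or
  negative volume bias and are selectable via `min_contrast`.
* Deformation mapping is 2D and qualitative; it demonstrates distortion
  patterns, not a voxel-accurate distortion calibration.
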