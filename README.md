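# phantomqa

Phantom-based geometric-accuracy quality assurance for preclinical
(small-bore) MRI.

Animal studies quantify stroke, tumour and other lesions from structural
MRI, but the scanners doing the measuring are rarely checked for geometric
accuracy: miscalibrated gradient coils scale the image along each axis,
and 2D volumetry adds partial-volume and thresholding biases on top. This
package is for imaging-facility physicists and analysts who want to
quantify those errors — on real phantom scans, or on simulated scans with
exactly known implanted distortion.

It implements the full QA pipeline around a small structural phantom: a
cuboid with caliper-verified internal dimensions 12.80 × 8.45 × 12.80 mm
and a central frustum-shaped compartment of ground-truth volume
153.14 mm³, filled with a doped solution (T2 = 53.1 ms).

**Core quantities.** A measured length `L` gives the per-axis linear
scaling error `e = 100 (L − L₀)/L₀`; a measured compartment volume `V`
gives the volumetric error `e_V = 100 (V − V₀)/V₀`. The volumetric error
predicted by linear scaling alone is

    pe_V = 100 · (e_x + 100)(e_y + 100)(e_z + 100) / 10⁶ − 100

evaluated at the per-direction medians. The excess of `e_V` over `pe_V`
is the contribution of partial volume, thresholding and noise — the
quantity 2D volumetry should worry about.

**Modules.**

- `phantom_spec()`, `frustum_volume()`, `rasterize_phantom()` — parametric
  phantom model and ground-truth rasterization;
- `simulate_scan()`, `simulate_multiecho()`, `simulate_ct()`,
  `distortion_model()`, `noise_model()` — scan simulator with exact
  implanted scaling errors, smooth nonlinear fields, partial volume, bias
  field and Rician noise;
- `measure_dimensions()`, `edge_positions()`, `fit_t2_map()`,
  `segment_compartment()`, `compute_volume()`, `calibrate_ct_threshold()`
  — sub-pixel opposing-edge dimension measurement, T2 mapping, compartment
  volumetry and CT threshold calibration;
- `scaling_error()`, `predicted_volumetric_error()`, `summarize_errors()`,
  `mann_whitney_u()`, `bland_altman()`, `dice()` — the statistics layer;
- `register_rigid()`, `register_bspline()`, `displacement_magnitude()`,
  `deformation_map()` — per-pixel distortion maps against a reference;
- `run_study()`, `run_longitudinal()`, `read_qa_workbook()`,
  `replicate_results()` — between-scanner and longitudinal orchestration
  and deposited-data replication.

## Worked example

Simulate a between-scanner comparison: one scanner with a gross gradient
miscalibration (+4.47 %, +4.82 %, +4.47 % on x, y, z) and one calibrated
scanner, both at SNR 40, measured with the standard protocol (six scans:
three planes × swapped frequency/phase encoding):

```r
library(phantomqa)

study <- run_study(list(
  A  = list(distortion = distortion_model(c(4.47, 4.82, 4.47)), snr = 40),
  ok = list(distortion = NULL, snr = 40)), seed = 7)
study
#> # Phantom QA report
#> Scaling-error acceptance bound: +/- 1.00 %
#>
#> | group | e_x % | e_y % | e_z % | e_V % | pred e_V % | diff (pts) | within bounds |
#> |---|---|---|---|---|---|---|---|
#> | A | 4.42 | 4.78 | 4.41 | 19.08 | 14.23 | 4.85 | NO |
#> | ok | -0.06 | -0.08 | -0.06 | 8.63 | -0.20 | 8.82 | yes |
```

Reading the table: the miscalibrated scanner's implanted scaling errors
are recovered to within a few hundredths of a percentage point from the
images, and its measured volumetric error (19.08 %) exceeds the 14.23 %
predicted by scaling alone — the excess (4.85 points) is the
partial-volume/thresholding contribution of 1 mm-slice volumetry, which is
present even on the calibrated scanner (8.82 points). Per-direction
medians outside the ±1 % bound are flagged.

The ground-truth side of the pipeline works the same way on a simulated
reference CT:

```r
spec <- phantom_spec()
ct   <- simulate_ct(spec, iso_resolution_mm = 0.0345)
cal  <- calibrate_ct_threshold(ct, c(12.80, 8.45, 12.80))
ct_compartment_volume(cal$smoothed, cal$threshold)
#> [1] 153.1064        # 153.14 mm^3 analytic, -0.02 %
```

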