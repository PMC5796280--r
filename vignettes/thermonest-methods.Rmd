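---
title: "Methods: thermographic nest-occupancy sensing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: thermographic nest-occupancy sensing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(thermonest)
```

This vignette documents the model behind `thermonest`, the parameter choices
that matter, what the synthetic generators do and do not emulate, and the
numerical conventions. It states no empirical result beyond what the test
suite and `scripts/acceptance.R` themselves compute.

## The sensing model

A thermographic frame is an 8-bit grayscale image whose pixel intensities
are proportional to scene surface temperature under a linear calibration
(`temperature_calibration()`, default 0 °C ↔ 0 and 51 °C ↔ 255, i.e.
0.2 °C per step — an order of magnitude finer than the ±2 °C accuracy of
typical uncooled microbolometer cameras, so the calibration grid never
limits accuracy). Radiometric physics (emissivity, Planck-law inversion) is
out of scope: intensities are taken as already linearized by the camera.

The per-frame pipeline (`process_frame()`) assumes the nest interior is a
scene with exactly two thermal populations:

* a **floor/background** population: the large majority of pixels,
  approximately normal around the floor temperature;
* **warm bodies**: hens, substantially warmer than the floor.

### Background estimation

The floor temperature is estimated as the *mode* of the intensity
histogram after a centred 5-bin moving average, not as the global mean:
the histogram's dominant component is the background normal, and its mean
coincides with its mode, whereas the global mean is biased upward by
warm-body pixels. The 5-bin window (1 °C at the default calibration) is
wide enough to stabilize the arg-max under Poisson bin noise and narrow
enough not to shift a background peak sitting next to a body peak.
Smoothing can flatten an extremely sharp peak into a plateau of tied bins;
ties are broken by the raw bin count and then toward the lower intensity,
so a constant frame is recovered exactly. On pure Gaussian floors
(σ = 0.3 °C) the estimator recovers the mean within ±0.5 °C in ≥ 99% of
seeded replicates (property-tested).

### Thresholding, particles, CP, MNO

The Background Color Threshold is the floor estimate plus a shift Δt
(field settings 1, 3 or 5 °C), converted to intensity. "Overcame" is read
as *strictly greater than* for both comparisons in the pipeline — a pixel
is foreground iff `intensity > BCT`, and a frame is flagged iff
`CP > MNOT` — on the grounds that a threshold named after the background
must itself classify as background, and that the two rules should be
consistent. A shifted temperature beyond the calibration range clips to
intensity 255 with a warning, which makes a frame colder than the
calibration range yield CP = 0 rather than an error.

Particles are 8-connected components (diagonal contact joins a hen's
head and body across a thin neck even when rasterization leaves only a
corner touch). The spot filter is an area opening with a default minimum
area of 50 px — about 7% of a head imprint, large enough to kill salt
noise and small reflections, small enough never to touch a real imprint.
The filter is idempotent and never increases CP (property-tested).

### Template matching

Hen counting runs on the **binary** image (the pipeline's flow places
pattern recognition after binarization), treating mask values {0, 1} as
intensities. The raw cross-correlation
`C(i,j) = Σ t(x,y) p(x+i, y+j)` is provided for completeness; the sensor
uses the normalized form `R(i,j)` (mean-centred template and window,
divided by the product of root-sum-square deviations), which lies in
[−1, 1] and is invariant under positive affine intensity maps. Windows
with zero intensity variance carry no evidence for or against a match and
score 0 by convention; a constant template is rejected as an error because
its own variance term vanishes.

Both kernels are compiled (Rcpp) and compute *exact* sums: window
statistics come from summed-area tables, which are exact in double
precision for integer-valued images, and the cross term is accumulated
directly over the template's nonzero pixels. The implementation is
validated against an exhaustive double-summation oracle (exact for `C`,
< 1e−9 for `R`) on hundreds of random small images.

Orientation is handled by matching the template at every rotation in
`rotation_step` increments (default 30°, 12 orientations — the coarsest
step at which a triangle rotated half a step still overlaps its template
well above threshold), nearest-neighbour re-rasterized and re-binarized.
Candidates at or above the score threshold (default 0.5) from all
rotations are pooled and reduced by greedy non-maximum suppression,
highest score first.

The **suppression radius** defaults to the *longest side of the template*
(43 px for the deployed triangle). A radius of half the template diagonal
(27 px) looks natural but measurably fails its purpose: a 43 × 33 triangle
re-matches its own 180°-flip at R ≈ 0.52 at a centre offset of ≈ 28 px,
so one hen would be counted twice at the default threshold. Self-match
artifacts are bounded by the template's extent, while genuinely distinct
hens sit farther apart than one template length, so the longest side is a
safe separator. The hen count is capped at `max_hens` (default 5) as a
guard against degenerate inputs.

When MNO = 0 the sensor skips matching (the monitoring system only needs
the count in the multiple case) and reports one hen if CP exceeds the
minimum particle area, zero otherwise; the single-hen identity comes from
the RFID layer, not from vision.

### Calibration (steps A and B)

`compute_cp_distributions()` produces per-label CP samples and a two-group
one-way ANOVA. The F statistic is computed from between/within sums of
squares — a deliberately explicit, testable formula (for two groups it
equals the squared pooled-variance t statistic; the tests cross-check it
against `stats::aov` and `stats::t.test`).

`select_mnot()` returns the **largest** integer cutoff whose sensitivity
(share of multiple-occupation frames with CP strictly above it) still
reaches the target, default 80%. "At least 80%" leaves the direction open;
maximizing the cutoff maximizes specificity subject to the sensitivity
floor, which is the only reading consistent with calibration sensitivities
hugging the floor from above while specificity stays high. The selection
is validated against an exhaustive scan of every integer cutoff.

Step B (`evaluate_step_b()`) runs the full configured sensor over a
labelled set and scores the MNO flag with positive = multiple occupation;
the returned per-frame hen counts support a separate counting-accuracy
assessment on the truly-multiple frames.

Calibration set sizes are configurable; the shipped tests and the
acceptance script use 200 scenes per label, a desk-scale stand-in chosen
so the whole calibration-plus-evaluation run completes in a few minutes on
one CPU while keeping the binomial noise on a 90% rate near ±2%.

## The synthetic scene generator

`generate_scene()` emulates the statistical structure the sensor assumes,
not hen photorealism:

* **floor**: uniform temperature drawn from 13–21 °C per scene (the field
  range of the reference deployment), plus i.i.d. Gaussian pixel noise,
  σ = 0.3 °C — deliberately ~7× the nominal 0.04 °C camera sensitivity,
  to be conservative;
* **hens**: a rigid body — a filled **body ellipse** whose *surface*
  (feathers insulate) sits only 3.5 °C above the floor, carrying a
  **head/comb triangle** at 37–40 °C placed fully inside the body outline
  near one end (the top view of a sitting hen), both with per-pixel jitter
  at the same σ. Bodies are rendered first and heads second, so an
  overlapping neighbour's cooler body never occludes a head.

This two-layer thermal model is what gives the generator the same
shift-dependent behaviour as real imprints: at Δt = 1 °C the whole body
ellipse is above threshold (whole-body imprint, equivalent-ellipse
descriptor), at Δt = 5 °C only the head triangle survives (head imprint,
bounding-rectangle descriptor), and a single hen's CP stays in the
single-occupation regime under the deployed MNOT. Geometry defaults are
body axes 151–165 × 77–89 px and head triangles 42–44 × 32–34 px
(height × base), matching the reference deployment's reported template
statistics (means 158 × 83 and 43 × 33).

A configurable fraction of scenes (default 10%) are **hard cases**: a
single hen clipped at the frame border, or a multiple scene whose second
hen's head is dropped only 20–40 px from the first (body overlap is
allowed in regular scenes too — hens huddle — and is flagged in the
truth). Hard cases exist so that the evaluation includes the failure
modes a real nest produces: imprints cut by the field of view and merged
head blobs.

What the generator does **not** emulate: feather texture, temperature
gradients across the body, radiosity/reflections, camera vignetting or
lens soiling, motion blur, and partial visibility from hens standing at
the nest border with the head outside the frame. Passing tests therefore
demonstrate the pipeline's correctness and its behaviour under the
assumed two-population thermal model, not field performance; the published
field numbers enter the tests only through the metric formulas applied to
the published confusion tables.

`generate_event_stream()` scripts visits (1 Hz RFID reads, exponential
durations with a 10 s floor, per-visit egg and multiple-occupation
probabilities) with consecutive visits forced to different hens, so the
number of ground-truth records equals the number of visits and the state
machine can be checked for exact recovery.

## Numerical conventions and edge cases

* Coordinates are row-major, origin at the top-left pixel, 0-based in all
  public values (offsets, centroids, detection centres); matrices are
  indexed 1-based internally as usual in R.
* Intensity conversion rounds **half-up** (`floor(x + 0.5)`), then clips
  to [0, 255]; percentages round half-up to one decimal, the reporting
  convention of the field. The temperature→intensity→temperature round
  trip errs by at most half a calibration step.
* The equivalent ellipse is the second-moments ellipse (axes
  `4·sqrt(eigenvalues)` of the pixel covariance with a 1/12 unit-pixel
  correction); it is rotation/translation-invariant and recovers a
  rasterized ellipse's axes within ±2 px. A degenerate collinear particle
  gets a minor axis floored at 1 px.
* The bounding rectangle is the minimum-area *rotated* rectangle
  (rotating calipers over the convex hull of pixel centres, plus one
  pixel per side). Hulls of centres rather than corners avoid inflating
  oblique staircase edges; an axis-aligned w × h block measures exactly
  w × h.
* Templates rasterize by pixel-centre inclusion; every triangle row keeps
  at least one pixel so the apex survives. Rendered areas match the
  analytic `h·b/2` (triangle) and `π·h·b/4` (ellipse) within 5%.
* Rotated templates that exceed the image at some rotation skip that
  rotation with a warning rather than failing the match.
* `select_mnot()` with an unreachable target warns and returns 0; a
  metrics call with an empty denominator (TP+FN = 0 or TN+FP = 0) is an
  error rather than a silent NaN.
* Event streams must be time-ordered; an egg with no open record is
  collected as an orphan, not an error; a `nest_empty` event closes the
  open record so end-of-day records are flushed (the reference system
  only closed records on the next hen's arrival, which would leave the
  last visit of a day unstored).

## Known limitations

* Matching on binary imprints discards interior intensity structure; two
  hens whose head imprints merge into one blob are resolved only when the
  template still fits their flanks distinctly.
* The MNOT is a pure area threshold: a single unusually large imprint
  (wings spread) can exceed it, and two heavily occluded hens can stay
  below it; that is inherent to the CP statistic, not to this
  implementation.
* The linear intensity↔temperature model and the fixed camera geometry
  (no multi-scale search) are assumptions inherited from the deployment
  this package models.
* The one-way ANOVA assumes independent frames; consecutive video frames
  of the same visit are strongly dependent, so calibration sets should be
  subsampled accordingly.
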