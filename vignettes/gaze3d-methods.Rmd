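---
title: "Eyeball modeling and IR-to-RGB gaze mapping: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Eyeball modeling and IR-to-RGB gaze mapping: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gaze3d)
```

## The problem

A head-mounted tracker with two eye cameras — one infrared, one RGB —
can track the pupil reliably only in the IR stream, while the corneal
image (the scene reflected on the cornea) is visible only in the RGB
stream. Relating the two requires a point-to-point transform between the
image planes, and for that an object-level 3D model: the eyeball itself.
`gaze3d` builds that model per user and per wearing, with no calibration
procedure on the user's side, and uses it for IR→RGB mapping, 3D gaze
rays, online validity monitoring, and self-supervised label harvesting.

## Geometry and conventions

* World frame = IR camera frame; the IR camera sits at the origin with
  identity rotation. All 3D quantities are in **millimetres** — the fixed
  12 mm eyeball radius and the 2 mm filter windows make mm the natural
  unit.
* Pixels are continuous, 0-based, origin top-left, x right, y down.
* The stereo pose follows the projection-matrix convention: a world
  point `X` maps into the RGB camera as `K_rgb (R X + T)`, so the RGB
  camera center is `−RᵀT` and an RGB pixel's world direction is
  `Rᵀ K_rgb⁻¹ p′`. Conventions in the eye-tracking literature differ on
  whether `(R, T)` denotes the forward or inverse transform; we fix the
  projection matrix `M_rgb = K_rgb [R|T]` as the single source of truth
  and derive everything else from it, because the output mapping is
  computed with `M_rgb` and any internally inconsistent convention would
  silently bias the mapped pixels. If a device's calibration uses the
  opposite convention, invert the pose before writing the calibration
  file.
* Lens distortion is not modeled (pinhole only): eye cameras sit a few
  centimetres from the eye with narrow effective fields of view, and the
  calibration file format has no distortion fields.

## Triangulation and outlier filtering

For each synchronized detection pair, the top-left, center and
bottom-right points of the pupil bounding rectangles are triangulated
independently — all three lie near the corneal surface, tripling the
sample count per frame (a `points = "center"` switch restricts to
centers). The closest-approach problem for the two back-projected rays is
solved by linear least squares on the 3×2 system; the midpoint `S` of
the two closest points is the 3D estimate and the residual gap `d` the
stereo-consistency score.

Two filters then run, with defaults of 2 mm each:

* **gap filter** — `d ≤ 2 mm` for the rays to count as intersecting;
* **depth-median filter** — each point's ray depths must lie within
  ±2 mm of the *per-camera* median depth.

The per-camera choice (rather than one pooled median over both cameras'
depths) is deliberate: with an asymmetric rig the two cameras' depths to
the same pupil differ systematically by several millimetres, so a pooled
median would sit between the two populations and clip valid points on
both sides. Points with a negative ray depth in either camera are
removed before the medians are taken — the eye is always in front of
both cameras, so negative depths can only be detector failures, and
letting them enter the median would shift it.

A consequence worth knowing: the depth-median window also clips *valid*
points taken at extreme gaze angles, because the pupil genuinely moves
~1.8 mm in depth across a 25° gaze cone. In the simulated sessions about
a third of clean points fall to this filter. This costs sample size, not
correctness — the sphere fit is unbiased on the survivors — and it is
exactly what makes the filter effective against desynchronized captures.

## Sphere fit

The eyeball is a sphere `‖P − C‖ = r` with `r = 12 mm` fixed (the
anatomical average; re-estimating it from a small corneal cap is badly
conditioned, so the radius is never fitted — an override exists for
sensitivity analysis only). Two phases:

1. **Approximation.** Pupil points cover a small spherical cap, so they
   are nearly coplanar; the plane is tangent to the sphere. The centered
   point matrix's smallest right singular vector gives the plane normal
   `N`, and `C₀ = P̄ + r·N`. The sign of `N` is chosen toward larger
   depth: the cameras face the eye, so the center must be farther from
   them than the pupil points. The printed formula adds exactly `r`
   rather than `r` minus the cap's chord height; for a 15° cap the
   resulting bias is ≤ 0.41 mm along the axis, which the optimization
   phase absorbs (the initialization is only a starting point).
2. **Optimization.** A truncated M-estimator minimizes
   `Σ_P min(|‖P − C‖ − r|, δ)` over `C`, run twice: `δ = 1 mm` to pull
   the center through the initialization bias, then `δ = 0.5 mm` to
   sharpen it with outliers fully saturated. The objective is
   piecewise-smooth (kinks at the truncation boundary and at the sphere
   surface), so a derivative-free Nelder–Mead simplex search is used,
   parametrized by the *offset* from the current center so that the
   initial simplex scale does not depend on where the eye sits in the
   world frame. Each pass restarts the simplex up to five times (a
   restarted simplex recovers from premature shrinkage) and stops when
   the center moves less than 1 µm between restarts; each restart is
   capped at 500 iterations. Fits with fewer than 10 filtered points are
   refused — below that the SVD plane estimate is not trustworthy.

`fit_sphere_lsq()` provides the non-robust baseline (plain least squares
on surface deviations, no truncation, no filtering): on contaminated
synthetic sessions it is worse by two orders of magnitude, which is the
empirical justification for the robust machinery.

## Ray–sphere mapping

For an IR pixel with unit ray `v`, `α² − 2(v·C)α + (‖C‖² − r²) = 0`
selects the pupil point `P_w = αv`:

* two real roots → the **smaller positive** root: the near surface of
  the eyeball, the one facing the camera. If the smaller root were
  negative with the larger positive, the camera would be inside the
  sphere — reported as a broken model rather than silently mapped.
* negative discriminant (ray misses the sphere — detector noise or
  model drift) → `α = v·C`, the real part of the conjugate roots, i.e.
  the point of closest approach. These frames are flagged
  `approximated_complex` so consumers can weight or drop them; the
  mapping itself does not hide the approximation.
* a tangent ray is the measure-zero case of two equal roots and needs no
  separate branch.

The 3D gaze ray runs from `C` through `P_w` — the *optical axis* proxy
for gaze. The visual axis differs per person by the kappa angle, which
cannot be observed without a fixation procedure; modeling it is out of
scope, and reported angular errors are therefore optical-axis errors.

## Validation and self-supervision

Validation compares the mapped rectangle against occasional RGB detector
output. The model is invalidated after `n_consecutive = 10` successive
disagreeing frames (IoU < 0.5); frames without detector output neither
break nor extend a run — they carry no evidence either way. Ten frames
at the 1 Hz pairing cadence means a model surviving ten seconds of
contradiction is rebuilt; the threshold is configurable, and the module
itself is cadence-agnostic (a `validation_period` parameter controls how
often the RGB detector is invoked).

Self-supervision exports one candidate label per frame in which the RGB
detector fired: the rectangle mapped from the IR side, accepted exactly
when mapped and detected rectangles agree with IoU ≥ 0.5. Simulated
headset slips show why the depth direction matters most: a 3 mm lateral
slip degrades consensus IoU to ~0.65 (the sphere slides with the pupil
and the mapping partly self-corrects), while a 3 mm slip along the
camera axis collapses it below 0.1 and trips validation within the
10-frame window.

## The synthetic rig

`simulate_session()` emulates the capture conditions the pipeline is
designed for: 1280×960 sensors, eye center ~30 mm from the IR camera,
20 mm baseline with the RGB camera toed in toward the eye, 150 frames
per session at one usable pair per second, and a 25° half-angle gaze
cone about the camera-facing direction (a natural free-viewing range).
Detection noise is isotropic Gaussian on every reported coordinate with
σ = 1 px as the realistic default; rectangle-size jitter emerges from
the independent corner noise rather than a separate multiplicative term,
so the σ = 0 configuration is *exactly* consistent — a property the
exactness tests rely on. The focal length default (1000 px) makes the
pupil span ~200 px, the scale at which a close-up eye camera images a
2 mm-radius pupil; the rectangle corners are projections of true 3D
pupil-boundary points on the sphere, so corner triangulation is
geometrically faithful rather than cosmetic.

Failure injection: `outlier_rate` frames replace one camera's detection
with a uniform random in-image rectangle (detector failure);
`desync_rate` frames recompute one camera's detection from a second gaze
draw (the cameras caught different instants of a saccade). Timestamps
jitter within each one-second interval so the pairing logic is
exercised. One master seed drives every draw in a fixed order, making
sessions bit-reproducible.

What the simulator does **not** model — and what passing tests therefore
do not show: CNN detector error structure (real detectors fail in
correlated, illumination-dependent ways, not i.i.d. Gaussian), corneal
refraction, eyelid occlusion, photorealistic appearance, and kappa-angle
anatomy. The sub-degree gaze errors on synthetic data are a statement
about the *geometry pipeline*, not about end-to-end accuracy on real
recordings, where detector noise dominates and median errors in the
low single degrees are the realistic outcome.

## Problem sizes and numerical choices

The shipped tests and the acceptance script use 100–150-frame sessions,
20-seed recovery sweeps, 1000-case ray–sphere oracle comparisons at
1e-3 mm sampling, and 500-pair IoU rasterization checks — sizes at which
every geometric claim is exercised densely while a full run stays
comfortably interactive on one core. Other numerical choices: rotation
orthonormality is enforced at 1e-6; parallel-ray triangulation is
rejected below a cross-product norm of 1e-12; the SVD plane estimate
requires a second singular value above 1e-9 (collinear guard); medians
of even-length sets are the mean of the central pair; rates are stored
as exact fractions and converted to percentages only for reporting.

## Known limitations

* The optical-axis/visual-axis (kappa) discrepancy is not corrected.
* The eyeball is a single sphere: no separate corneal curvature, no
  aspheric model; the 12 mm radius is population-average, not per-user.
* Filtering assumes the eye is in front of both cameras and that the
  depth distribution of true pupil points is unimodal within ±2 mm.
* `approximated_complex` frames are flagged but not down-weighted by any
  built-in consumer; downstream users should decide their policy.
* The detector plug-in contract is synchronous and per-image; batch
  detectors need a thin adapter.
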