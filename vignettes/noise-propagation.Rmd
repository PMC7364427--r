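---
title: "Noise propagation in stereotactic localizer geometry"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Noise propagation in stereotactic localizer geometry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stereoloc)
```

## The problem

A stereotactic frame carries a fiducial localizer whose rods cross every
tomographic slice, leaving fiducial marks whose image coordinates encode
the slice's position in frame space. `stereoloc` models the recovery of
the section height z for two devices and asks a single quantitative
question: when image noise displaces the detected fiducial centers, how
large is the error in the reconstructed z, as a function of the section
height z, the section tilt β, and the noise amplitude ε?

## Geometric model and assumptions

The tomographic section is idealized as an infinitely thin plane (the
central plane of the slice) and each rod as its cylindrical axis, so a
rod–section intersection is a point. Fiducial detection from pixel data is
outside the model: the fiducial centers are taken as given, and noise is
injected directly into their coordinates. All lengths are millimetres and
all angles degrees at every public interface; pixel-size conversion of
measured distances is the caller's responsibility, which matters for the
Sturm-Pastyr device because its reconstruction is homogeneous of degree one
in the distances, while the N-localizer's dimensionless ratio cancels any
calibration factor.

The forward models place the three fiducials on the image u-axis. This is
one of infinitely many rigid placements of the triplet in the image plane;
since both reconstructions depend on the coordinates only through
inter-fiducial distances, any placement yields identical results, and the
collinear one makes the unperturbed configuration transparent (`v = 0`
everywhere, `d_AB + d_BC = d_AC` for the N-localizer).

Both inverse formulas are exact algebraic inverses of their forward
models: the package's property tests check the round trips to 1e-9
relative tolerance over the full valid pose domain, and this tolerance
reflects accumulated floating-point rounding only, not model error.

## Tunable parameters

* **N-localizer constants** (`n_localizer()`): rod height span
  `z_bottom = 0` to `z_top = 140` mm and `rod_spacing = 140` mm — the
  classical frame dimensions. Configurable because manufactured frames
  differ; all three enter only through the interpolation anchors.
* **Rod angle** (`sturm_pastyr()`): `upsilon = arctan(1/2)` = 26.565°, the
  manufactured angle of the classical V-shaped device.
* **Section pose**: height `z` ≥ 0 mm and tilt `beta` in degrees. Tilt is
  capped at 85° for the N-localizer (the 1/cos β stretch of the fiducial
  pattern diverges at 90°) and at 60° for the Sturm-Pastyr localizer,
  strictly below its geometric singularity at 90° − υ = 63.435° where the
  section becomes parallel to rod C and `d_BC` diverges. Hard caps make
  the failure explicit instead of returning astronomically magnified
  coordinates.
* **Noise half-width** `epsilon` (mm): each of the six fiducial
  coordinates is shifted independently by a uniform draw from [−ε, +ε].
  The default ε = 1 mm corresponds to a conservative two-pixel detection
  error at a typical stereotactic field of view (250–360 mm over 512
  pixels, i.e. 0.5–0.7 mm/pixel).
* **Iterations** `n`: default 2^25 per cell for final figures. The test
  suite and the acceptance script use 2^22 for the noise-amplitude fits
  and 2^20 per cell for tilt sweeps — sizes at which the Monte Carlo
  standard error of an RMS estimate is a few hundredths of a percent, so
  the reported slopes move only in the third decimal while a full sweep
  stays interactive on one CPU.

## What the noise model emulates — and what it does not

Uniform, independent, per-coordinate noise is the most literal model of a
fiducial-detection error bounded by a fixed number of pixels, and it is
applied to the v-coordinates as well as the u-coordinates: the distances
are recomputed with the full Pythagorean formula, so transverse noise
contributes the second-order (super-linear) error component that dominates
nowhere but is visible for the Sturm-Pastyr device at large ε. The model
does **not** emulate: correlated displacement of nearby fiducials (e.g.
patient motion or gantry miscalibration, which shift all fiducials
coherently), anisotropic or heavy-tailed detection error, rounding of
coordinates to the pixel grid, finite slice thickness, finite rod
diameter, or pixel-size miscalibration — the last of which affects the
Sturm-Pastyr reconstruction multiplicatively and the N-localizer not at
all. Passing tests therefore demonstrate the geometric noise sensitivity
of the two designs under idealized bounded white noise, not a clinical
end-to-end accuracy budget.

## Numerical choices

* **RNG and substreams.** All randomness flows through R's Mersenne-Twister.
  A cell's seed is derived from the master seed and the cell parameters by
  a 31-bit polynomial string hash (`cell_seed()`), so sweep cells can be
  recomputed independently, in any order, with identical results. Each
  iteration consumes six consecutive uniforms, which makes results
  invariant to the streaming `block_size`. Perturbations are generated as
  `runif(-1, 1) * epsilon`, so a fixed seed gives common random numbers
  across noise amplitudes — used by the monotonicity tests and available
  for paired comparisons between localizers.
* **Accumulation.** The sum of squared errors is combined across blocks
  with Kahan compensation; at n = 2^25 the plain running sum would already
  lose digits relative to the 1e-12 streaming-vs-batch agreement the RMS
  helper is tested to.
* **Apex convention.** `sturm_pastyr_z(0, 0)` returns 0: both distances
  vanish only at the apex of the V, where z = 0, and the 0/0 limit of the
  formula along any approach ray is 0.
* **Degenerate inputs.** Zero `d_AC`, negative distances, non-finite
  coordinates and out-of-domain poses raise errors; sweep grids skip
  invalid cells with a warning rather than dropping them silently.
* **Tie-breaking.** `find_beta_of_max_rms()` evaluates its grid in
  ascending order and returns the smallest angle among ties.
* **Maximum error** is max |z − ẑ| over the draws — the only reading of a
  "maximum error" consistent with the RMS definition. Unlike the RMS it is
  an extreme-value statistic: it grows slowly with n and is intrinsically
  noisier, which is why the error-scaling fit on maxima is held to a wider
  tolerance than the fit on RMS values.

## Design choices that were genuinely open

* **OLS with intercept** for the error-scaling fits (`linear_fit()`).
  "Least-squares fit" underdetermines the model; with-intercept is the
  standard reading, and on near-proportional data the choice moves the
  slope by under 2% (asserted as a test property).
* **Sweep grids.** The height sweep defaults to z = 5–140 mm in 5-mm steps
  at tilts {0, 5, 10, 15, 20}°; the tilt sweep to 0–60° in 1° steps at
  z = 20 mm. These are the natural grids for the ranges over which the
  two devices differ; nothing in the analysis depends on the exact
  spacing.
* **First-order cross-check.** `delta_method_rms()` linearizes the
  reconstruction in the six coordinates (central finite differences) and
  propagates the per-coordinate variance ε²/3. It is an independent check
  on the simulation engine, accurate where curvature is negligible. Near
  the Sturm-Pastyr apex the curvature of the distance and reconstruction
  formulas is no longer negligible even at ε = 0.25 mm: at z = 10 mm the
  simulated RMS exceeds the first-order prediction by a few percent (a
  deterministic bias, reproduced across seeds), so the agreement property
  is asserted at 3% only where the first-order regime actually holds, and
  the apex excess is asserted separately as a positive, bounded deviation.

## Known limitations

Only the z-coordinate is reconstructed; (x, y) recovery is a fixed-offset
lookup for both devices (vertical rods have constant x, y) and is out of
scope, as are fiducial detection, DICOM/NIfTI ingestion and frame
hardware. Monte Carlo point estimates carry no uncertainty bands; at the
default problem sizes their standard errors are far below every tolerance
used, but users pushing to very small n should expect visible scatter in
maximum-error statistics. The uniform-noise idealization above is the main
caveat when transferring conclusions to clinical images.
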