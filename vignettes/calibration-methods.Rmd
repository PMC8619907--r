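---
title: "Calibration methods for rotating underwater video landers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calibration methods for rotating underwater video landers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(uwcal)
```

`uwcal` calibrates the optics of unbaited rotating video landers — systems
that record six contiguous 60° frames per 360° rotation on the seabed — and
simulates their recording protocol. This vignette explains the models the
package implements, the choices made where the design was open, and what
the synthetic-data tests do and do not establish.

## Field of view from a grid span

With a flat grid target perpendicular to the optical axis at distance $D$
(cm), a physical span $dx_{cm}$ between two reference edges measuring
$dx_{pix}$ pixels on an image $N_x$ pixels wide gives the full horizontal
field of view

$$\theta = 2\arctan\!\left(\frac{N_x\,dx_{cm}}{2\,D\,dx_{pix}}\right).$$

The estimator assumes a central pinhole projection; because lens distortion
biases the measured span (a pincushion stretches the outer edges outward),
`calibrate_image()` fits and removes the distortion *before* measuring the
span. The reference edges are the outermost grid-line columns, and the span
is averaged over all grid rows.

## Flat-port refraction

An underwater housing with a flat window refracts each ray at the
water–window–air interface. Neglecting the window thickness (thin flat
port), Snell's law on the half-angle links the in-air and in-water fields
of view:

$$\sin(\theta_{air}/2) = n\,\sin(\theta_{water}/2).$$

The default refractive index is $n = 1.34$ (seawater). With it, an 82° lens
maps to 58.6° in water (reported as 59°) and a 60° in-water FOV maps to
84.1° in air (reported as 84°). These two printed conversions imply
slightly different effective indices once rounded; the package keeps a
single default and treats whole-degree agreement as the reporting
convention rather than forcing one $n$ to satisfy both exactly. Angles are
handled in radians internally and exposed in degrees; nothing is rounded
except in reports. `water_to_air_fov()` refuses angles past the total
internal reflection limit $n\sin(\theta/2) > 1$.

## Grid distortion

The distortion model is deliberately minimal — a single coefficient $d$
(pix⁻¹) acting on center-relative coordinates with $r=\sqrt{x^2+y^2}$:

* **radial** (default): $x' = x(1+dr),\; y' = y(1+dr)$ — radially
  symmetric, $d>0$ pincushion, $d<0$ barrel;
* **literal**: $x' = x+dr,\; y' = y+dr$ — the same scalar offset added to
  both coordinates.

The literal form is kept because the grid-transform formulation this model
descends from is written that way; it is not radially symmetric (a node on
the $y$ axis shifts horizontally), so only the radial variant reproduces
textbook barrel/pincushion geometry. Both are linear in $d$, so
`fit_distortion()` is closed-form ordinary least squares through the
origin, stacking both coordinates of all nodes; no robust loss is applied.
The distortion center is fixed at the image center and not refined —
appropriate for the small coefficients (|d| of order 10⁻⁴) this class of
housing exhibits, where center misestimation is second-order.

Inversion is closed-form for the radial variant (the positive root of
$d r^2 + r - r_{obs} = 0$, applied as a scale $2/(1+\sqrt{1+4dr_{obs}})$)
and a fixed-point iteration for the literal one (tolerance $10^{-9}$ px,
cap 50 iterations). The inversion is well posed while $|d|\,r < 0.5$ across
the frame — three orders of magnitude above realistic coefficients.
`undistort_image()` resamples by inverse mapping with bilinear
interpolation; out-of-frame samples take a fill value, which is why a
corrected pincushion frame shows filled corners (slightly non-square usable
FOV).

## Colour attenuation

Water absorbs long wavelengths first, so the red channel of a chart patch
decays fastest with capture distance. The package models each channel as
single-path Beer–Lambert decay over the camera-to-target distance,
$v = v_{ref}\,e^{-k_c D}$, and fits $k_c$ (m⁻¹) as the least-squares slope
through the origin of $-\log(v/v_{ref})$ against $D$, pooled over patches.
Through-origin is the model-consistent choice: at $D=0$ the ratio is 1 by
construction. Measured values at or below 5 (0–255 scale) are excluded
before the log transform — near-black channels are dominated by noise and
quantization and would otherwise dominate the fit. A channel with no usable
observations is flagged unfittable rather than forced.

Patch colour is measured as the mean over the central 50% (by area) of each
patch box, a reproducible replacement for manual single-pixel colour
picking.

## The synthetic scene generator

`render_scene()` emulates a controlled-pool calibration shot: a black grid
on a light background plus a six-patch colour chart, pinhole-projected at
the capture distance, warped by the scene's distortion, attenuated per
channel, and degraded with seeded additive Gaussian pixel noise. Rendering
evaluates the target plane analytically at each output pixel's undistorted
position, with a one-pixel anti-aliasing ramp, so sub-pixel node
localization against ground truth is meaningful. Key generator choices:

* **Distance series 1–6 m** with the target scaled to fill ~60% of the
  frame width at each distance, mirroring the practice of printing several
  pattern sizes; this keeps the grid's pixel geometry comparable across
  distances.
* **7 × 9 grid, default d = 1.3·10⁻⁴ pix⁻¹ (moderate pincushion), noise
  sd 1** as the baseline condition; recovery tests run at noise sd 2.
* **Attenuation defaults (k_r, k_g, k_b) = (0.6, 0.15, 0.08) m⁻¹**, a
  seawater-like ordering (red ≫ green > blue) of plausible coastal
  magnitude. The exponential form is the generator's declaration, not an
  empirical claim.
* **Grid lines overhang the outer nodes by a quarter pitch** so edge nodes
  sit on full crossings; otherwise their centroid refinement would be
  biased toward the grid interior.
* Chart reference values are arbitrary but span all channels so the three
  coefficients are identifiable.

The generator does **not** model turbidity or scattering, vignetting,
depth-of-field blur, compression artefacts, or non-Gaussian sensor noise.
Passing recovery tests therefore establishes the correctness and numerical
behaviour of the estimators — not their field performance on real footage,
where detection robustness and colour constancy face conditions the
renderer never produces.

## Node detection and matching

`detect_nodes()` computes, per orientation, the mean darkness of a strip
centred on each pixel minus the darker of two flanking strips; the
pointwise minimum of the two orientation responses peaks only where two
lines cross. Using the *darker* flank (rather than the mean) suppresses
half-plane features such as colour patches and their corners. After
non-maximum suppression, nodes are refined by separable centroids of the
baseline-subtracted darkness profile in a ±9 px window; on noiseless
renders this is exact to machine precision, and under noise sd 2 the mean
localization error stays well below half a pixel. Defaults (strip ±4 px,
smoothing ±6 px, flanks at ±12 px, 20 px minimum separation) suit grids
whose pitch projects to ≳40 px and lines to ~3–8 px; they are exposed as
arguments for other geometries. Matching to the projected ideal grid is by
mutual nearest neighbour after centroid alignment, with unmatched nodes
dropped (failure below 50% matched).

## Recorder protocol simulation

The recorder's life cycle is a five-state machine — STARTING, READY,
WORKING, STANDBY, SHUTDOWN — driven by boot completion, magnet swipes on
the start/stop reed switch, dwell-timer ticks (legal only while WORKING),
and a shutdown swipe (legal only from STANDBY, where the metadata CSV is
flushed). Any other pair is a protocol error; safety (no shutdown without
standby) is verified by exhaustive enumeration of event strings up to
length 6. One observation is `n_rotations × frames_per_rotation` dwell
periods — 180 s per rotation and 540 s per three-rotation observation with
the 60°/30 s defaults. The Maltese-cross indexing makes orientation a pure
function of the step count (`rotation_index()`). Metadata (pressure in
dbar, temperature in °C, ISO-8601 UTC timestamps) is sampled every 10 s
from recording start to end inclusive, from a pluggable constant, ramp or
seeded-random sensor source; the motor-alignment delay on entering WORKING
is a configurable constant defaulting to 0 s since its real duration is
small and unspecified.

## Problem sizes and numerical choices

The test suite renders at two formats: a reduced 800 × 600 build of the
same optics for unit tests, and the full 1600 × 1200 (UXGA) format for
end-to-end checks — 50 seeded replicates cycling the 1–6 m distances at
noise sd 2 for parameter recovery, with attenuation fitted per complete
six-distance series. `scripts/acceptance.R` repeats the recovery on two
full series (12 scenes) plus the closed-form identities and FSM
enumeration. Distances are treated as exact (they are tape-measured in the
emulated procedure); no distance-uncertainty model is fitted. Least-squares
fits are unweighted; outlier handling is left to the caller, matching the
simplicity of the fitted models. Degenerate inputs (all nodes at the
center, single-column grids, blank images, channels below the measurement
floor) raise informative errors rather than returning numbers.

## Known limitations

* The two printed refraction conversions cannot both be matched exactly by
  one refractive index; whole-degree reporting absorbs the difference.
* The single-coefficient model cannot represent mixed (mustache)
  distortion or tangential components; it is intended for the mild,
  monotone distortions of flat-port housings.
* Attenuation coefficients estimated from synthetic scenes inherit the
  generator's idealized Beer–Lambert assumption; on real footage they
  additionally absorb sensor response and white-balance effects, so they
  characterize a camera–water combination, not the water alone.
* Node detection assumes a roughly axis-aligned grid; strong rotation of
  the target would require re-tuning the strip/flank geometry.
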