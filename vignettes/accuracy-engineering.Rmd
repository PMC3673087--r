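---
title: "Engineering image accuracy for crop/weed detection: camera arrangement and illumination control"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Engineering image accuracy for crop/weed detection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(agrocam)
```

## The problem

A tractor-mounted RGB camera observes maize rows ahead of the vehicle to
locate crop lines and weed patches for site-specific treatment. Two groups of
factors limit how accurately greenness can be segmented from such images:

1. **Geometry.** The extrinsic parameters — pitch angle $\alpha$ (measured
   from the horizontal, $\alpha = 90^\circ$ being nadir), camera height $h$,
   and the horizontal distance $d$ to the ground region of interest (ROI) —
   determine onto how many pixels a fixed ground area projects. That pixel
   count $n$ is the accuracy proxy: fewer pixels per square metre means
   coarser weed maps.
2. **Illumination.** Outdoor light is uncontrolled. An under- or over-excited
   sensor, and the radial red attenuation that a UV/IR cut filter induces
   toward the image corners (vignetting), both degrade colour-based
   segmentation.

`agrocam` implements both machineries: a pinhole arrangement simulator with a
bundled table of 125 field measurements of $n(\alpha, h, d)$, and an
illumination-control pipeline (white-panel exposure feedback, vignetting
correction, fuzzy-clustering greenness segmentation, PCC scoring), exercised
end to end on a synthetic field-scene renderer with exact ground truth.

## The camera model and its conventions

The reference sensor is a 2336 × 1752 CCD with 5.5 µm square pixels behind a
10 mm lens. World frame: origin on the ground directly beneath the camera,
$X$ forward, $Y$ left, $Z$ up; the camera sits at height $h$. Conventions the
source material leaves open, fixed here once and documented:

* **Pitch reference.** $\alpha$ is measured from the horizontal, so
  $\alpha = 90^\circ$ points straight down. Some conventions measure from the
  vertical; all angles in this package are from the horizontal.
* **Rotation composition.** Yaw about world $Z$, then pitch about the camera
  $x$ axis, then roll about the optical axis (world-to-camera). Roll and yaw
  are zero throughout the study (flat terrain, correct guidance), which makes
  the composition order unobservable in scope; it is fixed for
  reproducibility.
* **Distance referent.** $d$ runs horizontally from the camera's vertical
  ground projection to the **near edge** of the ROI, which is centred
  laterally. This keeps $d$ independent of $\alpha$.
* **Pixel coordinates.** Origin at the image top-left, $u$ rightward, $v$
  downward, half-open bounds $[0, W) \times [0, H)$; pixel $(i, j)$ covers
  the unit square with centre $(i + 0.5,\, j + 0.5)$. Projected areas are
  continuous (shoelace formula, no rounding); a rasterized integer count
  exists in the tests as an independent oracle.
* **Sensor clipping.** `quadPixelArea(..., clip_to_sensor = TRUE)` clips the
  polygon with Sutherland–Hodgman before the shoelace sum.
  `sweepArrangements()` reports the pure analytic trapezoid area by default,
  matching the procedure the simulator re-implements (project the four ROI
  corners, take the area of the trapezoid), and flags off-sensor corners
  rather than discarding them.
* **No lens distortion.** The simulator is pure pinhole; distortion
  calibration is out of scope.

## What the simulator does and does not reproduce

Over the study grid ($\alpha \in \{10..50\}^\circ$, $h \in \{210..230\}$ cm,
$d \in \{3..5\}$ m), the simulated areas reproduce the qualitative structure
of the bundled measured table:

* $n$ strictly decreases with $d$ at every fixed $(\alpha, h)$, and the
  global maximum sits at $d = 3$ m;
* at $d = 3$ m, $\alpha = 30^\circ$ is the worst pitch for every height: the
  ROI then sits at the image centre, where a pinhole camera spends the fewest
  pixels per steradian ($\propto 1/\cos^3\psi$ in the off-axis angle
  $\psi$), while at $10^\circ$ and $50^\circ$ it falls near the image border;
* the Pearson correlation between the 125 simulated areas and the measured
  counts is 0.96 (the acceptance script recomputes it).

One measured trend is **not** reproduced, and we believe cannot be by any
pure pinhole model under the conventions above: the measured counts grow
with $h$ in *every* column, while the simulated area decreases slightly with
$h$ at steep pitch ($\alpha = 40^\circ$, $d = 3$ m and $\alpha = 50^\circ$,
$d \le 4.5$ m). Raising the camera at steep pitch moves the ROI toward the
image centre, and the $1/\cos^3\psi$ pixels-per-steradian factor then shrinks
faster than the subtended solid angle grows. The measured table is itself not
fully consistent with the stated optics — at $\alpha = 50^\circ$, $d = 5$ m
the ground patch lies outside the nominal vertical field of view, yet a count
is reported — so we attribute the discrepancy to unmodelled field effects
(lens distortion at the image periphery, imprecise distance/pitch referents,
cardboard placement). The corresponding check in `test-acceptance.R` asserts
the height trend as stated and is expected to fail at those five grid
columns; we prefer that visible disagreement to silently weakening the test.

A printed aggregate agreement statistic for the original simulation exists
but does not define its numerator and denominator, so it is not reproducible;
the package reports correlation and relative errors instead.

## Exposure-time control

A four-colour panel lies in the field of view; the white quadrant is the
reference. Each capture computes the channel means $\bar R, \bar G, \bar B$
over the panel and $H = \max\{\bar R, \bar G, \bar B\}$. With saturation
$M = 255$ and band fractions $a = 0.90$, $b = 0.98$:

* $H < aM$: exposure is raised, $E_t \leftarrow (1 + p)E_t$;
* $H > bM$: lowered, $E_t \leftarrow (1 - p)E_t$;
* otherwise kept, and the loop stops.

with $p = 0.20$. The update inequalities are applied verbatim; note they keep
$H = bM$ although the target interval is stated half-open — the boundary case
is resolved in favour of the update rule. Because one band width
($0.98/0.90 \approx 1.089$) is smaller than the step factor $1.2$, a static
scene can straddle the band for several iterations; the loop therefore
carries a `max_iter` cap (default 10) and a `converged` flag instead of
assuming termination. The panel region is supplied explicitly (rectangle or
mask); the original setup knows the panel position by construction but gives
no coordinates.

## Vignetting correction

The correction pattern $P$ is the distance of each pixel from the pattern
centre $(c_x, c_y)$ normalised by the largest corner distance — the only
normalisation that satisfies both stated boundary conditions ($P = 0$ at the
centre, $P = 1$ at the corners). Channels are corrected multiplicatively,

$$R_c = (1 + K_r P) R, \quad G_c = (1 + K_g P) G, \quad B_c = (1 + K_b P) B,$$

with defaults $K_r = 0.3$, $K_g = K_b = 0$: only red is restored, because the
cut filter attenuates red toward the periphery and shifts colours toward
green/blue exactly where greenness segmentation is most fragile. Numerical
choices: integer images are corrected in floating point and rounded half-up
(half-to-even would bias integer image maths); results are clamped to
$[0, M]$ and clamping events are counted on the returned attribute;
zero-gain channels are returned bit-identical.

The synthetic sensor applies vignetting *forward* as division by
$(1 + K_r P)$, so the correction above is its exact inverse; a corrected
render matches an attenuation-free render within ±1 level wherever no
clipping occurred (rounding forward and back can cost one level, never two).

## Greenness segmentation

The global threshold comes from two-class fuzzy C-means on RGB samples
(default 2,000 pixels, uniform without replacement, seeded). Internals of the
clustering strategy are not prescribed by the source material, so the minimal
standard method is used: $k = 2$, fuzziness $m = 2$, tolerance $10^{-4}$ on
centre movement, 300-iteration cap, centres initialised deterministically
from the per-channel 25 % and 75 % sample quantiles. The centre with the
larger green chromatic coordinate $g = G/(R+G+B)$ is the vegetation class,
and the threshold is the green fraction of that centre,
$t = G_v/(R_v + G_v + B_v)$. A pixel is vegetation iff $g > t$ strictly; ties
are background (fixed convention), and zero-sum pixels are background. The
hand-written optimiser is cross-checked against `e1071::cmeans` in the test
suite; the library is never the implementation.

The bright-orange cardboard used for pixel counting has no numeric colour
definition in the source material; the default bounds are hue
15°–40° with saturation ≥ 0.5 and value ≥ 0.5, overridable, with an optional
largest-connected-component filter (via EBImage).

## Scoring and the 2 × 2 experiment

Masks are scored with the percentage of correct classification,
$\mathrm{PCC} = (TW + TB)/(TW + TB + FW + FB)$, after removing the top third
of the rows (`floor(H/3)`, rounding unspecified in the source material) —
that part of the frame is outside the treated area. In the packaged
experiment the threshold is also *learned* from the cropped region: the top
of the frame contains sky and far field, which would contaminate a two-class
colour clustering that is only meant to separate vegetation from soil.

`simulateConditionGrid()` renders pairs of captures of the same scene — one
deliberately under-exposed at $8 \times 10^3$ µs, one at the exposure the
closed loop selects (the loop typically lands near $3.4 \times 10^4$ µs,
consistent with a full-scale reference of $3.5 \times 10^4$ µs) — and scores
the four conditions (exposure adjusted? × vignetting corrected?) against the
renderer's exact vegetation truth. Ground truth is the renderer's own mask;
the original protocol builds it by expert retouching, which is not
reproducible in software. The absolute PCC levels of the original field
study depend on its 25 undeposited image pairs and are explicitly not
reproduced; the package reproduces the *ordering* — no corrections <
vignetting only, and no corrections < exposure only < both — which emerges
robustly across seeds.

## What the synthetic scenes emulate, and what they do not

The renderer casts one ray per pixel against the flat ground plane
($z = 0$), so geometry and truth masks are exact: crop rows 0.75 m apart
(as in maize), seeded elliptical weed blobs between rows at a target ground
coverage, optional 1 × 1 m orange cardboard and four-colour panel, sky above
the horizon. The sensor model is linear in exposure with additive Gaussian
read noise (sd 2 levels), rounding and clipping.

Default class colours are soil (120, 95, 70), crop (60, 140, 55), weed
(70, 150, 60), cardboard (240, 120, 30). Perfectly flat class colours would
make the segmentation task degenerate — classes separable at any exposure,
corrections changing nothing — so each class carries a seeded per-pixel
reflectance texture (`colorJitterSd`, default 20 levels per channel), a
realistic stand-in for the within-class spectral spread of soil and canopy.
This value was fixed when the generator was designed and is not tuned per
experiment.

Not modelled: real reflectance spectra, shadows and specularities, 3-D
canopy structure and occlusion, motion blur from tractor oscillation, lens
distortion. Passing tests therefore demonstrate that the pipeline's
machinery is correct and that the corrections help under the modelled
degradations; they do not certify absolute accuracy on real field imagery.

## Problem sizes and determinism

The packaged experiments render 320 × 240 frames (same field of view as the
full sensor, scaled pixel pitch) and use 10 scene pairs and 2,000-pixel
segmentation samples; these sizes give stable orderings while keeping the
whole suite quick to run. Every stochastic component — weed layout,
reflectance texture, read noise, feature sampling — draws from an explicit
seed through an RNG-state-preserving helper, so identical configurations
and seeds give bit-identical frames, tables and reports.

## Known limitations

* The height trend of the measured arrangement table at steep pitch is not
  reproduced (see above); the simulator is a lower-fidelity pinhole twin,
  not a re-fit of the field data.
* The exposure loop assumes a static scene between captures; on a moving
  tractor the white-panel statistics would also carry motion noise.
* Fuzzy C-means with two clusters assumes the (cropped) image is dominated
  by exactly two colour populations; scenes with a third dominant population
  (standing water, plastic mulch) would need a third cluster or masking.
* The BMP codec is deliberately minimal: uncompressed 24-bit only.
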