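---
title: "Dual-view fish morphometry: models, design choices and limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dual-view fish morphometry: models, design choices and limitations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fishmetry)
```

## The measurement model

A fish photographed in water rarely lies straight or parallel to either
camera. `fishmetry` measures seven traits from two orthogonal
orthographic views — lateral ("side", image axes: longitudinal x,
vertical y) and dorsal ("top", longitudinal x, lateral y) — of the same
specimen, each annotated with a fixed landmark skeleton (10 side-view,
9 top-view points) and calibrated independently with a ruler.

Three traits are planar: body height, body thickness and tail-handle
height are single landmark-pair distances in one view times that view's
cm-per-pixel scale. They assume the landmark pair is parallel to the
image plane, which holds when the fish is upright (height pairs) or
seen from above (thickness pair) — the same assumption a hand-held
calliper measurement makes.

The remaining four traits run along the body and must be corrected for
curvature. The core primitive is the dual-view length reconstruction:
for a segment with side-view projected length $L$, side-view direction
cosine $\cos\alpha$ and top-view direction cosine $\cos\beta$ (both
against the shared longitudinal axis),

$$|OA| = \sqrt{\left(\frac{L\cos\alpha}{\cos\beta}\right)^2 +
               \left(L\sin\alpha\right)^2}.$$

The horizontal run recovered in the side view, $L\cos\alpha$, is
divided by $\cos\beta$ because the top view reveals how much of the
segment points away from the side-view plane; the vertical rise
$L\sin\alpha$ is seen at true length. For a segment with exactly
measured projections this is an identity, which is how we test it: for
1000 randomly oriented 3D segments, computing both cosines from exact
projections and applying the formula recovers the true length to
numerical precision (the test asserts 1e-9 relative).

Direction cosines are taken as absolute values ($|dx|/|v|$). Only
$\cos^2$ and $\sin^2$ survive in the reconstruction, so the sign
carries no information, and dropping it makes every length independent
of whether a vector is written head-ward or tail-ward. Scalar
projections are likewise returned as magnitudes, because the full
length chooses the *shorter* of the two caudal-fin lobes by comparing
projected lengths; a signed comparison would misorder a
backward-pointing lobe.

Body length decomposes the fish into a head chord (mouth to
head-middle) plus the mid-body (head-middle → small-middle →
caudal-fin base, summed in the side view), the latter distributed over
the three top-view body segments in proportion to their apparent
top-view lengths and reconstructed per segment with a single side-view
chord cosine. Using one side cosine for all three mid-body terms (the
small-middle → head-middle chord) is a fidelity choice: a per-segment
side cosine variant might track strongly S-shaped fish better, but the
single-chord form is the published procedure and the one our
measurements must reproduce. Full length adds the tail term; ties
between the two lobes' projections resolve deterministically to the
upper lobe (the result can differ between equal-projection lobes only
through their cosines, and a deterministic rule keeps runs
reproducible).

Degenerate geometry is refused rather than patched: a zero-length axis
vector or a top-view cosine below $10^{-6}$ (segment nearly
perpendicular to the longitudinal axis in the top view, where the
$1/\cos\beta$ correction blows up) raises an error naming the failing
measurement. No pixel coordinate is ever rounded; sub-pixel annotation
positions pass through untouched.

## Calibration

Each camera is calibrated from one ruler: scale = true length / pixel
length, in cm per pixel, per view (the two cameras differ in distance
and optics, so no scale is shared). The package does not model lens
distortion or refraction at the water/box interface; a ruler placed at
a different depth than the fish biases the scale multiplicatively, and
that bias propagates linearly into every trait.

## Annotation handling

All 19 landmarks are mandatory. Every trait formula consumes specific
named points, and there is no principled way to measure around a
missing one, so partial specimens are rejected with per-landmark
findings instead of silently imputed. The canonical orientation is
head-left; annotations with the head on the right are mirrored on load
with a warning, because a mirrored skeleton is unambiguous to repair.
The annotation JSON schema is versioned and serialises coordinates at
17 significant digits so write→read round-trips are bit-exact.

## The synthetic generator

The generator is the package's validation instrument: it produces 3D
specimens whose ground-truth phenotypes are known exactly, projects
them orthographically into the two views, and optionally adds Gaussian
annotation noise (modelling human labelling and detector error).

The body centreline is piecewise linear: a head segment with free 3D
direction, two mid-body segments meeting at the caudal peduncle, and a
tail segment. Two structural constraints are imposed by construction:

* all mid-body and tail bending happens in the horizontal (top-view)
  plane, with one shared side-view inclination, and
* the two mid-body segments share one bend *magnitude* (signs free, so
  S-curves are included).

These are exactly the conditions under which the measurement
decomposition above is exact — the three top-view polyline segments
then share one direction cosine, and the proportional distribution of
the side-view mid-body length reproduces each 3D segment length. We
derived this equal-cosine condition analytically and use it
deliberately: ground truth is *defined* by the same segment
decomposition applied to exact 3D coordinates, so the noiseless
round-trip test (generate → project → measure, 100 seeded specimens,
max relative error below 1e-6; observed ~1e-15) isolates implementation
error from the decomposition's own approximation error on arbitrary
shapes. An out-of-plane bend is available behind the
`vertical_bend_deg` flag; it breaks the shared side-view inclination,
and a test documents that the measurement then deviates from truth by a
small but genuine amount (order 1% at 25°). Consequently, a passing
test suite shows the pipeline is faithful to the published procedure —
not that the procedure itself is exact for fish bending out of the
horizontal plane, which it is not.

Default parameters describe a market-size channel catfish
(~14 cm total length: 3.2 cm head chord, 7.0 cm mid-body, 1.1 cm
peduncle, 2.9 cm tail, 2.4 cm body height, 2.1 cm thickness);
`random_fish_params(seed)` draws cohort-like variation (total length
roughly 11–17 cm, bends up to 40°, poses tilted up to ~8° in pitch and
20° in yaw). Randomness is confined to that one seeded function —
`generate_fish(params)` itself is deterministic, which keeps parameter
draws, geometry construction and noise injection independently
reproducible; annotation noise takes its own seed in
`perturb_specimen()`.

The rasteriser fills the body outline polygon through the silhouette
landmarks (dilated 15% so landmarks are strictly interior, with small
disks stamped at each landmark where the outline pinches — fin tips,
caudal fork) over a noisy background. It emulates only what the
detector needs — a shaped, textured foreground whose geometry encodes
the keypoints. It does not emulate photographic nuisance factors
(water, reflections, texture, occlusion), so detector results on these
images say nothing about accuracy on real photographs.

## The keypoint detector

The detector is a stacked-hourglass heatmap regressor: a stem pools the
input to heatmap resolution, then `num_stacks` (default 2) hourglass
modules of order 4 — symmetric encoder–decoders with a skip branch at
every scale — each emit per-keypoint heatmaps trained against Gaussian
targets (peak 1, σ = 1.5 heatmap pixels) under a summed MSE loss with
intermediate supervision, optimised full-batch with Adam at learning
rate 1e-3. Decoding is per-map argmax times the upscale factor, ties
to the lowest row-major index; argmax (rather than sub-pixel
refinement) is the default because the resulting quantisation error of
at most half the upscale factor per axis is an explicit, analysable
term in the error budget. Sub-pixel decoding is deliberately left out
of scope for v1.

Because no deep-learning framework is available to R here, the network
is implemented natively: im2col convolutions as BLAS matrix products
with hand-written backward passes, verified against finite differences
in the test suite. The working configuration is desk-scale — 64×64
inputs, 16×16 heatmaps (upscale ×4), 8 channels — chosen so the
characterisation run (20 rasterised synthetic side views, 400 Adam
steps) finishes in about a minute on one CPU while still demonstrating
real learning: the loss falls to ~2% of its initial value and every
training keypoint is recovered within 2× the upscale factor. This is
an overfit sanity protocol, not a generalisation claim; one model is
trained per view, and the architecture accepts larger resolutions if
compute allows (the input/heatmap ratio must stay a power of two, and
the heatmap must be divisible by $2^{\text{order}}$).

## Error metrics and the bundled reference data

RMSE, MAE and MRE are computed per trait over paired
(automated, manual) values, with the across-trait "Average" row the
unweighted mean of the seven per-trait values (verified: the mean of
the seven MAE values reproduces the published average exactly). The
bundled dataset — 20 channel catfish measured manually and by the
automated pipeline — ships as plain CSV; the regression test
recomputes all 24 statistics and compares each at its printed decimal
count using round-half-even. MRE requires strictly positive manual
values and the report refuses mismatched specimen ids rather than
pairing by position when ids are present.

## Numerical choices, in one place

* Top-view cosine guard: $|\cos\beta| \ge 10^{-6}$, else a
  near-perpendicular-view error.
* Tie-break in the tail-lobe minimum: upper lobe.
* Heatmap argmax tie-break: lowest row-major index.
* Annotation JSON: 17 significant digits (bit-exact round trip).
* Measurement CSV: 3 decimals by default (the precision of the manual
  reference data), configurable.
* No rounding inside any geometric computation.

## Problem sizes used in validation

Property tests use 1000 random 3D segments for the reconstruction
oracle, 100 seeded random specimens for noiseless end-to-end recovery,
200 paired replicates per noise level (σ ∈ {0, 1, 2, 4} px) for the
noise-response check, and the 20-image/400-step detector run described
above. These sizes were chosen as the smallest that exercise each
property convincingly; all are set in code, not tuned to outcomes.

## Known limitations

* Refraction and lens distortion are unmodelled; calibrate with the
  ruler at the specimen's depth.
* The body-length decomposition uses a single side-view chord cosine
  for the mid-body and is exact only for horizontal-plane curvature.
* Partial or occluded skeletons are rejected, not imputed.
* The detector's accuracy is characterised on synthetic silhouettes
  only; no claim transfers to real photographs.
* The landmark set is fixed to this two-view skeleton; other species
  or view geometries would need a new label set (the data model keeps
  labels as row names precisely to make that extension mechanical).
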