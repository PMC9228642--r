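---
title: "tabletrace: measurement model, design choices and limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{tabletrace: measurement model, design choices and limitations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the science it implements:
what is being measured, under which assumptions, which parameters matter,
what the synthetic generator does and does not emulate, and where the design
was genuinely open.

## 1. The measurement model

A tablet immersed in dyed medium is photographed from above at fixed
intervals (canonically 31 frames, one per minute). Three concentric fronts
are defined relative to the tablet's **initial border** — the
tablet/medium transition in frame 0:

* **wetting** (liquid penetration): the dye stains tablet matter from the
  border inward; the penetration distance is the initial radius minus the
  innermost stained/unstained transition radius;
* **gel**: hydrated polymer forms a translucent halo *outside* the initial
  border; gel thickness is the outer halo radius minus the initial radius;
* **erosion**: the outer boundary of solid matter recedes *inside* the
  initial border; erosion distance is the initial radius minus the current
  matter radius.

Each process is treated as linear in time over the 30-minute window, so a
rate (mm/min) is the ordinary least-squares slope of the aggregated
distance-versus-time series. This linearity is an assumption inherited from
the experimental design, not a physical law; the package deliberately does
not offer square-root-of-time (Washburn-type) wetting models.

The instrument magnification is irrelevant to the software: all distances
are calibrated through a user-supplied `pixel_size` (mm/px). (The source
experiment reports inconsistent magnifications, which is precisely why
calibration must come from the pixel size.)

## 2. Segmentation design

The experiment gives no segmentation rule, so the package states one.

* **Blueness index** `b = (B − (R+G)/2 + 1)/2 ∈ [0, 1]`. The dyed medium is
  the bluest thing in the scene; undyed tablet matter the least blue.
* **Dye threshold**: Otsu's threshold computed once on frame 0 (medium vs
  tablet) and held fixed for the whole stack. A per-frame threshold would
  drift as the tablet stains; a fixed one cannot.
* **Mediumness index**: Euclidean RGB distance to the median medium color
  of frame 0, normalized by √3. This separates "any kind of matter or gel"
  from "pure medium" regardless of staining.
* **Gel threshold**: 25% of the frame-0 tablet-interior mediumness. The gel
  halo is a partial blend of matter over medium, so it sits well above this
  level while medium noise stays below it.
* **Erosion (matter) threshold**: 15% of the same reference. It must sit
  *below* the mediumness of heavily dye-stained matter (which is itself a
  blend toward the medium color), hence lower than the gel threshold.

Thresholds crossing an anti-aliased edge at a level other than the ramp
midpoint bias the crossing radius by a constant sub-pixel amount. Because
every trace is re-zeroed per ray against its own frame-0 measurement (see
below), these constant biases cancel in the slope; they only shift the
intercept, which is reported but not interpreted.

* **Radial sampling**: 360 rays from the foreground centroid, profiles
  sampled every 0.5 px with bilinear interpolation, crossings located by
  linear interpolation across the threshold. The original measurement drew
  a single line per image; the ray-median is its rotation-invariant
  generalization, and 360 rays make the median essentially insensitive to
  any single artifact.
* **Search domains**: gel is searched only outward of the initial radius,
  erosion only inward. This makes the two unambiguous even on rays where a
  halo surrounds a receding core.
* **Occlusion**: a ray in a frame is excluded from the median when its
  profile crosses the threshold more than once in the direction that
  defines the boundary (a bubble splits the profile), or when a detected
  bright blob (a connected bright component not containing the tablet
  center) overlaps the crossing within ±3 px. CO₂ bubbles are the dominant
  artifact in effervescent formulations; the exclusion rule is ours, since
  the source experiment never states one.
* **Aggregation**: per-frame distance = median over usable rays; a frame
  with fewer than 50% usable rays reports NA ("front not measurable") —
  the same rule is used to flag gel traces of fast-eroding formulations
  whose halo cannot be measured.

### Zero baseline and saturation

Distances are defined relative to the frame-0 border *as measured by the
same estimator*: the per-ray frame-0 value is subtracted, then negatives
are floored at 0. This makes the t = 0 distance exactly zero (an invariant)
and cancels constant threshold biases.

A wetting front can traverse the whole radius before the stack ends (the
fastest published rate crosses a 6.35 mm radius in ~4.4 min). Rays stained
all the way to the center are flagged *saturated* (NA), and once most rays
saturate the frame aggregate is NA; the rate regression then uses only the
pre-saturation frames. This is the only reading under which a 31-frame
stack of a fast-wetting tablet yields the published rate: the alternative
(regressing through a plateau at the radius) would report a meaningless
smaller slope.

## 3. Rates

* OLS with a **free intercept**; the slope alone is the rate. With ideal
  data the intercept is ≈ 0; with real data it absorbs lag and sub-pixel
  offsets.
* Replicates: one slope per replicate, then mean ± sample SD (n − 1) over
  replicates — matching the "n = 5 per formulation" design — rather than
  pooling all points into one regression.
* Rates are not floored at zero: a small negative slope on a noisy null
  series is reported as-is and rounds to 0.000 at the 3-decimal report
  precision.

## 4. Dissolution kinetics

The release models and information criteria follow the unweighted DDSolver
conventions (the source experiment names the software but not the
formulas):

* `KP_F0`: `F(t) = F0 + K_KP·tⁿ`, `F0 ∈ [0, 100]`, `K_KP ≥ 0`, `n ∈ (0, 2]`;
* `PS`: `F(t) = k1·tᵐ + k2·t²ᵐ`, `k1, k2` unbounded (published tables
  contain negative values), `m ∈ (0, 1]`;
* `WSS = Σ(F_obs − F_pred)²`, `R² = 1 − WSS/SST`,
  `AIC = N·ln(WSS) + 2p`, `MSC = ln(SST/WSS) − 2p/N`, all weights 1;
* `p = 3` for both models (F0 counts as fitted even when it converges
  to 0);
* `t = 0` points are excluded from fitting (`tⁿ` has an undefined
  derivative at 0 for fractional exponents);
* a perfect fit (`WSS = 0`) reports sentinel `AIC = −∞`, `MSC = +∞`.

**Optimizer.** Both models are linear in two of their three parameters once
the exponent is fixed. `fit_model()` therefore profiles the exponent:
a fixed grid (step 0.1 over the exponent's range) with an exact —
constrained, for `KP_F0` — linear solve at each point, deterministic 1-D
refinement (`optimize`, tolerance 1e-10) around the best grid point, then a
box-constrained quasi-Newton polish of all three parameters. The result is
deterministic, needs no random restarts, and recovers noiseless parameters
to ~1e-6. The test suite checks it against an independent brute-force
oracle: an exhaustive 1e-3 grid over the exponent with `lm()` solves — the
exponent is the only non-convex direction, so that grid is an exhaustive
search of the parameter box up to exact linear algebra.

**Model selection** takes the majority of the three criteria. For equal `p`
and `N` all three are monotone transforms of WSS, so they always agree; the
disagreement branch (lowest AIC wins, flagged) is reachable only for
unequal parameter counts.

**A boundary-value subtlety.** The published plain-drug Peppas–Sahlin row
evaluates to F(0.25 h) = −0.03%: the fitted curve dips marginally below
zero at early times. A container that rigidly enforced F ∈ [0, 100] could
not represent noiseless data generated from those printed parameters, and
clipping would move the best-fit `k2` by ~0.04 — far beyond the 1e-3
round-trip tolerance. `dissolution_profile` therefore tolerates small
excursions (−5 to 105), and `simulate_dissolution` clips only noisy draws,
leaving noiseless curves exactly equal to the model evaluation.

**Mechanism**: from a Peppas–Sahlin fit, `k1 > k2` calls Fickian diffusion
dominant, `k2 > k1` relaxation/erosion dominant, equality within 1e-6 is
"mixed"; the dissolution rate k is the positive coefficient (the larger if
both are positive, 0 with a warning if neither is). Burst release is
flagged from the companion `KP_F0` fit's `F0 > 0` at report precision.

## 5. Correlation stage

The property table holds one row per formulation with per-medium rate and
DT columns plus the dissolution rate k. Correlations are reported
descriptively (slope, intercept, r²) without p-values, as is conventional
for these small n.

The default subset rule excludes formulations whose predictor rate is
exactly zero because the front never moved (the plain hydrophobic drug in
acid shows no dye ingress at all): a "rate" of a process that never started
is a different null category, not a small measurement. This rule — exposed
as `exclude_nonwetting` — is what reproduces the published wetting-rate vs
dissolution-rate correlation (r² = 0.9641 on the six polymer-containing
formulations). The qualitative plateau of dissolution rate above erosion
rates of ~0.16 mm/min is noted in reports but deliberately not fitted.

## 6. The synthetic world

`simulate_immersion_stack()` renders the stated world: a disk (default
12.7 mm diameter at 0.05 mm/px in a 512×512 frame, 31 frames at 1/min)
whose dye front advances inward at constant speed, gel halo grows outward,
and outer boundary recedes with optional per-ray Gaussian roughness (smooth
periodic perturbation, 64 angular control points, redrawn per frame) and
bright bubble discs placed just outside the receding edge. Colors:
saturated blue medium, white tablet, stained matter = 65% blend toward the
medium color, gel = 50%-alpha whitish blend over medium, all edges
anti-aliased over 1 px. Pixel noise is Gaussian with SD as a fraction of
dynamic range. Everything is a deterministic function of the seed.

Two geometry accommodations follow from the published rates themselves:

* a published wetting rate of 1.459 mm/min saturates a 6.35 mm radius in
  ~4.4 min — handled by the saturation semantics above, not by changing
  the geometry;
* the fastest published erosion rate (0.375 mm/min) recedes 11.25 mm in
  30 min, *more than the physical tablet radius*. (The original experiment
  may have measured erosion as a diameter change; this package follows the
  border-to-border edge-distance definition of its measurement figure, and
  emits the ×2 diameter convention only as an optional report column.)
  Scenes exercising that rate render a larger disk (radius 240 px) so the
  full recession stays in frame; the generator refuses scenes whose tablet
  would be consumed.

The study fixture (`make_study_fixture()`) emulates the full design —
seven formulations × two media × five replicates, velocities drawn from
the published mean ± SD, dissolution profiles from the published
Peppas–Sahlin rows on a 9-point grid (0.25–24 h; the experiment's actual
grid is not printed, so this grid is a stated assumption). Disintegration
times mix printed values with interpolated stand-ins, marked `synthetic_*`
in their `source` column. ND gel entries render as zero gel velocity.

**What the generator does not emulate** — and therefore what a green test
does not establish: real dye transport (sharp prescribed fronts, no
diffusion gradients), bubble dynamics (static bright discs per frame, no
growth or drift), gel rheology, illumination drift, vignetting, focus
changes, or any coupling between wetting, gelation and erosion. Recovery
tests validate the *measurement chain*, not the physics.

## 7. Numerical and formatting choices

* Radial profiles: 0.5 px step, bilinear interpolation; crossings by linear
  interpolation; rotation invariance holds to < 1 px-equivalent.
* Image coordinates: row/col with pixel centers at integers; distances
  always in mm.
* Report precision mirrors the published tables: 3 decimals for rates,
  4 for kinetic parameters and criteria.
* File formats: PPM (ASCII P3 or binary P6) frames with a JSON sidecar.
  This is the one deliberate narrowing of scope: the environment this
  package must run in has no TIFF/PNG reader available to R, and PPM is
  the only standard raster format that is trivially self-implementable and
  text-capable end to end.
* Configs are JSON with a closed key schema; unknown keys are rejected by
  name.

## 8. Known limitations

* Thresholds (25% gel, 15% matter) are stated fractions of a frame-0
  reference, chosen for robust margins on both synthetic and plausibly
  real contrast; strongly stained, nearly medium-colored matter could fall
  below the matter threshold and read as eroded.
* The erosion tracker assumes the gap left by erosion reads as medium; a
  gel-filled gap inward of the initial border would shift the detected
  matter boundary.
* Sub-pixel fronts moving < ~1 px between consecutive frames are detected
  with an onset delay of about a frame (narrow-gap detectability), which
  slightly biases very slow erosion rates upward; at the published rates
  the bias is far inside the acceptance tolerances.
* Replicate SDs in the fixture are across replicates; whether the original
  tables' SDs are across replicates or rays is not stated.
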