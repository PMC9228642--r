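# tabletrace

Image-based characterization of immersed tablets, and the dissolution
kinetics that go with it.

When a tablet is dropped into a dyed medium under a stereomicroscope, three
fronts move at once: the dye **wets** inward from the border, a translucent
**gel** layer (from hydrophilic carriers such as poloxamer 407) grows
outward, and the outer boundary **erodes** inward — fastest for effervescent
formulations, whose CO₂ bubbles roughen the surface. Each front's
distance-versus-time slope is a rate in mm/min that predicts how the
formulation disintegrates and dissolves. `tabletrace` turns a calibrated
time-lapse image stack into those three rates, fits cumulative dissolution
profiles with the two standard power-law release models, and quantifies how
the physical rates correlate with the dissolution rate.

It is aimed at formulation scientists who have (a) time-lapse RGB stacks of
a tablet in dyed medium with a pixel-size calibration, (b) cumulative-%
dissolution profiles, and optionally (c) disintegration times — or who want
a fully synthetic, ground-truthed version of all three to validate an
analysis pipeline.

## What it computes

**Front tracking.** Frame 0 is segmented into dyed medium vs tablet by an
Otsu threshold on a blueness index `b = B − (R+G)/2`; the initial border
radius `R₀(θ)` is measured along 360 rays from the foreground centroid with
sub-pixel interpolation. Per frame and ray:

- wetting distance `d(t) = R₀ − r_innermost dye transition` (inside the border),
- gel thickness `g(t) = r_outer gel boundary − R₀` (outside the border),
- erosion distance `e(t) = R₀ − r_outer matter boundary` (inside the border),

each aggregated as the median over non-occluded rays (rays crossing gas
bubbles are detected and excluded). Rates are ordinary least-squares slopes
of distance vs time, replicates summarized as mean ± SD.

**Dissolution kinetics.** Profiles `F(t)` (% dissolved) are fitted by
unweighted least squares with

- F0-modified Korsmeyer–Peppas: `F = F0 + K_KP·tⁿ`,
- Peppas–Sahlin: `F = k1·tᵐ + k2·t²ᵐ`,

selected by R² (higher), AIC = `N·ln(WSS) + 2p` (lower) and
MSC = `ln(SST/WSS) − 2p/N` (higher). The dominant release mechanism follows
from the larger of `k1` (Fickian diffusion) vs `k2` (relaxation/erosion),
and the dissolution rate k is the positive one.

**Correlation.** Per-formulation rates, disintegration times and k are
joined into a property table; relationships are reported as OLS slope,
intercept and squared Pearson correlation.

## Worked example

A synthetic fast-wetting, fast-eroding effervescent tablet in acidic medium
(wetting 0.516 mm/min, erosion 0.375 mm/min, per-ray roughness 1 px),
tracked and regressed:

```r
library(tabletrace)
spec <- scene_spec(width = 640, height = 640, radius_px = 260,
                   pixel_size = 0.05, n_frames = 31,
                   wetting_velocity = 0.516, erosion_velocity = 0.375,
                   roughness_sd = 1, seed = 42)
sim  <- simulate_immersion_stack(spec, medium = "HCl_pH1.2")
geom <- detect_initial_border(sim$stack)
#> tablet_geometry: center (320.50, 320.50) px, 360 rays, radius 12.996 +/- 0.003 mm
estimate_rate(trace_to_series(track_wetting_front(sim$stack, geom)))
#> rate_estimate (wetting): slope 0.5158 mm/min, intercept -0.0211 mm, r2 1.0000, n 26
estimate_rate(trace_to_series(track_erosion_boundary(sim$stack, geom)))
#> rate_estimate (erosion): slope 0.3748 mm/min, intercept -0.0066 mm, r2 1.0000, n 31
```

Both generator velocities are recovered within a few tenths of a percent
(the wetting regression uses 26 frames: this front reaches the center
before minute 30 and later frames are flagged saturated).

Dissolution fitting and mechanism call for a fast-releasing formulation:

```r
prof <- simulate_dissolution("PS", c(k1 = 31.4441, k2 = -5.3375, m = 0.1751),
                             c(0.25, 0.5, 1, 2, 4, 6, 8, 12, 24),
                             formulation_id = "IP30E")
ps <- fit_model(prof, "PS"); kp <- fit_model(prof, "KP_F0")
select_model(list(kp, ps))
#> model_fit (IP30E, PS): k1 = 31.4441, k2 = -5.3375, m = 0.1751 | WSS 2.851e-19, R2 1.0000, AIC -378.3136, MSC 47.6237, N 9
classify_mechanism(ps, kp)
#> mechanism_call (IP30E): diffusion_dominant, dissolution rate k = 31.4441 %/h, burst = FALSE
```

Correlating the packaged published wetting rates (acidic medium, the six
P407-containing formulations) with their Peppas–Sahlin `k1`:

```r
linear_correlation(c(0.084, 0.159, 0.236, 0.388, 0.485, 0.516),
                   c(5.1761, 8.5832, 15.3681, 29.2022, 30.1941, 31.4441),
                   x_name = "wetting_rate", y_name = "dissolution_rate_k")
#> correlation (dissolution_rate_k ~ wetting_rate): slope 64.8390, intercept -0.1919, r2 0.9641, n 6
```

A wetting rate increase of 0.1 mm/min corresponds to ~6.5 %/h more
dissolution rate across these formulations, with r² = 0.9641.

## Command line

```sh
Rscript inst/cli/tabletrace.R simulate  --config cfg.json --out study/
Rscript inst/cli/tabletrace.R track     --input study/ --out study/
Rscript inst/cli/tabletrace.R rates     --input study/ --out study/
Rscript inst/cli/tabletrace.R fit       --dissolution study/dissolution.csv --out study/
Rscript inst/cli/tabletrace.R correlate --out study/
Rscript inst/cli/tabletrace.R all       --config cfg.json --out study/
```

Configs are JSON (`validate_run_config()` documents the schema; unknown keys
are rejected). Stacks on disk are directories of PPM frames with a
`stack.json` sidecar giving `pixel_size_mm` and timestamps.

## Layout

- `R/` — implementation (imaging, rates, dissolution, correlate, synthgen, cli)
- `tests/testthat/` — unit, property and acceptance suites
- `vignettes/tabletrace-methods.Rmd` — models, assumptions, design choices
- `inst/extdata/` — packaged published rate/kinetics/DT tables
- `scripts/acceptance.R` — acceptance report
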