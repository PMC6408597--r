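---
title: "Breaking camouflage: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Breaking camouflage: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(camosearch)
```

## The scientific problem

Edge enhancement is a disruptive-coloration strategy: luminance
gradients placed alongside internal reflectance boundaries make those
boundaries mimic depth edges, so an observer segmenting a cluttered
scene is pushed towards parsing the animal's interior pattern as object
outlines. Binocular disparity, by contrast, signals the *true* 3-D
layout. `camosearch` provides a complete synthetic test bed for the
interaction between the two: it builds camouflaged snake targets in
leaf-litter scenes, renders calibrated stereo pairs under two
illumination models, simulates observers searching for the target, and
analyses the resulting reaction times with a fully within-subjects
2×2×2 design (edge enhancement × illumination × viewing condition).

Everything is deterministic given seeds, and every stage exposes ground
truth (target masks, per-pixel depth and disparity), which is what
makes the pipeline testable end to end.

## Texture synthesis

A snake texture starts as i.i.d. uniform noise on a 1024×128 raster
(mapped along the body), smoothed by a Gaussian kernel with
`sigma = 33` px (reflective boundaries) and thresholded at 0.5 (values
at exactly the threshold go to 1; this is measure-zero but fixed for
determinism). The resulting binary blob map is painted with two base
colours drawn from a natural palette.

Edge enhancement adds a signed field to the HSV value channel: every
pixel within 10 px (Euclidean distance) of a region boundary receives
magnitude `0.25 * (1 - d/10)`, positive on the lighter side and
negative on the darker side, so the light region lightens and the dark
region darkens towards the boundary. Boundary pixels are detected as
4-neighbour label changes — on binary input this is exactly what a
Canny detector localises, and the morphological definition makes the
edge set testable pixel for pixel. Distances come from an exact
Euclidean distance transform (Felzenszwalb's lower-envelope algorithm,
implemented in C++ and tested against a brute-force oracle).

Two numerical choices worth knowing: the ramp attains ±0.25 *at* the
boundary pixels (d = 0) and is exactly zero at d ≥ 10; and the
enhancement acts on the value channel only (hue and saturation are
untouched), our reading of a "luminance gradient".

## The colour palette

The natural palette emulates sampling RGB triplets from below-horizon
regions of eight forest scenes: 8 groups × 100 samples = 800 triplets.
The synthetic generator concentrates hue mass in green (≈0.26) and
yellow–brown (≈0.10) bands with small group-level hue/value offsets
standing in for scene-to-scene variation, a saturation distribution
straddling 0.3, and a broad value spread. A CSV loader
(`load_palette_csv()`) accepts real samples instead; 0–255 files are
auto-detected.

Base-colour selection reproduces the study's filters: samples with
value outside (0.25, 0.75) (strict, so the ±0.25 ramp can never push
the value channel outside [0, 1]) or saturation ≤ 0.3 are excluded; the
dark colour is drawn uniformly from the 10th–45th value centiles of the
filtered set and the light colour from the 55th–90th. Centile ranks use
`(rank − 0.5)/n × 100` with inclusive band bounds and ties broken by
sample order; on the worked five-value example {0.30, …, 0.70} this
yields ranks 10, 30, 50, 70, 90 and the expected band membership. The
centiles are taken over the *value* dimension — the surrounding
procedure is entirely about luminance contrast, and this is the reading
that guarantees `dark$v < light$v`.

## Scene composition

World units are cm; the ground plane is z = 0 and the viewing axis is
+z, so "up" out of the litter points at the camera. The background
subtends 39.64° × 28.74° at 57 cm (41.09 × 29.21 cm via
`size = 2·D·tan(θ/2)`). Leaves are 1.10° × 0.50° × 0.02° sheets whose
outline is a cubic Bezier half-profile mirrored about the long axis,
curled parabolically (default depth 0.08 cm) orthogonal to that axis.
The snake is an elliptical tube, 4.00° × 0.40° × 0.02°, constant over
the central body with a slightly wider head (peak 1.15× radius) and a
tapering tail. The tail tapers to 18% radius rather than a
mathematical point — a stylisation that keeps the rendered mask's major
axis at the full body length under rasterisation.

Rigid-body physics is replaced by a deterministic height-field stacking
model (1 mm cells): each of the 4500 leaves samples a uniform XY
position and Z rotation, then rests *flat* at the running maximum of
the field under its footprint, capped so the stack never exceeds
1.5 cm; its top surface then raises the field. The snake is placed the
same way (optionally constrained so its centroid lies in a requested
quadrant) and is added to the field so it casts and receives shadows.
The original drop heights (5–7 cm for leaves, 12 cm for the snake) are
retained as metadata but do not affect the rest state. What the model
preserves is what matters perceptually downstream: clutter, occlusion
("the snake is not always the closest object"), height variation, and
the snake-on-top tendency. What it gives up: tilted resting poses and
collision response, which slightly changes image statistics relative to
a physics engine.

## Rendering

The renderer is a deliberately simple z-buffer rasterizer (C++):
perspective projection through each optical centre onto the shared
ground-plane window, affine attribute interpolation (triangles are tiny
relative to scene depth), Lambertian shading computed at vertices and
interpolated (Gouraud), and per-pixel cast shadows under directional
light obtained by marching the height field towards the light. Ambient
illumination is the cosine-weighted upper-hemisphere term
`(1 + n·up)/2` with no cast shadows and no ambient occlusion;
directional illumination uses `floor + (1 − floor)·max(0, n·L)·vis`
with a configurable shadow floor (default 0.15). Light azimuth is
measured clockwise from screen-up seen from above (350° puts the light
slightly left of up; shadows fall down-right); this convention is a
documented guess where the original tooling leaves it unspecified.

One consequence of height-field shadowing: the field stores top
surfaces, so a *raised* element shadows like a solid column and its
shadow is a smear whose far edge is the element's outline displaced by
`h/tan(elevation)`. The closed-form shadow tests measure that far edge.
In stacked scenes elements rest on their support and the column
approximation is immaterial.

Stereo: the two cameras sit ±3.25 cm about the cyclopean point, 57 cm
from the image plane, both projecting onto the same window, so
disparity is zero at the ground plane and crossed (positive, in
degrees) for nearer points. The ground-truth disparity map is computed
from cyclopean depth via the exact vergence-angle difference
`2·atan(ipd/2/d) − 2·atan(ipd/2/57)`; tests verify that rendered
left/right offsets match it within a pixel. Monoscopic trials duplicate
the cyclopean render bit-exactly. `make_anaglyph()` routes left/right
luminance to the red/green channels. The default raster is 1200×870
(~30 px/deg); `res_scale` refines the raster without changing the
field, and all angular measurements use the exact tangent mapping of
the rig rather than a linear px/deg constant (which would itself be ~2%
wrong across a 39.64° field). Images export as plain-text PPM
(`write_ppm()`); ground truth as CSV/JSON.

## The synthetic observer

The observer is a stand-in for human participants, not a mechanistic
search model. Reaction times are additive in milliseconds:

* `baseline_rt` (default 2000 ms) for the fastest reference cell
  (stereoscopic, directional, unenhanced);
* condition shifts parameterised directly by the study's printed mean
  differences: enhancement costs 436.39 ms under monoscopic and
  96.40 ms under stereoscopic viewing; ambient (shadow-free) lighting
  costs 540.75 / 309.97 ms; and a monoscopic base cost of 100 ms for
  unenhanced targets — the one delta the study does not print (it
  reports "very little advantage" of stereo viewing for unenhanced
  targets), chosen once as a realistic value and not revisited;
* a Gaussian subject intercept (SD 300 ms) and mean-centred lognormal
  trial noise (SD 500 ms, sdlog 0.5) — right-skewed, which is exactly
  why the analysis uses a reciprocal transform;
* lapses to no-response with probability 0.0107 and incorrect responses
  (uniform over wrong quadrants) with probability 0.0354, the study's
  observed rates; RTs above the 20 s timeout also become no-responses.

Because effects are additive in milliseconds, the reciprocal transform
induces small interactions on the analysis scale; that is a real
feature of such data, not a bug. Two honest limitations: there are no
subject-by-condition random slopes, so simulated t statistics are much
larger than the study's at the same mean differences (the *mean*
structure, not the uncertainty structure, is calibrated); and the
simulator is decoupled from the renderer — RTs do not depend on the
rendered images, so a green statistics test establishes nothing about
image content, which is covered by the geometry tests instead.

## The analysis

The pipeline follows the study exactly: (1) remove participants whose
error rate exceeds the mean by 4 SD (single pass); (2) drop no-response
and incorrect trials, logging percentages against the pre-removal
count; (3) transform each trial to 1/RT in s⁻¹, screen for transformed
values more than 3 SD from the pooled grand mean, and collapse to
per-participant means in the 8 cells (transform-then-average; the
millisecond-scale cell means are kept alongside for descriptive
differences); (4) a fully within-subjects 2×2×2 ANOVA via the classical
marginal-means decomposition, each effect tested against its own
subject-by-effect error term on (1, n−1) df; (5) generalized eta
squared with all subject-related variance in the denominator,
`SS_eff / (SS_eff + SS_subjects + ΣSS_error)`; (6) simple-effects
paired t-tests on the transformed scale with both `d_z` (difference
over SD of differences) and `d_av` conventions reported — the study's
printed d alongside its t is not consistent with `d_z`, so both are
exposed. No multiple-testing correction is applied, matching the
original analysis.

The test suite checks the ANOVA against two independent oracles: an
explicit contrast-coding projection (per-subject contrast scores) to
1e-10 relative tolerance, and `stats::aov()` with an `Error()` stratum.
Calibration is checked operationally: under a null observer, each of
the seven effects rejects at α = 0.05 in 3–7% of 1000 simulated
29-participant experiments; under the printed-difference deltas the
large-monoscopic / small-stereoscopic enhancement pattern is recovered
in essentially every run.

## What a green test does and does not establish

The synthetic palette emulates the *distributional shape* of forest
colours, not any particular forest; the stacking model preserves
clutter statistics, not contact mechanics; the observer reproduces the
study's mean structure, not its variance structure or any perceptual
mechanism. The study's headline statistics (F values, ηG², removal
percentages) live in its deposited human dataset, which this package
does not ship; `read_trials_csv()` with a column mapping will run the
identical pipeline on that file if you have it. What the green suite
establishes is that every stage implements its stated model exactly,
at the stated parameter values, with calibrated false-positive
behaviour.

## Worked example

```{r example, eval = FALSE}
records <- simulate_experiment(observer_model(), n_participants = 29,
                               master_seed = 42)
results <- analyze_trials(records)
print(results)
```

See the README for the output this prints and how to regenerate the
acceptance numbers with `scripts/acceptance.R`.
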