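---
title: "Methods: image-based and viability-based drug testing in tumor organoids"
author: "organoscreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: image-based and viability-based drug testing in tumor organoids}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(organoscreen)
```

# The problem

Drug testing in 3D tumor organoids (for example, organoids derived from
prostate-cancer patient-derived xenografts) is usually read out as a single
whole-well ATP-based viability number. That read-out cannot distinguish a
drug that stops growth (cytostatic) from one that kills cells (cytotoxic),
and it discards all organoid-to-organoid heterogeneity. This package
implements the computational side of a complementary strategy:

* a **viability arm** — vehicle-normalized whole-well readings, a
  four-parameter logistic (4PL) dose–response fit, and plate acceptance
  rules that reject experiments whose controls do not behave; and
* an **imaging arm** — per-plane segmentation of organoids and of nuclei
  within organoids from three-channel live-cell confocal z-stacks
  (Hoechst 33342 marking all nuclei, Caspase 3/7 Green marking apoptosis,
  propidium iodide marking membrane rupture), per-nucleus mean dye
  intensities, a control-calibrated four-population death gating scheme,
  and organoid-load statistics normalized to the pre-treatment baseline.

Everything is exercised end to end on a seeded synthetic-data generator
with known ground truth, so each stage is testable without microscope
data.

# Acquisition model

`acquisition_geometry()` describes the sampling of one well: square fields
of `field_area` µm² at `pixel_size` µm/pixel, `n_planes` z-planes spaced
`z_step` µm apart, `n_fields` fields per well. The defaults describe a
spinning-disk high-content setup with a 40× water objective: a
78,974.6 µm² field imaged as 15 planes at 25 µm steps (937 × 937 px at
0.3 µm/px). All quantification is **per-plane 2D**: with a 25 µm step the
planes are optically far apart, z-stacks are a sampling scheme rather than
a volume, and intersections of one organoid on several planes are
deliberately counted as separate organoid records. Maximum projections are
for display only.

# The synthetic-data generator

`synthetic_scene()` + `render_scene()` emulate exactly the statistical
structure the analysis relies on, and nothing more:

* **Organoids** are 3D clusters of nuclei spread over up to three
  neighbouring planes. Nuclei sit on a hexagonal grid with
  centre-to-centre spacing `4 σ` where `σ = nucleus_sigma` (default
  2.5 µm). Each nucleus is rendered as an isotropic 2D Gaussian blob of
  that σ; its ground-truth label is the disc of radius `2 σ`, so adjacent
  discs touch: the organoid footprint is connected while individual
  nuclei stay separable. Nucleus size is parameterised in **µm**, not
  pixels, so the 250 µm² organoid filter keeps its meaning at every pixel
  size.
* **Death modes** follow two-dye gating logic: viable = low/low,
  apoptotic = high Caspase / low PI, necrotic = low/high, late apoptotic
  (secondary necrosis) = high/high. "Low" and "high" are lognormal
  distributions with arithmetic means 100 and 1000 (a.u.) and log-SD 0.2 —
  a 10× separation, recoverable but overlapping in the tails. Real dye
  intensities are instrument-specific; these scales are generator
  parameters, not claims about any instrument.
* **Debris** is rendered as bright Hoechst-channel specks with areas drawn
  from 20–150 µm², below the 250 µm² organoid filter, placed clear of
  organoid footprints and of each other so that specks can never fuse into
  a filter-passing region.
* **Depth attenuation** is a linear 2 %-per-plane intensity loss — a
  one-parameter stand-in for scattering in the gel dome; no optical PSF,
  photobleaching or murine-cell contamination is modelled.
* **Background** is additive truncated-Gaussian noise, `c(mean 5, sd 2)`
  by default; `c(0, 0)` gives noiseless images for exact oracles.
* **Plates**: `simulate_plate()` draws the untreated signal as
  `baseline · growth_rate^day · lognormal(cv)`; the default growth rate
  `2^(1/10)` doubles untreated viability over the 10-day exposure, the
  dynamic the growth-ratio QC rule expects of a healthy culture. Treated
  day-10 wells are scaled by the true 4PL response at their dose;
  staurosporine positive controls are scaled to a 5 % residual.

Identical seeds give bit-identical scenes, images and plates.

What the generator does **not** emulate — real organoid morphology
(lumina, irregular shapes, touching organoids), intensity gradients within
nuclei, fragmented apoptotic nuclei, spectral crosstalk, field-edge
vignetting. Passing tests therefore demonstrate that the algorithms
recover a known truth under the stated model, not that segmentation is
robust to every real-world artefact.

# Image analysis pipeline

The commercial high-content software used in such screens exposes only
coarse descriptions of its operators ("Gaussian filtering and region
resizing"), so the pipeline is built from standard, reproducible
morphological pieces (EBImage):

1. **Combined image** (`combine_channels()`): per-channel max
   normalisation, then the sum of the three channels — organoids are found
   whether their cells are Hoechst-, caspase- or PI-bright. Sum, rather
   than max or a weighted blend, is an exposed choice.
2. **Organoid segmentation** (`segment_organoids()`): Gaussian blur
   (σ = 2 px) → Otsu threshold → morphological closing → hole filling →
   "region resize" (erosion then dilation, radius 2 px) → connected
   components → area filter at `min_area = 250` µm². Two numerical
   guards matter:
   * the threshold is floored at `median + 6 × MAD` of the blurred plane;
     Otsu always finds *some* split, and on planes with no real foreground
     it would otherwise segment the background noise itself;
   * the closing radius must bridge the gaps between the bright nuclei of
     one organoid (about the nucleus radius in pixels; the pipeline
     default is `ceiling(nucleus_sigma / pixel_size) + 1`) while staying
     below half the organoid-to-organoid distance.
   Regions touching the field border are kept but flagged `on_border` —
   partially imaged organoids are data, merely size-underestimated.
3. **Nucleus segmentation** (`segment_nuclei()`): peak-seeded watershed on
   the lightly blurred Hoechst channel, restricted to organoid regions.
   Each nucleus is assigned to exactly one organoid — the one containing
   its centroid, or the nearest by boundary distance if rounding puts the
   centroid just outside (the tie-break is deterministic).
4. **Intensity extraction** (`extract_intensities()`): arithmetic mean of
   the **raw** caspase and PI pixels under each nucleus mask; filtering is
   for finding objects, never for measuring them.
5. **Well loads** (`quantify_well()`): total nuclei, mean organoid
   cross-section area (µm²), total organoid records, per sampled area
   `n_fields · field_area`.

On noiseless synthetic fields with non-touching organoids the pipeline
recovers region counts exactly and per-region areas typically within 10 %
(worst observed ≈ 14 % for the smallest cross-sections, where the closing
step inflates area relatively most); with default noise, per-well sampled
nucleus counts stay within 15 % of ground truth. These are the margins the
test suite asserts.

# Death gating

The gating model has two calibrated parts.

**Viable thresholds.** On day-0 untreated controls (pooled per
experiment, not per well), the viable gate in each channel is
`mean + 2 SD` of the per-nucleus mean intensities. A nucleus is viable iff
it is at or below **both** thresholds. The complementary rule — dead iff
above **either** threshold — is the only reading under which a purely
caspase-high apoptotic population and a purely PI-high necrotic population
can exist, and matches the "negative for both dyes" definition of viable
cells. For independent Gaussian channel noise the viable fraction of a
control population converges to `pnorm(2)² ≈ 0.955`, which the tests use
as an analytic oracle. Thresholds are computed on the linear intensity
scale by default; a log10 option exists (on log scale the whole gating is
exactly invariant to global intensity rescaling).

**Gate lines.** Dead nuclei are split by two straight rays anchored at
`(t_caspase, t_pi)`, at angles measured from the caspase axis:
`theta_apoptotic` (default 30°) bounds the caspase-dominant apoptotic
sector, `theta_necrotic` (default 60°) bounds the PI-dominant necrotic
sector, and everything between the rays is late-apoptotic. Points above
one threshold but "behind" the anchor are clipped onto the anchor's axes
before the angular test, which maps them into the pure sector — consistent
with the verbal population definitions. The defaults split the dead
quadrant into three equal 30° sectors; nothing in the underlying screen
fixes these angles, so they are exposed, logged parameters.

Optionally the angles are calibrated on day-10 untreated controls (which
contain enough spontaneous death of all modes): the angular positions of
dead cells about the anchor are partitioned into three groups by a
deterministic 1-D k-means (centers initialised at the 1/6, 1/2, 5/6 angle
quantiles) and the rays are placed midway between adjacent group centers.
A plain central-quantile mode is also provided, but note that for a
balanced three-mode mixture pooled-angle quantiles land *inside* the outer
clusters rather than between them — the cluster-midpoint rule is the one
that actually separates well-separated modes (the tests demonstrate ≥95 %
recovery). Both calibrations are equivariant under rotation of the dead
points about the anchor. With zero dead cells in the controls, the
defaults are kept with a warning.

`validate_positive_control()` checks the biology end of the chain: wells
exposed to 1 µM staurosporine (a broad-spectrum kinase inhibitor used as a
death positive control) must show a mean dead fraction at least 0.2 above
untreated wells.

# Organoid-load statistics

Growth under treatment is the day-10 well metric divided by the **pooled
mean** of day-0 control wells (`normalize_growth()`); fold changes are
scale-free, so rescaling all wells cancels. Each dose is compared to
untreated day-10 wells with a two-sided unpaired t-test
(`compare_to_untreated()`); Welch's unequal-variance form is the default —
treated and control wells have no reason to share a variance — with the
pooled-variance form behind a flag. Bonferroni correction multiplies p by
the number of doses tested against the same controls per metric.

# Viability arm and plate QC

`fit_dose_response()` fits
`v(d) = bottom + (top − bottom) / (1 + 10^{h·(log₁₀ d − log₁₀ IC₅₀)})`
by Levenberg–Marquardt least squares, with starting values taken from the
data (asymptotes from the extreme-dose means, IC₅₀ from the dose nearest
the midpoint, h = 1). Vehicle (dose-0) wells are excluded from the fit —
they act only through normalisation. Flat responses and non-convergence
set `converged = FALSE` with a note instead of raising.

`compute_qc()` implements the plate-acceptance rules on raw readings:

| rule | definition | pass |
|---|---|---|
| growth ratio | mean(day-10 untreated) / mean(day-0 untreated) | ≥ 1.5 (inclusive) |
| CV | sd/mean of day-10 negative controls | < 0.22 (strict) |
| Z-factor | 1 − 3(σ₊ + σ₋)/\|μ₊ − μ₋\| (sample SDs) | > 0.4 (strict) |
| DMSO effect | mean(DMSO vehicle)/mean(untreated), day 10 | 0.8–1.2 (inclusive) |

CV is computed on negative controls (standard screening practice; the
alternative — all replicate wells — would mix treatment effect into a
noise metric). The Z-factor needs ≥ 2 positive-control wells, otherwise
the rule is *not applicable* rather than failed; same for DMSO without
DMSO wells. The overall verdict is the conjunction of applicable rules.

# Putting it together

```{r pipeline, eval = FALSE}
geom <- geometry_from_pixels(192, pixel_size = 1, n_planes = 3)
scene <- synthetic_scene(geom, n_organoids = 3, seed = 1)
stack <- render_scene(scene, well_id = "A1")
out <- run_pipeline(list(stack_a1 = stack, ...), platemap,
                    readings = readings, out_dir = "results/")
```

`run_pipeline()` chains segment → quantify → gate → load-stats
(→ plate-qc when readings are given), halts naming the failing stage, and
stamps every output table with the configuration hash and seed; identical
inputs and configuration reproduce byte-identical CSVs. A thin wrapper
script (`inst/scripts/organoscreen.R`) exposes the same stages as shell
subcommands.

# Problem sizes and numerical notes

The demonstration and test workloads use reduced geometries — typically
192² px fields at 1 µm/px with 3–5 planes and 3–5 organoids per field,
8-well experiments, and 100-replicate plate simulations — chosen so the
whole validation suite explores every code path in seconds while leaving
all defaults at the full acquisition scale. Other numerical choices worth
knowing:

* all centroids and areas are reported in µm (areas via `pixel_size²`);
* watershed fragments smaller than half a nucleus cross-section are
  discarded as shot-noise peaks;
* `fit_viable_thresholds()` requires ≥ 2 nuclei (SD undefined below);
  `fit_dose_response()` requires ≥ 4 distinct nonzero doses;
* classification at exactly a threshold or gate line is deterministic:
  thresholds are inclusive for "viable", gate lines inclusive for
  "late apoptotic";
* seeds are 32-bit integers; every stochastic entry point takes one.

# Limitations

Endpoint measurements only — no organoid tracking over time. Per-plane 2D
counting overestimates organoid numbers for large organoids (multiple
intersections) and underestimates sizes at field edges; the well-load
metrics are *sampled* quantities by design. The gating geometry assumes
the two dye channels are crosstalk-free. Real plates fail QC for reasons
the simulator does not generate (edge effects, dispensing errors); the QC
rules here verify the arithmetic and the verdict logic, not those causes.
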