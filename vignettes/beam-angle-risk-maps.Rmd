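---
title: "Geometry-based beam-angle risk maps: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Geometry-based beam-angle risk maps: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(beamrisk)
```

## The problem

Proton beams stop. Where they stop depends on the integrated stopping power
along the beam path, so a lung tumour that moves with respiration does not
merely blur the dose — it shifts the Bragg peak in depth. A beam direction
whose radiological path to the target is stable across the breathing cycle
is robust; one whose path crosses moving lung/soft-tissue interfaces is
fragile. Independently, every direction determines which organs at risk
(OARs) sit in the entrance channel. Both effects are *geometric*: they can
be scored from the 4DCT alone, before any dose calculation, and used to
pre-select candidate beam angles.

`beamrisk` scores every orientation on a gantry–couch grid with two
metrics, normalises and combines them into a unified risk map, and selects
a beam set under a separation constraint. This vignette records the model,
its assumptions, and every place where the design was genuinely open.

## Pipeline and model

1. **Structures.** The per-phase GTV is expanded isotropically (default
   5 mm, physical distance to voxel centres, anisotropy-aware) into a CTV;
   the ITV is the union of CTVs over the cycle; OARs are composite
   (all-phase-union) contours. Expansion thresholds true Euclidean distance
   rather than using a structuring element, so it is exact against a
   brute-force oracle and testable as such.
2. **Calibration.** HU → relative stopping power via a piecewise-linear
   lookup table anchored at water (0 HU → RSP 1.0), clamped outside the
   node range. The shipped 8-node curve is a representative
   stoichiometric-style surrogate — the pipeline's behaviour depends only
   on a monotone calibration — and any site curve can be supplied as a
   `hu,rsp` CSV.
3. **Ray tracing.** For each orientation, parallel rays (source at
   infinity; no divergence, scattering or energy-layer model) are seeded at
   2 mm pitch in the beam's-eye view over the ITV projection plus one pitch
   of margin. Traversal is exact Siddon-style: boundary-crossing parameters
   are breakpoints, each interval is attributed to the voxel containing its
   midpoint, and chord sums telescope to the geometric in-grid path length
   (verified to 1e-9 mm).
4. **ΔWEPL.** WEPL is integrated for the AIP and all phases along
   *identical* geometric paths, and ΔWEPL is the mean absolute AIP-phase
   difference over rays and phases. ≥ 0 by construction, exactly 0 for a
   motionless case.
5. **PIV.** The fraction of OAR voxels crossed by at least one ray, rays
   truncated at their distal stop point.
6. **Risk map.** Per-VOI Z-scores (population SD) over deliverable cells,
   user weights (defaults 2 / 1.5 / 1.5 / 0.5 for target / heart / lungs /
   cord), hard constraints (`exclude_intersecting`, i.e. PIV > 0, or a
   strict PIV threshold), weighted sum. Lower is better.
7. **Selection.** Greedy by ascending score with a minimum pairwise
   central-angle separation (default 20°); `worst` mode ranks descending
   for benchmarking poor geometry.

## Angle convention

Gantry 0° is an anterior beam travelling posteriorly, increasing toward
patient-left; the couch rotates about the vertical axis of a supine
patient. The travel direction is `(-sin g · cos c, cos g, sin g · sin c)`
in the patient frame (x = left, y = posterior, z = superior). Vertical
beams (gantry 0°/180°) are couch-invariant, so the default grid drops the
24 repeated directions: 36 × 13 = 468 cells → 444 unique orientations.
Machine-specific collision limits are expressed as a deliverability CSV
rather than hard-coded; no standard exclusion rule exists that the package
could assume.

## Decisions that were genuinely open

- **Distal stop points are fixed on the AIP-frame ITV** and reused for all
  phases. The alternative — per-phase distal edges — would conflate path
  geometry with the metric itself; fixing the stop point makes ΔWEPL a
  pure path-composition comparison along identical rays. Flagged as a
  choice, not the only defensible reading.
- **Ray keep-radius.** Seeds whose axis passes within `pitch/√2` (the seed
  grid half-diagonal) of a target voxel centre are kept. With the tighter
  `pitch/2` radius the nearest seed to a voxel centre can be discarded and
  beam's-eye-view coverage is no longer guaranteed; the half-diagonal
  radius makes the coverage property (every target centre within
  `pitch/√2` of a kept ray) hold by construction.
- **PIV truncation.** Rays end at the target's distal edge — protons stop —
  so an OAR entirely distal to the target scores 0 regardless of
  alignment.
- **Normalisation before exclusion.** Z-score statistics are computed over
  all deliverable cells *before* constraints remove any, so adding a
  constraint changes admissibility but never re-scales the remaining
  scores; scenarios that differ only in constraints stay directly
  comparable.
- **Population SD** (not sample) in the Z-score, for reproducibility and
  because the grid is the full population of candidate orientations.
- **Greedy selection** rather than exhaustive subset search: selection is
  defined as "lowest scores subject to separation", and greedy is the
  minimal faithful reading; ties break by (couch, gantry) lexicographic
  order so results are deterministic.
- **Boundary tie-breaks.** Voxels are half-open intervals
  `[lower, upper)` per axis; the midpoint attribution in the traversal
  makes grazing rays deterministic.

## The phantom: what it emulates and what it does not

The generator paints an elliptical thorax (+40 HU), two low-density lungs
(−750 HU), an anterior-left heart (+30 HU), a posterior midline spinal
cord (+40 HU) and a spherical tumour (+30 HU, default radius 12 mm) in a
fixed priority order on a 96³ grid at 2 mm isotropic spacing (a desk-scale
volume that traces in well under a second per orientation). The tumour
translates rigidly along a configurable axis with sinusoidal displacement
— zero at phase 0, the full peak-to-peak amplitude (default 10 mm,
a typical superior–inferior lung excursion) at mid-cycle. Optional
additive Gaussian HU noise is seeded and defaults to 0 so tests are
deterministic.

Deliberately absent: deformable anatomy (lungs and OARs are static),
hysteresis, CT texture and beam-hardening artefacts, and realistic
mediastinal anatomy. Passing tests on the phantom therefore demonstrate
the *geometric machinery* — traversal exactness, metric definitions,
normalisation, constraint and selection semantics, and the qualitative
physics (amplitude-monotone ΔWEPL, anterior heart exposed only to anterior
beams, beams parallel to the motion axis least motion-sensitive). They do
not certify performance on deformable patient anatomy, where ΔWEPL also
picks up density changes the rigid phantom cannot produce.

## Parameters that matter

| parameter | default | unit | rationale |
|---|---|---|---|
| CTV margin | 5 | mm | standard clinical GTV→CTV expansion |
| ray pitch | 2 | mm | spot-grid scale; PIV resolution is set by this |
| gantry / couch step | 10 / 15 | deg | full deliverable space at desk-scale cost |
| weights | 2 / 1.5 / 1.5 / 0.5 | — | target-prioritising plan with modest cord emphasis |
| min. separation | 20 | deg | avoids near-parallel beam sets |
| motion amplitude | 10 | mm | typical SI lung-tumour excursion |

## Numerical sizes used by the test suite

Tests run the full 444-orientation grid only for the zero-motion null
(where no OAR scoring is needed); map-level properties use a
30°/45° grid (52 orientations) and the amplitude sweep a 45°/45° grid
(32 orientations), with the default 96³ phantom throughout. The traversal
oracle compares 1000 random rays against 0.01 mm-step dense midpoint
integration on random 32³ RSP volumes at 2 mm spacing, with rays through
the central half of the volume (as treatment beams are); agreement is
better than 0.1 % with the chord-length identity exact to 1e-9 mm.

## Known limitations

- Purely geometric: no dose, no DVH, no interplay or rescanning model —
  the maps rank candidate geometries, they do not replace planning.
- PIV is resolution-limited by the finite ray set; halving the pitch
  roughly quadruples the ray count and sharpens the footprint.
- Only axis-aligned volumes are accepted; oblique acquisitions are
  rejected rather than silently resampled.
- The calibration surrogate is not a patient-specific stoichiometric fit;
  absolute ΔWEPL values in mm depend on the curve supplied.
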