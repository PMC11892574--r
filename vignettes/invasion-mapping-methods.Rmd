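---
title: "Trajectory-based tumor invasion mapping: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Trajectory-based tumor invasion mapping: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(invasionmap)
```

## The problem

High-grade gliomas infiltrate the brain along white-matter fibers well
beyond the contrast-enhancing tumor core, and often beyond the edema zone
visible on T2-FLAIR. Metastases, by contrast, are surrounded by a purely
vasogenic edema without an infiltrative component. Diffusion-kurtosis
parametric maps (MD, FA, MK, KA, AWF and related metrics) are sensitive to
this microstructural difference, but reading them voxel by voxel is
confounded by noise, by gray-matter and CSF neighborhoods, and by the fact
that infiltration follows fiber geometry rather than Euclidean distance.

`invasionmap` addresses this by analyzing parametric maps *along
plausible infiltration routes*: pseudorandom walks on the voxel lattice
that run from distant white matter to the tumor border, with step
probabilities weighted by the local diffusion tensor. Per-voxel summaries
of where those route profiles change significantly produce "gradient
maps" that highlight the infiltrated margin.

## The pipeline

### Step distance in the white-matter labyrinth

`compute_distance_map()` labels every white-matter voxel with the minimal
number of single-voxel steps needed to reach the tumor while staying
inside the white-matter mask. This is a breadth-first labeling: voxels
adjacent to the tumor get 1, their unlabeled white-matter neighbors 2,
and so on. Two conventions are deliberate:

* **Adjacency is the full 26-neighborhood**, the same 26 directions used
  by the transition matrices, so "one step" means the same thing in every
  stage and the distance-gating tests ($d_j \le d_i$ and $d_j \ge d_i$)
  are consistent. The connectivity is configurable (6/18/26).
* **Distance is a step count**, not a metric length: a diagonal step also
  counts one. It measures corridor depth in the labyrinth, not millimetres.

White matter not connected to the tumor is marked unreachable and excluded
from all later stages; masks that overlap are resolved in favor of the
tumor.

### Tensor-weighted transitions

For voxel $i$ and neighbor direction $n_{ij}$ (one of the 26 unit
vectors), the directional diffusivity is the quadratic form

$$\mathrm{ADC}_{ij} = n_{ij}^{\mathsf T} D_i\, n_{ij},$$

clamped at zero (noisy tensor fits can make it slightly negative). Step
probabilities are

$$W_{ij} = \frac{m_{ij}\,\mathrm{ADC}_{ij}}{\sum_j m_{ij}\,\mathrm{ADC}_{ij}},$$

where the gate $m_{ij}$ is 1 only for eligible white-matter neighbors
that do not violate the mode's distance rule: walks toward the tumor
never step to $d_j > d_i$, walks away never step to $d_j < d_i$.
Equal-distance neighbors stay admissible in both modes, allowing walks to
wander within a distance stratum, which is what the stall limit (below)
exists to bound.

Two numerical choices matter here:

* **ADC floor** (`adc_floor = 1e-6` mm²/s): after gating, directional
  diffusivities below the floor are raised to it. Every voxel with
  $d > 1$ has, by construction of the distance map, a strictly closer
  neighbor, so with the floor no walk can reach a dead end even on
  degenerate (e.g. all-zero) tensors. At healthy white-matter
  diffusivities (~1e-3 mm²/s) the floor changes probabilities by less
  than one part in a thousand.
* The quadratic form is evaluated for all eligible voxels at once as a
  dense `nvox x 26` matrix product, so the matrices are built once per
  run and walks are cheap.

### Pseudorandom trajectories and the coverage scheduler

Walks sample steps from the `W` rows (compiled code, driven by R's RNG so
a single `set.seed()` reproduces a run bit-exactly, scheduling included).
A toward-walk ends on entering a voxel at $d = 1$ (the tumor margin). If
a walk takes `stall_limit` (default **12**) consecutive steps without
getting closer, its next draw is restricted to strictly-descending
neighbors. The limit bounds wandering; forcing descent (rather than
aborting) preserves the walk and the no-dead-end property.

Away-walks use the opposite gate and stop at a local distance maximum
(all-zero row) or after `stall_limit` equal-distance steps. The
stopping rule for away-segments is a design choice: something must bound
a walk that can legally wander a stratum forever, and the same stall
parameter is the natural bound.

The scheduler guarantees **at least `min_coverage` (default 100)
trajectories through every eligible voxel**. The first cycle starts walks
from uncovered voxels, beginning at the most distant stratum ($d_{max}$)
and exhausting each stratum before moving toward the tumor; later cycles
revisit each stratum far-to-near and start walks from its
minimum-coverage voxels. Starts below $d_{max}$ are stitched from a
toward-segment and an away-segment sharing the start voxel, so every
trajectory spans far white matter to the tumor margin. A trajectory
increments a voxel's coverage once, however often it revisits it. Each
cycle strictly raises every unfinished stratum's minimum, so termination
within `min_coverage` cycles is guaranteed; `max_cycles` (1000) is a
safety bound only.

### Profiles, smoothing, significant gradients

Profiles sample a parametric map at each trajectory voxel, oriented tumor
border first, with the step distance as the x-axis. Smoothing is a
sliding **median of window 6** (the shipped default): kurtosis maps carry
heavy thermal-noise spikes that medians remove without blunting monotone
trends. Two conventions are ours:

* The median of an even-length window is the mean of the two central
  order statistics, and windows truncate at the profile ends (a profile
  shorter than the window is smoothed with the largest window that
  fits). The window parameter is configurable.
* Smoothing runs over the *sample sequence*, not over unique distances:
  equal-distance wandering samples are retained so that every visited
  voxel carries a sample for the per-voxel statistics.

Local extrema of the smoothed profile (plateaus collapsed to their
midpoints, profile endpoints included) partition it into alternating
monotone segments. A segment is **significant** when its amplitude
exceeds

$$k \cdot 1.4826 \cdot \operatorname{median}\lvert\,\text{raw} - \text{smoothed}\,\rvert,$$

with $k = 3$ by default — a per-profile robust noise scale, which makes
the rule scale-free across parametric maps with different units; an
absolute threshold can override it for calibrated maps. Raising $k$ can
only remove significant segments, never add them.

**Sign convention.** Segment direction is reported relative to the tumor:
a *rising* segment is one where the parameter increases as the tumor
border is approached. This is the sign an invasion map is meant to
highlight — the parameter elevated toward the infiltrated border — and it
makes the phantom's planted ramp (high at the border, decaying outward)
register in the rising map.

### Gradient maps

For each voxel, $Q$ counts the trajectories passing through it and $P$
those whose profile has a significant rising (or falling) segment
covering one of the voxel's samples; the outputs are the two percentage
maps $100\,P/Q$. They are reported separately because a voxel can lie in
segments of both kinds; their sum may exceed 100. Voxels with $Q = 0$
are NaN. Attribution is by profile sample, not geometric interpolation:
profiles are defined on trajectory voxels. Multiplying a map by a
positive constant leaves both outputs unchanged.

No statistical inference is attached to the maps: they are descriptive
percentages, not p-values.

## The phantom generator

No patient data ship with the package; `make_phantom()` builds
lattice-native scenes with planted ground truth:

* **Geometries.** `corridor` (one straight tube), `labyrinth` (a
  randomized-Prim spanning-tree maze over a coarse node lattice with
  3-voxel spacing, carved as 1-voxel corridors — connected by
  construction), `shell` (a solid ball, the worst case for wandering).
  A separate generator, `make_two_slice_crossing_phantom()`, joins
  corridor systems on two axial slices by an oblique bridge carrying the
  only planted gradient, emulating an invasion route that no single slice
  can show.
* **Tensors** are exactly prolate with the principal axis along the local
  corridor direction: $D = \lambda_\perp I + (\lambda_\parallel -
  \lambda_\perp)\,u u^{\mathsf T}$ with defaults
  $\lambda_\parallel = 1.7\times10^{-3}$,
  $\lambda_\perp = 0.3\times10^{-3}$ mm²/s. Directional ADC along/across
  the corridor equals the eigenvalues exactly, which several tests
  exploit.
* **Parametric map.** Baseline 1.0 everywhere; in glioblastoma mode a
  ramp of height `map_contrast` (default 0.5) is added at the tumor
  border, decaying linearly over `gradient_extent` (default 5) steps of
  the distance map — the planted-truth mask marks exactly the ramp
  voxels. Metastasis mode plants nothing: flat baseline, emulating pure
  vasogenic edema. Additive Gaussian noise (default sd 0.05, i.e. a
  contrast-to-noise ratio of 10) is applied on top. The defaults — 40³
  grid at 2.5 mm isotropic voxels, labyrinth geometry — are the study
  conditions used by the acceptance checks; 2.5 mm is a typical DKI
  acquisition grid.

What the phantoms do *not* model: partial-volume effects, tensor-fit
noise (available as an option via map noise only; tensors are noiseless
by default), crossing-fiber voxels, or realistic brain geometry. Passing
tests on phantoms therefore demonstrate the correctness of the lattice
algorithm and its statistics, not clinical performance on real DKI data.

## Problem sizes, runtime, false positives

The shipped test-and-acceptance runs use 14³–20³ phantoms for unit-level
checks and the default 40³ labyrinth for end-to-end checks; a default 40³
run (≈6500 eligible voxels, $d_{max}$ ≈ 50, ≈90 000 trajectories)
completes in about 1–2 minutes on one core. Runtime scales linearly in
total trajectory steps.

With the default $k = 3$ threshold, pure-noise profiles of typical length
show a significant segment in roughly 7–8% of cases; on the default
metastasis-mode phantom this translates to mean map values of ≈3–4%,
versus ≈80% inside a planted glioblastoma shell. Users wanting stricter
maps on noisy data should raise `significance_k` rather than the filter
order.

## Deviations and open choices, in brief

* "6th-order median filter" is read as a 6-sample window (not a
  polynomial order); the even-window median convention is stated above.
* The significance rule for "significant gradient" is this package's own
  (robust, scale-free, $k = 3$); no published definition exists for it.
* The CLI phantom spec file is YAML.
* Tensor component order is lower-triangular-by-row on disk, with a
  `diagonal_first` remap flag, since both dialects circulate.
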