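---
title: "Histology-optimized tractography and photosensitivity analysis with optotract"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Histology-optimized tractography and photosensitivity analysis with optotract}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(optotract)
```

## The problem

Diffusion-MRI tractography can reconstruct cortico-subcortical pathways —
such as the motor hyperdirect pathway running from motor cortex to the
subthalamic nucleus (STN) — but the reconstruction is notoriously sensitive
to its parameters, which are usually chosen by convention rather than
evidence. When a retrograde tracer has labeled the true cortical origins of
a pathway, the histological fluorescence map provides an anatomical ground
truth against which tractography parameters can be *optimized* rather than
assumed. `optotract` implements that optimization, the histological
reconstruction it requires, the resulting whole-target connectivity report,
and the companion electrophysiological analysis: deciding which deep-nucleus
units respond to optogenetic photostimulation of the pathway.

The package works on three data families, all expressible in standard
formats: streamline tractograms (TRK/TCK), labeled cortical surface meshes
(ASCII OFF mesh + label table) with per-vertex maps, and spike-event time
series (CSV) with OFF/ON/POST period boundaries. All geometry is kept in
world millimetres, RAS orientation; voxel-convention inputs (TRK, NIfTI) are
converted at the I/O boundary, so no stage downstream of a reader ever sees
a voxel coordinate.

## Terminal geometry: depth and angle

Each selected streamline is characterized at its cortical end by two
anatomically meaningful parameters:

* **depth** Δ — the arc length along the streamline from its *last* crossing
  of the cortical surface to its terminal point (mm);
* **angle** θ — the angle between the terminal direction and the *inward*
  surface normal at the crossing (degrees), so that a fiber leaving the
  cortex perpendicular to the surface has θ = 0.

Streamlines are first restricted to those passing within a seed sphere
(default diameter 1 mm) centred on the injection site inside the deep
target. The crossing is found by exact segment–triangle intersection,
walking the streamline backwards from its terminal so that a streamline
grazing a sulcal bank twice is measured at its final entry. The terminal
direction is the least-squares direction of the last *k* = 3 points
(single-segment tangents are noisy at streamline step scale), and the
normal is interpolated barycentrically at the crossing point.

Filtering keeps terminals with |depth − Δ| ≤ 0.5 mm and |angle − θ| ≤ 15°
by default — half the spacing of the default candidate grid
{2, 3} mm × {0, 30, 45}°. Both windows are inclusive at the boundary. The
depth grid is in millimetres: macaque cortical thickness is 2–3 mm, so
depths of order 2–3 are only physically meaningful on the mm scale, and the
unit is configurable should a different convention be needed.

We treat (Δ, θ) as a *post-hoc selection* applied to the terminals of a
whole-brain tractogram, not as constraints inside the streamline
propagation algorithm; propagation is deliberately out of scope, and the
selection view makes the optimization a pure filtering problem with an
exactly reproducible search space.

## Comparing tractography with histology

The histological reference is built from serial sections: binary
fluorescence masks (fixed threshold, or Otsu per slice) are stacked into a
block with anisotropic voxels — in-plane pixel size as photographed,
inter-slice spacing 0.32 mm by default (every 8th 40-µm section). Gaps
between sections are *not* interpolated; all statistics are computed on the
sampled slabs, which is unbiased for volume fractions and avoids inventing
an interpolation the data do not support. Per-region fluorescence is
reported both as each region's share of the total fluorescent volume and as
the fluorescent fraction of each region's volume, with an explicit
"unassigned" row so shares always total 100%.

Fluorescent voxels are projected to the nearest surface vertex within a
3 mm cap (leakage across sulci is bounded by the cap; geodesic-aware
assignment is out of scope), and streamline terminals are deposited on
their crossing vertices and spread with a mass-conserving truncated
Gaussian kernel over a 2 mm geodesic neighborhood. The two surface maps are
then compared by **local correlation**: at each vertex, the Pearson
correlation of the two maps over the geodesic neighborhood of radius 3 mm
(configurable; the analyses are robust between 2 and 4 mm). Geodesic
distance is the shortest path along mesh edges (Dijkstra); with radii much
larger than the edge length the approximation error is negligible.
Vertices whose neighborhood has fewer than 3 members or zero variance in
either map are flagged undefined and excluded from area sums — a
correlation there is simply not estimable.

The optimization objective for a cortical region is the surface area of
that region where local correlation exceeds 0.5, averaged across subjects
(arithmetic mean; sem uses the n − 1 denominator). The grid argmax is
reported; ties are broken toward smaller angle, then smaller depth, and are
logged. No multiple-testing control is applied: the grid search is a
selection, not an inference, and the r values are descriptive.

The connectivity report then applies each region's optimal window to the
streamlines reaching the whole target and reports, per region, the
percentage of all kept fibers (these sum to 100 within a hemisphere by
construction) and the percentage of the region's surface lying within the
density smoothing radius of at least one terminal — our operationalization
of a region "projecting" to the target, since a vertex-level definition is
otherwise arbitrary.

## Photosensitivity of spike trains

Units recorded in the deep nucleus are classified by asking whether the ON
(photostimulation) period is consistent with the rate model fitted on the
OFF (pre-stimulation) period:

1. fit an OFF rate model — constant by default, matching tonic subthalamic
   firing; piecewise-constant and Gaussian-kernel (reflection edge
   correction) intensities are available when the OFF period is visibly
   nonstationary;
2. *self-check* the OFF fit: fit on the first half of OFF, time-rescale the
   held-out second half, and run the goodness-of-fit suite. A unit failing
   its own OFF self-check is unclassifiable and excluded from population
   fractions — testing ON against a model that cannot even describe OFF
   would conflate misfit with photosensitivity;
3. time-rescale the ON spikes under the (full-)OFF model and run the suite;
   the unit is photosensitive iff the self-check passes and the ON fit is
   rejected.

The suite is the standard Ogata residual-analysis quartet on the rescaled
times, each test at the Bonferroni-adjusted level α/4 (family level ≤ α,
default α = 0.05), rejection if any test rejects: uniformity of event
positions (KS), Berman's exponentiality test on the rescaled gaps (KS),
lag-1 independence of the Berman residuals (Fisher z), and the maximum
excursion of the centered counting process N(τ) − τ. Two numerical points
deserve note:

* the counting excursion is referred to the supremum distribution of
  |Brownian motion| on [0, 1], which is its unconditional limit; a Brownian
  *bridge* band would only be correct after conditioning on the event
  count, and that conditional statistic is already exactly the uniformity
  KS test. Using the bridge band unconditionally would inflate the
  counting test's level several-fold;
* when the model has itself been estimated from *m* events (the OFF fit),
  the centered process acquires an extra drift of variance Λ²/m, and the
  excursion is normalized by √(Λ(1 + Λ/m)) instead of √Λ. Without this the
  family level roughly doubles at typical subthalamic rates (≈1100 OFF
  events), because the plug-in rate error is of the same order as the
  Poisson fluctuation being tested. The other three tests are conditional
  on the count and unaffected.

With fewer than 10 events the report is flagged underpowered and only the
counting test is evaluated — it is meaningful for any count, including
zero, so a unit silenced by stimulation is still (correctly) detected as
photosensitive through the excursion of the expected count.

Population statistics follow the field's conventions: photosensitive
fraction 100·k/n over classified units (reported to one decimal); one-way
repeated-measures ANOVA over the OFF/ON/POST rates of photosensitive units
with Greenhouse–Geisser ε-corrected degrees of freedom (reported always,
alongside the uncorrected ones and Mauchly's test); Tukey HSD pairwise
comparisons on the ANOVA error term; Shapiro–Wilk normality on the per-unit
ON − OFF differences; and an exact two-sided Wilcoxon signed-rank test for
paired fluorescence intensities (exact null distribution for n ≤ 25, zero
differences dropped). The per-unit percentage change is averaged across
units rather than taken as a ratio of mean rates; the two differ slightly
and the per-unit average is the quantity whose sem is meaningful.

## Synthetic data: what it emulates and what it does not

Every stage is testable without any acquisition through the generators:

* `make_labeled_surface` builds a folded sheet (sinusoidally displaced
  triangulated grid, default 20 × 20 mm, 2 mm fold amplitude, 10 mm
  wavelength) partitioned into contiguous geodesic-Voronoi patches. A
  folded sheet rather than a sphere is deliberate: sphere normals are
  degenerate with position, which would make angle filtering trivially
  confounded.
* `make_tractogram` plants pathway streamlines from a deep seed through
  the surface at annotated (depth, angle) with optional Gaussian jitter,
  plus decoys in three equal families — missing the seed sphere, wrong
  depth (±1.25–2.5 mm), wrong angle (+31–55°) — each violating exactly one
  selection clause so each filter clause is exercised separately.
* `make_histology_block` fills Voronoi-clipped cortical-ribbon columns
  (2.5 mm deep, 0.5 mm lateral radius) under weighted surface vertices,
  sampling voxels so the expected fluorescent volume under a vertex is
  exactly proportional to its origin weight and the total volume is stable
  under resolution changes.
* `make_spike_trains` draws OFF/ON/POST renewal trains (Poisson or
  gamma-renewal) at a baseline rate times an ON multiplier. Defaults —
  18.2 Hz baseline, 60 s periods — reflect tonic subthalamic firing in the
  awake primate.

All generators are pure functions of their parameters and an integer seed,
and return ground-truth annotations sufficient to compute any downstream
confusion matrix without re-deriving geometry.

What the synthetic data does *not* emulate: real gyrification and atlas
geometry, susceptibility- and noise-driven tractography errors (decoys are
geometric, not physical), stain variability and registration error in
histology, and pulse-locked spiking structure (the 130 Hz stimulus
fine-structure is deliberately not modeled; the analysis operates at the
period-rate scale). Passing tests therefore demonstrate correctness of the
computations and calibration of the statistics under controlled conditions,
not robustness to every artifact of in-vivo data.

## Problem sizes and numerical choices

The test and acceptance suites run the pipeline at desk scale, chosen to
keep full runs to minutes while leaving every statistical conclusion
well-powered: surfaces of ~300–500 vertices, tractograms of 100–120
streamlines (half decoys), two synthetic subjects and 100 optimization
replicates per jitter condition, 1000 replicates of 200 events for the
goodness-of-fit calibration, and 100 classification replicates for power.
Parameter recovery is checked at zero jitter (exact recovery expected every
time) and at jitter equal to half the tolerance windows (recovery expected
in ≥ 90% of replicates).

Degenerate inputs are handled explicitly rather than silently: empty
tractograms and empty filter results propagate as empty objects; an
all-zero objective grid returns the tie-break cell with a warning;
constant-intensity slices under Otsu fall back to background with a
warning; a kernel fit on zero events falls back to the zero constant rate;
and every reader validates its header and fails naming the offending
field. Every pipeline stage logs input counts, parameter values and output
counts (enable with `options(optotract.verbose = TRUE)`).

## A compact worked example

```{r example, eval = FALSE}
cfg <- run_config()
surf <- make_labeled_surface(6, mesh_resolution = 18, rng_seed = 42)

subjects <- lapply(1:2, function(sj) {
  tr <- make_tractogram(surf, tract_ground_truth(2, 30, n_true = 50,
                                                 n_decoy = 50),
                        rng_seed = sj)
  origin <- density_map(data.frame(vertex =
    tr$truth$vertex[tr$truth$family == "true"]), surf, smoothing_mm = 2)
  blk <- make_histology_block(surf,
                              surface_map(origin$values, "fluorescence"),
                              rng_seed = sj)
  sel <- select_by_seed(tr$tractogram,
                        seed_sphere(tr$seed_center_mm,
                                    cfg$seed_sphere_diameter_mm))
  list(terminals = terminal_geometries(sel, surf),
       histo_map = fluorescence_to_surface(blk, surf))
})

optimize_params(subjects, surf, region = 1, cfg)

spikes <- make_spike_trains(list(spike_ground_truth(18.2, 1.5)),
                            rng_seed = 7)
classify_photosensitive(spikes$records[[1]], cfg)
```

## Known limitations

* Geodesic distances are edge-path approximations; on very coarse meshes
  with radius comparable to the edge length the neighborhoods are ragged.
* Voxel-to-surface assignment is Euclidean nearest-vertex with a cap, not
  geodesic; across tight sulci a small volume can still be assigned to the
  wrong bank within the cap.
* The constant OFF model is the default everywhere; strongly
  nonstationary OFF periods should use the piecewise or kernel families,
  at the cost of the exactness of the rescaling integral (kernel Λ is
  tabulated numerically).
* Subjects are assumed co-registered to a common space; no registration is
  performed.
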