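---
title: "Generating safe-margin volumes for bone tumor resection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Generating safe-margin volumes for bone tumor resection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(safemargin)
```

## The problem and the model

A bone tumor must be resected together with a layer of surrounding normal
bone at least `d_s` millimetres thick (the safe margin, 10/15/20 mm
depending on the Enneking stage). The *safe-margin volume* is the tumor
plus all bone within `d_s` of it; a cut-plane plan that stays outside this
volume is guaranteed margin-adequate. The inputs are two co-registered
binary masks on an anisotropic voxel lattice: bone `V_b` and tumor `V_t`,
with in-plane spacings `S_x, S_y` (mm), per-slice z positions `P_z^k`, and
in-plane origin `(P_x, P_y)`. Only the intraosseous tumor drives margin
growth, so the tumor is always intersected with the bone first
(`refine_tumor()`): tumor outside bone does not contact bone and including
it would only inflate the resection.

Voxel `(i, j, k)` is identified with its centre
`((i-1)S_x + P_x, (j-1)S_y + P_y, P_z^k)`; all exported functions use
1-based indices matching this convention. The exact anisotropic Euclidean
distance transform gives each voxel its minimum distance in millimetres to
the tumor, with index offsets weighted by the per-axis spacings. It is
computed by a separable lower-envelope algorithm in compiled code and is
exact to floating-point rounding — a chamfer or other approximate metric
would break the error guarantees below, which is why the package ships its
own kernel rather than an approximate one. Thresholding the map at `d_s`
(inclusive, as is every comparison in the package) and intersecting with
bone yields the margin volume on whatever grid the map was computed on.

## Coarse + fine-ring fusion

On the original grid the margin boundary is only accurate to about one
voxel: every boundary voxel centre sits within `max(S_x, S_y, D̄)` (~0.8 mm
clinically) of the true offset surface, where `D̄ = (P_z^n - P_z^1)/(n-1)`
is the mean slice gap. Computing everything on a sufficiently fine grid
would fix the accuracy but multiplies the voxel count a thousandfold. The
pipeline (`generate_safe_margin_volume()`) therefore:

1. crops both masks to a region of interest `d_s + ξ` beyond the tumor
   bounding box;
2. computes the **coarse** margin volume `V_d` on the original cropped grid
   with metric spacings `(S_x, S_y, D̄)`;
3. replicates both cropped masks by odd factors
   `C = 2*ceil((S/S_t + 1)/2) - 1` per axis — the smallest odd integer with
   `S/C <= S_t` — and keeps only the **fine ring**: the shell with
   distances in `[d_s - 2*max(Ŝ), d_s]`, clipped to the resampled bone;
4. fuses the two voxel-centre point sets into the output surface cloud
   (`fused_points`), optionally triangulated for export.

Replication factors are odd so the fine sub-centres straddle each original
centre symmetrically in plane; replication is two-stage (in-plane first,
then z) to bound peak memory. The ring band of `2*max(Ŝ)` is wide enough
that the coarse volume and the ring always overlap: the coarse boundary lies
within one coarse voxel of the true surface and the ring covers the last two
fine voxels below it, so the fused cloud has no gap between the bulk and the
skin.

The construction yields an analytic accuracy guarantee. Inside the ring
`D <= d_s`; an outward boundary voxel has a 6-neighbour with `D > d_s`, and
the transform is 1-Lipschitz with respect to physical steps, so its own
value exceeds `d_s - max(Ŝ)`. Signed errors of the outward boundary against
the exact nearest distance to the fine tumor voxel centres therefore lie in
`(-max(Ŝ), 0]`: never beyond the true surface, never more than one fine
voxel inside it. At `S_t = 0.10` mm this is < 0.09 mm; the test suite and
the acceptance script verify the bound on every phantom run with an
independent KD-tree oracle.

## Parameters

* `d_s` (mm) — the safe margin; must exceed the ring band `2*max(Ŝ)`
  (~0.18 mm at default settings). Clinically 10–20 mm.
* `target` = `S_t` (mm, default 0.10) — desired fine spacing; accuracy and
  cost both scale with it (fine voxel count grows as `1/S_t^3`).
* `xi` = ξ (mm, default 2) — cropping slack beyond `d_s`. Any value safely
  above one coarse voxel works; 2 mm exceeds the discretization slack at
  clinical spacings while keeping the ROI tight. If the ROI overruns the
  scan extent it is clamped with a warning and the margin may be truncated
  by the volume border, matching clinical reality.
* `keep_fine` — retain the fine masks and distance map for evaluation
  (≈1 GB at default settings on the acceptance phantom).

## Slice positions of the resampled stack

Clinical stacks can have slightly unequal slice gaps, so z handling reads
the per-slice positions everywhere except in the distance metric, which
uses the scalar `Ŝ_z = (P_z^n - P_z^1)/(H_z C_z - 1)` of the resampled
stack (and `D̄` on the coarse grid). Where should the `H_z C_z` resampled
slices sit? Per-gap interpolation with step `D_i/(2C_z - 1)` is
well-defined for a two-slice stack but self-contradictory for longer ones
(adjacent gaps assign conflicting positions to shared slices), and any
per-gap layout makes the point coordinates inconsistent with the scalar
metric — which would void the error guarantee above. This package
therefore lays the resampled slices out **globally uniformly** from the
first to the last original position with spacing `Ŝ_z`. This reduces
exactly to the per-gap rule in the only case where that rule is consistent
(two slices), preserves both endpoints for any stack, and makes fine point
coordinates exactly consistent with the distance metric. Two documented
consequences:

* fine voxel z-centres can drift from their parent slice's position by up
  to `(C_z - 1) Ŝ_z` (< one coarse gap) near the stack ends — in-plane
  containment in the parent voxel remains exact;
* the fine z lattice depends on the cropped stack extent, so bit-identical
  rerun requires the same ROI (the pipeline's own ROI is deterministic, so
  end-to-end runs are reproducible byte for byte).

For non-uniform stacks the residual inconsistency between actual slice
positions and the scalar metric is bounded by the per-gap deviation from
uniformity; the phantom generator's z-jitter exists to exercise exactly
this.

## Baselines and the oracle

`dilation_baseline()` reproduces the criticized voxel-unit approach:
dilation of the refined tumor with a discrete index-space ball of radius
`round(d_s/S_x)` voxels, blind to anisotropy (the source method does not
specify its structuring element; the in-plane-normalized ball reproduces
its qualitative failure mode — errors that scale with the spacing
mismatch — without inventing precision). `coarse_only_method()` is the
transform on the original grid without resampling. `pointwise_oracle()`
realizes the predecessor point-cloud definition — bone points within `d_s`
of any refined tumor point — by explicit search, sharing no code with the
transform path, and the suite asserts its exact voxel-set equivalence with
the coarse method across 100 randomized grids.

## Evaluation conventions

The reference surface for geometric error is the exact Euclidean distance
to the fine-grid tumor voxel-centre set — the same set the fine transform
measures. No continuous ground-truth surface is defined by the problem;
this choice is self-consistent, independently computable (KD-tree or
exhaustive search), and on sphere phantoms agrees with the analytic
distance `max(0, ||p - c|| - r)` to within half a voxel diagonal
(digitization). Signed error = generated-surface distance minus `d_s`;
negative is conservative (inside). Evaluation points are the outward
boundary of the generated volume: ring voxels with a 6-neighbour beyond the
margin *inside bone*, which excludes faces where the volume is truncated by
the cortex rather than by the margin. Under this convention the fused
method's errors cannot be positive; reference sets are reduced to their
surface shell before nearest-neighbour queries, which is loss-free for
queries outside the set.

Summaries use the normal-approximation CI `mean ± 1.96 sd/√n` (boundary
point counts are 10^3–10^5, where it coincides with a bootstrap interval).
Cross-method comparison uses Anderson–Darling normality per sample, the
one-sided Wilcoxon rank-sum test in its normal approximation with
continuity and tie corrections (with n = m = 20 and complete separation
this gives p = 3.39e-8; exact enumeration would give ~7e-12 — the
approximation is the convention of the clinical analyses this mirrors), and
a pooled-variance t interval for the mean difference, which reproduces the
published effect-size intervals on the bundled cohort error table.
Kaplan–Meier estimation uses the product-limit estimator with deaths
processed before censorings at ties and Greenwood log-scale CIs; the CI
transform of the source analyses is unspecified, so the interval is
reported but not asserted.

## The phantom generator

`make_sphere_phantom()` builds the study conditions: clinical spacing
(0.75, 0.75, 0.80) mm, a 4 mm tumor ball centred in a cuboid bone of
half-width 16 mm — large enough that the 10 mm margin ball (radius 14 mm)
clears the cortex by more than two voxels, so no bone clipping touches the
evaluated boundary. A voxel is tumor iff its centre is inside the ball, so
the digitized tumor matches the analytic ball to half a voxel diagonal and
its volume to a few percent. `make_nonuniform_z_phantom()` adds seeded,
strictly-order-preserving jitter to interior slice positions (endpoints
fixed, so `D̄` is unchanged). What the phantom does *not* emulate: cortical
breakthrough, concave lesions, segmentation noise, CT intensities. Passing
tests therefore certify the geometry engine under known ground truth, not
robustness to segmentation error; the bone-clipping path is exercised
separately by construction in unit tests.

Default problem sizes: the acceptance phantom crops to a 43 × 43 × 41 ROI
and resamples it 9× per axis to 387 × 387 × 369 (~55M voxels, ~1.5 GB,
about half a minute end to end on one CPU); unit tests use smaller phantoms
(≤ 0.5 mm spacing, r = 2 mm) that run in under a second.

## Numerical choices and degenerate inputs

* All threshold comparisons are inclusive; ties in the survival estimator
  process deaths first.
* Physical-box to index conversion takes, per axis, the voxel whose centre
  is the nearest at or below each bound (floor); the ξ slack guarantees
  coverage above. Boxes overrunning the grid are clamped with a warning;
  boxes missing it entirely are an error.
* Empty refined tumor (tumor disjoint from bone), empty foreground,
  single-slice stacks, margins smaller than the ring band, and non-binary
  input volumes are all contract errors, not silent degradation.
* Fused point sets may contain near-duplicate points where ring and coarse
  sets overlap; deduplication is available (`dedupe = TRUE`) but off by
  default — duplicates are harmless for triangulation and removing them
  costs a sort.
* Surface reconstruction returns the boundary of the Delaunay
  tetrahedralization, which is the convex hull of the point set; it exists
  for export and visualization only, no metric depends on it, and it is not
  suitable for concave margin volumes (an alpha-shape extraction is out of
  scope).

## Known limitations

Axis-aligned grids only (direction cosines beyond flips are rejected at
I/O); a single ROI covers all tumor components; the coarse metric treats
slice gaps as uniform (`D̄`), so heavily non-uniform stacks push coarse
(not fused) accuracy toward the largest gap; runtime and memory grow with
`(S/S_t)^3`, so sub-0.05 mm targets on large ROIs are impractical on
desktop hardware.
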