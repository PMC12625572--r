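# safemargin

Safe-margin volume generation for computer-assisted bone tumor resection.

In bone tumor surgery the surgeon resects the tumor together with a
continuous layer of surrounding normal bone whose thickness must be no
smaller than a prescribed *safe margin* `d_s` (10/15/20 mm per the Enneking
staging of the tumor). Planning cut planes with adequate margins requires
the *safe-margin volume*: the region consisting of the tumor plus all bone
within `d_s` of it. This package computes that volume from two co-registered
binary masks — bone and tumor — on an anisotropic voxel grid (clinical CT
spacings are typically near 0.75 × 0.75 × 0.80 mm), for surgeons and
surgical-planning engineers who need a millimetre-accurate, reproducible
margin surface rather than a voxel-unit dilation.

## Method

Let `V_b`, `V_t` be the bone and (bone-intersected, "refined") tumor masks,
with in-plane spacings `S_x`, `S_y`, slice positions `P_z^k`, and voxel
centres `p(i,j,k) = ((i-1)S_x + P_x, (j-1)S_y + P_y, P_z^k)`. The exact
anisotropic Euclidean distance transform assigns every voxel

    D(i,j,k) = min over tumor voxels of sqrt(S_x^2 d_x^2 + S_y^2 d_y^2 + S_z^2 d_z^2)

(index offsets `d_x, d_y, d_z`, exact metric, not chamfer), and the margin
volume is `{D <= d_s} ∩ V_b`. Computed on the original grid this is accurate
only to about one voxel (~1 mm). The package therefore fuses two solutions:

* a **coarse volume** `V_d` on the original grid (spacings
  `(S_x, S_y, D̄)`, `D̄` the mean slice gap), which carries the bulk of the
  volume cheaply; and
* a **fine "dangerous ring"** on a grid replicated by odd integers
  `C = 2*ceil((S/S_t + 1)/2) - 1` per axis (`S_t` = 0.10 mm target spacing;
  `C_x = C_y = C_z = 9` at clinical spacing), keeping only the shell with
  `d_s - 2*max(Ŝ) <= D <= d_s` — the accurate outer skin, at a thousandth
  of the fine-grid point count.

The union of the two voxel-centre point sets is the generated surface; by
construction its outward boundary lies within one fine voxel (< 0.09 mm at
`S_t = 0.10`) inside the true offset surface. Everything is restricted to a
region of interest `d_s + ξ` around the tumor bounding box. Baselines
(voxel-unit ball dilation; coarse-only transform), a brute-force point-cloud
oracle, deterministic sphere phantoms with analytic ground truth, geometric
error reports, cross-method statistics (Anderson–Darling, one-sided Wilcoxon
rank-sum, pooled-t mean-difference CIs) and Kaplan–Meier survival estimation
are included.

## Worked example

```r
library(safemargin)

ph <- make_sphere_phantom(spacing = c(0.75, 0.75, 0.80),
                          bone_half_widths = c(16, 16, 16),
                          r = 4, d_s_max = 10)
res <- generate_safe_margin_volume(ph$bone, ph$tumor, d_s = 10, target = 0.3)
res
#> <safe_margin_result> d_s = 10 mm, target 0.3 mm: 24779 coarse + 78932 ring voxels, 103711 fused points

pts  <- outward_boundary_points(res)
errs <- signed_errors(pts, surface_points(res$fine_tumor), 10)
error_summary(errs)
#> <error_report> n = 32622, mean -0.1057 mm (95% CI [-0.1064, -0.1050]), max |err| 0.2533 mm
```

A 4 mm tumor ball in a cuboid bone is extended by a 10 mm margin at a 0.3 mm
target spacing. The 32 622 outward boundary points of the fused volume sit on
average 0.106 mm *inside* the exact 10 mm offset of the digitized tumor
(negative = conservative), never more than one fine voxel (0.253 mm here);
at the default `target = 0.10` the same run reaches ≈ 0.036 mm mean and
< 0.09 mm maximum error. Survival analysis of the bundled 20-patient cohort:

```r
cohort <- resection_cohort()
km <- kaplan_meier(cohort$follow_up_months, cohort$died)
100 * surv_at(km, 60)
#> [1] 83.125
```

A command-line wrapper (`inst/cli/safemargin.R`) exposes `phantom`,
`generate`, `baseline`, `evaluate`, `compare` and `km` subcommands over
NRRD/NIfTI masks, writing PLY/CSV/STL/NRRD outputs plus a JSON manifest.

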