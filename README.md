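# pairwise3d

Quantitative pairwise comparison of 3D surface meshes of anatomical
specimens, aimed at fragmentary material — isolated fossil bones that are
too incomplete for landmark-rich geometric morphometrics but still deserve
a quantitative comparison against better-known exemplars.

## What it does

Given a fragmentary **target** mesh and one or more **reference** meshes
(OBJ/PLY/STL, e.g. from CT segmentation), the package:

1. **Registers** the target onto the reference. A *first registration*
   estimates the least-squares similarity transform
   `x ↦ s·R·x + t` (uniform scale `s > 0`, proper rotation `R`,
   translation `t`) from ≥3 ordered homologous landmarks, in closed form
   via the SVD of the cross-covariance (reflections excluded). A *second
   registration* refines it with point-to-point **iterative closest point
   (ICP)** with scale: alternate nearest-reference-vertex correspondence
   and the closed-form similarity update, minimising the RMS
   point-to-point distance (default budget 20 iterations; the per-iteration
   RMS history is recorded and is non-increasing).
2. **Edits** meshes before comparison: vertex-mask trimming (with sphere
   and plane selection helpers) to delete fractured or artefactual
   surfaces, and quadric edge-collapse decimation to match the polygon
   count of the lower-resolution scan (upsampling is refused).
3. Computes the **absolute distance field** of the aligned target's
   vertices against the reference: cloud-to-cloud (`c2c`, nearest
   reference vertex) or cloud-to-mesh (`c2m`, exact nearest point on the
   reference triangles). Distances are unsigned; the field maximum is the
   directed Hausdorff distance. Summary statistics (mean distance MD,
   sample SD, range, n), 256-bin histograms, and cold-to-warm heat-map
   vertex colours (exportable as coloured PLY) describe the field: lower
   MD/SD mean greater similarity.
4. **Decomposes trial outcomes** across comparison conditions with a
   permutation-based **type-II ANOVA**: for trials factor-coded by surface
   removal, comparison method, ICP use, and reference specimen, each main
   effect's sum of squares is adjusted for all others, with significance
   from unrestricted permutation of the response
   (`p = (count(F* ≥ F) + 1)/(B + 1)`) and effect sizes
   `Z = (log F − mean log F*) / sd log F*`.
5. **Simulates** test data: a parametric claw-like specimen (curved
   tapered tube with lateral grooves and a ventral tubercle) degraded into
   a fragmentary target (missing distal tip, spherical excavation hole,
   along-normal Gaussian scan noise) under a planted similarity transform
   with known ground truth — so the whole pipeline is testable without
   scan data.

A command line ties it together
(`Rscript <pkg>/exec/pairwise3d <simulate|register|trim|decimate|compare|sweep|anova> [--flags]`),
writing JSON/CSV/OBJ/PLY outputs plus a provenance record per run.

## Worked example

```r
library(pairwise3d)

reference <- make_claw(claw_params(length = 10, proximal_radius = 1.6))
target <- degrade(reference,
                  degradation_spec(distal_fraction = 0.3, hole_radius = 0.6,
                                   noise_sd = 0.02, seed = 1))$mesh
moved <- plant_transform(target, scale = 0.8,
                         rotation = c(10, -6, 8) * pi / 180,
                         translation = c(2, -1, 0.5))
lms <- make_landmark_pair(moved$mesh, target, c(5, 120, 260, 400))
cmp <- pairwise_compare(moved$mesh, reference, mode = "c2m",
                        landmarks_target = lms$a, landmarks_reference = lms$b)
print(cmp)
print(cmp$icp)
```

```
Pairwise comparison (C2M + ICP): n = 586 distance values
  before ICP: MD = 0.015622, SD = 0.012210, range [0.0000, 0.0761]
  after ICP: MD = 0.015568, SD = 0.012199, range [0.0000, 0.0754]
ICP alignment: 2 iteration(s), converged
  final RMS: 0.0200876 (started at 0.0200876)
  correspondences used: 586
  recovered scale: 1.25003
```

The degraded target (586 surviving vertices) is registered back onto the
intact reference: the recovered scale 1.25 is the inverse of the planted
0.8, and the mean absolute surface distance after ICP (~0.016 model units)
is at the level of the simulated scan noise. `plot(cmp)` draws the
distance histogram; `heatmap_colors(cmp$field)` gives the per-vertex
heat-map colours.

The bundled case study — a fragmentary megaraptorid manual ungual
(NMV P186153) compared against two *Australovenator wintonensis* unguals —
ships as `ungual_trials()`, twelve factor-coded comparison outcomes that
feed the permutation ANOVA:

```r
fit <- anova_type2(ungual_trials(), seed = 1)
print(fit)
```

```
Permutation ANOVA (type II SS, 999 permutations, seed 1) on 'mean_distance'
          Df       SS       MS       R2        F      Z     p
removal    1 0.075661 0.075661 0.024661   5.2712 1.1940 0.058
method     1 0.014709 0.014709 0.004794   1.0247 0.5507 0.342
icp        1 0.203619 0.203619 0.066368  14.1858 1.5454 0.003
reference  1 2.413573 2.413573 0.786691 168.1496 2.7412 0.001
Residuals  7 0.100476 0.014354 0.032750       NA     NA    NA
Total     11 3.068004       NA 1.000000       NA     NA    NA
```

The choice of reference specimen dominates the outcomes (R² ≈ 0.79),
running the final ICP matters (R² ≈ 0.066), and the choice between C2M
and C2C barely does — the quantitative backbone of the case study's
conclusion that the fragment matches manual ungual II-3, not I-2.

## Vignette

`vignettes/pairwise-comparison.Rmd` documents the model and its
assumptions, the numerical choices (convergence tolerances, tie-breaking,
degenerate-geometry handling), what the synthetic specimen generator does
and does not emulate, and known limitations.
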