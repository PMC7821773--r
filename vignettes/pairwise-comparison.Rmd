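---
title: "Pairwise 3D comparison of fragmentary specimens: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pairwise 3D comparison of fragmentary specimens: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pairwise3d)
```

## The problem

Isolated, fragmentary vertebrate fossils often cannot be placed in a
landmark-based morphometric analysis: too few diagnostic landmarks
survive, and comparative samples are too small to map a morphospace.
What a curator or anatomist can still do is compare the fragment
*pairwise* against well-preserved exemplars: register the fragment onto
each candidate, measure the absolute surface-to-surface distances that
remain after size and pose are factored out, and treat low mean distance
and low spread as evidence of morphological similarity. `pairwise3d`
implements that workflow end to end, together with a simulation module
that generates fragmentary claw-like specimens with known ground truth so
every stage is testable without scan data.

## Registration model

Both registration stages estimate a *similarity transform*
$x \mapsto s\,R\,x + t$ with uniform scale $s > 0$, proper rotation $R$
($R^\top R = I$, $\det R = +1$), and translation $t$. Scale is included
because real specimens differ in size and the comparison is about shape;
shear and reflection are excluded — a reflected "match" would be
anatomically meaningless, so the closed-form estimator forces
$\det R = +1$.

**First registration.** `landmark_similarity()` solves
$\min_{s,R,t} \sum_i \lVert s R x_i + t - y_i \rVert^2$ for ordered
landmark pairs via the SVD of the cross-covariance matrix. Landmarks are
paired by row order, not by label: the picking order on each specimen
defines homology, and labels are documentation. At least three
non-collinear landmarks are required; collinear configurations leave a
rotation about the line unconstrained and are rejected explicitly rather
than returning an arbitrary solution.

**Second registration (ICP).** `icp_align()` is point-to-point ICP:
each iteration matches every (transformed) target vertex to its nearest
reference vertex, refits the closed-form similarity on the matched pairs,
and records the RMS point-to-point distance after the update. The
mean-squared objective is non-increasing across iterations, which the
test suite asserts on every run. Iteration stops at a relative RMS change
below `rel_rms_tolerance` (default `1e-8`) or at the iteration budget
(default 20). `iteration_sweep()` re-runs the alignment at budgets 5, 10,
…, 100 and locates the plateau; on the synthetic fixtures the RMS is flat
well before 20 iterations, which is why 20 is a comfortable default
rather than a tuned constant.

ICP is a local method. Its basin of attraction is the regime left behind
by a reasonable first registration — residual scale error within a few
tens of percent and pose error within a couple of tens of degrees. From
a wildly wrong initial pose, scaled ICP can collapse: if the matched
configurations are anti-correlated the closed-form scale estimate is not
positive, and the package raises a typed degenerate-geometry error
rather than silently producing a reflection or a zero-scale fit. The
stochastic registration tests therefore draw their planted misalignments
from the post-landmark regime; nothing is claimed about global
convergence.

Two deliberate simplifications: correspondences are nearest reference
*vertices* (point-to-point, matching the RMS point-to-point objective),
not point-to-plane; and there is no correspondence rejection by default
(`keep_fraction = 1`), because the recommended workflow removes
non-comparable surfaces *before* registering rather than asking the
estimator to ignore them. A `keep_fraction < 1` trimmed update is
available when pre-trimming is impossible.

## Distance fields

`c2c()` assigns every compared point the Euclidean distance to its
nearest reference point; `c2m()` assigns the exact unsigned distance to
the reference surface, minimising over all triangles with the closest
point allowed on a face interior, edge, or vertex. Both are exact:
nearest-neighbour search is exhaustive (vectorised and chunked), not an
approximate index — at the point counts this package targets (10^4–10^5)
exactness is cheap, ties can be broken deterministically (lowest
reference index), and the oracle tests can demand elementwise equality
with brute force. `c2m` distances are never larger than `c2c` distances
to the reference vertices, an invariant the tests assert on random
instances; degenerate zero-area reference triangles fall back to vertex
distances instead of producing NaN.

Distances are *absolute* (unsigned): the workflow interprets the mean
(MD) and standard deviation (SD) of the field as a fidelity measure, and
signed fields would let inside/outside errors cancel. The field maximum
is exposed as the directed Hausdorff distance. SD uses the sample
($n-1$) denominator; at the field sizes involved the distinction is
numerically irrelevant, but the choice is fixed and recorded in the
summary object. Histograms use 256 equal-width bins over $[0, \max d]$
with the rightmost bin closed (counts always sum to $n$); heat-map
colours interpolate blue → green → yellow → red with the warm end at a
configurable saturation distance, defaulting to the field maximum.

`pairwise_compare()` chains the stages and, when ICP is on, also records
the pre-ICP summary so the effect of the fine alignment is visible — in
the bundled case study and in the synthetic tests, running the final ICP
consistently lowers MD.

## Mesh editing

Trimming is a pure vertex-mask operation: surviving vertices keep their
coordinates, faces survive only if all three corners do, and the result
may be an open shell — exactly what deleting fractured surfaces from a
scan produces. Sphere and plane selection helpers cover the common
artefact geometries (circular excavation marks, planar fracture cuts);
boundary points count as inside, a convention fixed by test.

Decimation is iterative edge collapse ordered by quadric error (the
standard formulation: per-vertex sums of squared-distance-to-plane
quadrics, area-weighted; optimal collapse position from the 3×3 normal
system with endpoint/midpoint fallback when ill-conditioned; ties to the
lowest edge index). It stops when the referenced-vertex count reaches the
target, so the target is met exactly on well-behaved meshes, and reports
a fidelity bound: the maximum distance from any original vertex to the
decimated surface. `match_resolution()` applies it to equalise polygon
counts before a comparison and *refuses to upsample* — subdividing a
low-resolution scan manufactures detail the scanner never captured.

Surface *replication* (projecting the target's broken-edge geometry onto
the reference to fake equal fragments) is intentionally not implemented:
replicated identical surfaces contribute near-zero distances that inflate
the apparent similarity, concentrating the distribution at its mode and
making it leptokurtic. The acceptance suite reproduces that effect by
construction — appending an identical copy of a fracture-adjacent patch
to the reference raises the kurtosis and lowers the mode of the distance
histogram relative to removing the patch — and the package's supported
path is removal.

## Trial ANOVA

Comparison campaigns produce a small factor-coded table: one row per
trial with removal (yes/no), method (C2M/C2C), ICP (yes/no), reference
specimen, and the outcome MD. `anova_type2()` fits the main-effects
linear model and attributes to each factor its *type-II* sum of squares
— the residual SS of the model without that factor minus the residual SS
of the full model, i.e. each main effect adjusted for all others. With no
interaction terms in the model, type II and type III coincide; the
bundled twelve-trial table has 7 residual df under four single-df terms,
which the decomposition reproduces. The implementation works through QR
projections of the fixed design, so each permutation costs two quadratic
forms rather than a model refit, and `car::Anova` serves as an
independent cross-check in the test suite rather than as the
implementation.

Because the response is a single univariate outcome per trial, the
"non-parametric" inference is a permutation ANOVA: the response column is
shuffled without restriction `B = 999` times under an explicit seed,
$p = (\#\{F^* \ge F\} + 1)/(B+1)$ — so the smallest attainable $p$ is
$0.001$, the floor the bundled table's dominant factor reaches — and the
effect size $Z$ standardises $\log F$ against the permuted
$\log F^*$ distribution. The log-scale $Z$ is this package's fixed
definition; permutation-based effect sizes vary between packages, so $Z$
and $p$ are reproducible only under the package's own scheme and seed,
while $SS$, $MS$, $R^2$, and $F$ are scheme-independent.

Degenerate inputs are flagged rather than absorbed: a constant response
yields all-zero SS with `NA` statistics, and a factor left with no
degrees of freedom after adjusting for the others (perfect aliasing)
raises an error naming it.

## The synthetic specimen generator

`make_claw()` builds a watertight manifold surface from anatomically
motivated ingredients: a circular-arc axis (default arc length 10 model
units sweeping 90°), rings whose radius follows a taper law (proximal
radius 1.6, taper exponent 1.3 — a stubby curved ungual rather than a
needle), a groove indented on both lateral sides, and a rounded ventral
bulge near the proximal end standing in for a flexor tubercle. Default
resolution is 36 rings × 24 points + 2 cap vertices = 866 vertices; the
tests use 10–24 rings where speed matters, sizes chosen so the whole
suite exercises every stage in seconds while keeping several vertices per
groove/bulge feature. The per-vertex scalar field stores the normalised
axial coordinate, which the degradation stage uses to place cuts.

`degrade()` emulates the defects of real fragmentary material: a distal
cut (whole vertices beyond an axial fraction are removed, no
re-triangulation — the result is an open shell like a trimmed scan), a
spherical excavation hole, and Gaussian noise *along vertex normals*
(surface-scan error pushes points off the surface, and normal-directed
noise keeps the thin shell from self-intersecting at small sd; default
degradations use sd 0.02–0.03 units against a 1.6-unit radius, i.e. 1–2%
scan error). Every random step runs under an explicit seed in a local RNG
scope; with zero noise the output vertices are an exact subset of the
input, a property the tests assert.

What the generator does **not** emulate: CT-specific artefacts (beam
hardening, slice anisotropy), taphonomic plastic deformation, varying
triangle quality, or texture. Consequently, passing tests demonstrate
algorithmic correctness (exact distances, transform recovery, monotone
convergence, the replication artefact) on clean topology — they do not
certify performance on poorly meshed or deformed scans, where manual
inspection after registration remains essential.

## Numerical conventions

* Faces are stored 1-based internally (R convention); OBJ stays 1-based
  on disk, PLY/STL conversions happen at the boundary.
* Coordinates are written with 9 significant digits; round-trips are
  exact to that precision.
* STL stores independent facets, so exactly coincident corners are
  welded on read and the weld count is reported.
* Degenerate faces (a vertex repeated) are dropped with a warning, not
  fatal — fossil scans commonly contain a few.
* All nearest-neighbour ties break to the lowest reference index; edge
  collapse ties break to the lowest edge index. Determinism end to end
  under a fixed seed is a test invariant, including byte-identical CLI
  ANOVA output.

## Known limitations

* Registration is local; there is no global (feature- or RANSAC-based)
  initialisation. Landmarks or a rough manual pre-alignment are required
  when pose differs grossly.
* Point-to-plane ICP, non-rigid registration, hole filling, and
  remeshing are out of scope.
* The ANOVA module is univariate permutation ANOVA on a response column;
  it is not a distance-matrix PERMANOVA over arbitrary dissimilarities,
  and it fits main effects only.
* A pairwise comparison quantifies similarity against the references it
  is given; in isolation it neither supports nor rejects a taxonomic
  assignment.
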