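---
title: "Region-based statistical shape models of bone surfaces: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Region-based statistical shape models of bone surfaces}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rssm)
```

# The model

A statistical shape model (SSM) describes a cohort of corresponded
surfaces by a mean and a small set of orthogonal variation modes,

$$x = \bar{x} + \sum_i w_i \Phi_i,$$

where $x$ stacks the $3V$ vertex coordinates of one surface
(vertex-major, millimetres), $\bar{x}$ is the coordinate-wise mean of
the aligned training set, and $(\Phi_i, \lambda_i)$ are the
eigenvectors and eigenvalues of the training covariance. With $n$
training shapes at most $n-1$ modes are identifiable, because the
centred coordinate matrix has rank at most $n-1$. We use the
$1/(n-1)$ covariance convention so that $\lambda_i$ is the unbiased
variance of the training weights along mode $i$ and
$w_i = \pm 2\sqrt{\lambda_i}$ spans the conventional $\pm 2$SD shape
interval.

The package fits this model in two forms on the same aligned cohort:

* **nrSSM** (nonregion-based): one PCA over all vertex coordinates.
* **rSSM** (region-based): the surface is partitioned into regions by
  the sign of the smoothed Gaussian curvature, and one *independent*
  PCA is fit to each region's coordinates. Regional modes quantify
  local variation without averaging it against the rest of the bone.

For model-level comparison the regional modes are pooled across regions
and sorted by variance; cumulative-variance fractions are taken
relative to the total pooled variance. Pooling is a declared
convention of this package: when regions are analysed independently
there is no single canonical way to merge their spectra, and the pooled
ordering has the convenient property that a one-region partition makes
every rSSM output collapse exactly to its nrSSM counterpart (a
reduction identity the test suite asserts). For whole-bone $\pm2$SD
synthesis of a pooled mode, the mode's own region is perturbed and all
other regions stay at their mean; region boundaries are not blended,
which can leave a visible step at the boundary — acceptable for
variance bookkeeping, but worth remembering when interpreting
synthesized meshes near boundaries.

# Pipeline and its parameters

`runPipeline()` executes, in order:

1. **Template selection** (`selectTemplate`): every mesh is rigidly
   registered to every other with coherent point drift (CPD) and the
   subject minimizing the mean post-registration RMS nearest-point
   distance becomes the template (ties: lowest index). The mean RMS of
   the winner is reported in the log and the report so the cohort's
   template fit can be inspected.
2. **Correspondence** (`establishCorrespondence`): the template is
   rigidly registered onto each subject and each template vertex is
   placed at its exact closest point on the subject's surface
   (point-to-triangle projection). This is the simplest well-defined
   dense correspondence consistent with a rigid-only pipeline;
   non-rigid warping is intentionally out of scope. Cohorts that are
   corresponded by construction (the synthetic generator) may set
   `correspondence = "identity"`.
3. **Alignment** (`generalizedProcrustes`): iterative rigid alignment
   to the evolving consensus mean until the mean stabilises
   (RMS change < 1e-8 mm). Rotation and translation only — no
   scaling — so size differences remain in the data and are expected to
   surface as the leading mode. The alignment objective (sum of squared
   deviations from the consensus) is non-increasing by construction,
   and rigid alignment preserves each shape's centroid size exactly.
   A `skipGPA` flag models the cohort in the template frame instead,
   for pipelines that treat template registration as the final
   alignment.
4. **Region partitioning** (`gaussianCurvature`, `partitionRegions`)
   on the template, transferred to all subjects positionally (valid
   because correspondence makes vertex $i$ the same anatomical
   location everywhere).
5. **Model fitting, synthesis and comparison** (`fitSSM`, `fitRSSM`,
   `sdModel`, `distanceMap`, `compareCumulativeVariance`,
   `curvatureComparison`).

Registration parameters: CPD runs EM over a Gaussian mixture with a
single isotropic variance, rigid updates via SVD of the weighted
cross-covariance, defaults `maxIter = 100`, `tol = 1e-6` (relative
change of the negative log-likelihood), outlier weight 0. These are
the standard CPD defaults; the algorithm is deterministic given its
inputs. Non-convergence at `maxIter` is flagged, not thrown. Full
vertex sets are registered (no subsampling) at the problem sizes this
package targets.

# Discrete Gaussian curvature and regions

Curvature uses the angle-deficit discretization: at vertex $v$,
$\kappa_v = (2\pi - \sum_f \theta_{f,v}) / A_v$ with $\theta_{f,v}$
the incident face angles and $A_v$ the mixed vertex area (Voronoi
cotangent area for non-obtuse triangles; the standard obtuse fallback
of half/quarter face areas otherwise). Because the deficits alone
telescope over a closed mesh, the discretization satisfies
Gauss–Bonnet *exactly* up to floating error:
$\sum_v \kappa_v A_v = 2\pi\chi$. The tests assert this at 1e-6
relative on every closed fixture, the analytic value $1/r^2$ on a
sphere within 2%, and the $1/s^2$ scaling law under uniform scaling.

Region partitioning follows the concave/convex dichotomy: positive
smoothed curvature (convex caps, flares) versus non-positive (saddle
transitions; exact zeros join the non-positive region so the rule is
deterministic). Raw angle-deficit curvature is sign-noisy at mesh
resolution, so the field is first smoothed by `smoothingRounds = 3`
passes of one-ring area-weighted averaging, and connected components
smaller than 1% of the vertices are flipped to the surrounding label.
Both defaults favour a small number of large coherent regions — the
intended two-region anatomy — over speckle; smoothing never flips a
vertex whose entire one-ring shares its sign, and partitioning is
idempotent on the smoothed field. A surface whose smoothed curvature
has a single sign (a sphere) yields one region and a warning rather
than an error. The default configuration therefore produces $R = 2$
regions; $R$ is not forced, it emerges from the sign structure.

# The synthetic cohort generator

No bone-surface cohort ships with the package, so validation runs on a
synthetic population with known ground truth (`samplePopulation`). The
template (`buildTemplate`) is a closed genus-0 surface of revolution
along $z$ (distal $= +z$): 45 mm between end rings, base radius 7 mm
tapering to a 4 mm mid-shaft and widening to a 6 mm distal head, with
2 mm rounded cap apices. The $C^1$ cosine-squared radius profile makes
the flare-to-shaft transitions saddle-shaped and the caps convex — the
two-region sign structure the partitioner expects of a metacarpal-like
bone.

Each subject is the template deformed by four independent zero-mean
Gaussian latent modes, then corrupted and misaligned:

| mode     | action                                                     | default sd |
|----------|------------------------------------------------------------|-----------:|
| size     | all coordinates scaled by $e^w$                            | 0.05 |
| width    | radial distance from the long axis scaled by $1 + w$       | 0.05 |
| torsion  | rotation about the long axis ramping 0 → $w$ (mid-shaft → distal tip) | 6° |
| bending  | rigid rotation of the distal half about a transverse axis at mid-shaft | 4° |
| —        | isotropic vertex noise                                     | 0.05 mm |
| —        | rigid misalignment (rotation angle / translation per axis) | 10° / 5 mm |

The defaults describe what a skeletal morphometrics practitioner would
call a realistic healthy cohort: a ~5% coefficient of variation in
overall bone size, comparable relative width variation, and a few
degrees of torsion/bending — enough for size to dominate the variance
(mirroring the usual finding that the leading PC of un-scaled bone
SSMs is size) while the remaining modes stay individually resolvable.
The cohort size defaults to 31 with seed 20230001; the template
resolution defaults to 24 axial × 16 circumferential rings
(386 vertices, ~1.9 mm spacing), which keeps the all-pairs template
registration at desk scale while resolving the curvature sign
structure.

What the generator does *not* emulate: real metacarpals are not
surfaces of revolution (no asymmetric articular facets), CT
segmentation noise is spatially correlated rather than iid, and real
cohorts contain correspondence error that the shared-connectivity
construction sidesteps unless the projection-based correspondence
stage is exercised. Passing tests therefore demonstrate the
*machinery* — registration, correspondence, curvature, PCA,
bookkeeping — under controlled truth, not anatomical fidelity.

Two identifiability caveats, visible in the package's own validation:
the size and width displacement fields overlap (widening a bone also
moves every surface point outward), so at moderate cohort sizes PCA
can mix these two modes and the per-mode weight correlation for the
weaker of the pair fluctuates with the sampling seed (typically
0.8–0.99 at $n = 200$). And with bending/torsion active, rigid
alignment legitimately absorbs a few degrees of the deformation, so
misalignment-recovery tests use mode-free cohorts where the generating
transforms are an exact oracle.

# Numerical choices

* **PCA** is computed from the thin SVD of the centred $n \times 3V$
  matrix — the memory-light dual of the covariance eigendecomposition
  and exactly equivalent to it (asserted against a dense
  `eigen(cov(X))` oracle at 1e-8). Mode signs are fixed by making each
  column's largest-magnitude entry positive, since PCA signs are
  otherwise arbitrary and would break bit-reproducibility.
* **CPD E-step** uses a clamped single-precision polynomial
  exponential (relative error ~2e-6) and skips kernel terms below
  $e^{-25}$; both perturbations are orders of magnitude below the EM
  soft-assignment scale, and in the noiseless limit the assignments
  harden so pose recovery stays at machine precision (~1e-15).
  The mixture variance is floored at 1e-14 of the data scale; two
  consecutive floored iterations terminate the EM (exact-match
  collapse).
* **Zero-variance modes**: a mode variance below $10^{-12}$ of the
  mean-shape scale is treated as floating-point dust; $\pm k$SD
  synthesis then returns the mean with a warning, so degenerate
  cohorts (identical meshes) flow through the whole pipeline.
* **Ties**: template selection breaks RMS ties by lowest index;
  curvature zeros label as non-positive; pooled regional modes with
  equal variance order by region then local index. Every tie-break is
  deterministic, and the pipeline is bit-reproducible from config +
  seed (the generator saves and restores the caller's RNG stream).
* **STL reading** merges duplicate facet vertices by *exact*
  coordinate equality, not tolerance, so round-trips are
  deterministic; PLY writes double-precision coordinates (binary
  little-endian or full-precision ASCII) and round-trips bit-exactly.
  Vertex order is never changed by I/O, because correspondence is
  positional downstream.

# Problem sizes

The shipped validation runs at the study scale: 31-subject cohorts at
386 vertices for the end-to-end pipeline (≈45 s, dominated by the
$31 \times 30$ template-selection registrations), 2000-point clouds
for registration accuracy, 200-subject cohorts for latent-mode
recovery, and 20 random small cohorts ($V \le 200$, $n \le 20$)
for the PCA oracle. These sizes were chosen so the whole suite
completes in minutes on one CPU while every quantity is computed, not
stored.

# Known limitations

* Correspondence is rigid CPD plus closest-point projection; strongly
  differing shapes (beyond the generator's mode range) would need
  non-rigid correspondence, which is out of scope.
* Exactly two regions emerge from the curvature sign on the default
  template; finer parcellations (e.g. six anatomical regions) would
  require a different partitioning criterion than sign alone.
* No hypothesis testing on mode weights is provided; the comparison
  tables are descriptive.
* The rSSM ±2SD synthesis does not blend region boundaries.
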