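# rssm: region-based statistical shape models for bone surfaces

`rssm` builds statistical shape models (SSMs) of triangulated bone
surfaces and compares the classical whole-surface model (nrSSM) with a
region-based variant (rSSM) in which independent PCA models are fit to
surface regions delineated automatically by the sign of the Gaussian
curvature. The target application is skeletal morphometrics — e.g.
quantifying the dominant shape variations (size, width, torsion,
bending) of the first metacarpal across a cohort of CT-derived bone
surfaces — where localized models can attribute variation to anatomical
regions such as the convex articular heads versus the saddle-shaped
metaphyseal flares.

The core model is the linear point-distribution model over corresponded
vertex coordinates

    x = x̄ + Σᵢ wᵢ Φᵢ

where `x` is a flattened 3V-vector of vertex coordinates, `x̄` the
consensus mean after rigid generalized Procrustes alignment (no scaling,
so size stays in the model), and the orthonormal modes `Φᵢ` with
variances `λᵢ` come from PCA of the training coordinates (at most
`n − 1` modes for `n` training shapes). `wᵢ = ±2√λᵢ` gives the ±2SD
shapes used for distance maps and curvature comparison. The rSSM fits
one such model per curvature-sign region; its modes are pooled and
sorted by variance for model-level comparison.

The pipeline stages are: mesh I/O (PLY/STL/OBJ) → template selection by
all-pairs rigid coherent point drift (CPD) registration → dense
correspondence by closest-point projection of the template → rigid
generalized Procrustes alignment → angle-deficit Gaussian curvature and
sign-based region partitioning → nrSSM and rSSM fitting → ±2SD
synthesis, per-vertex distance maps, cumulative-variance and curvature
comparison tables. A seeded generator of metacarpal-like synthetic
cohorts with known latent modes provides ground truth for validation.

## Worked example

```r
library(rssm)

# a 31-subject synthetic cohort with known latent modes
cfg <- populationConfig()        # 31 subjects, seed 20230001
report <- runPipeline(cfg, outDir = "results/run")
show(report)
```

which prints (stage timings elided):

```
ComparisonReport
  template: subject 23 (mean RMS 0.6558 mm)
  cumulative variance (%):
 component    nrSSM     rSSM
         1 57.34617 41.84612
         2 74.24563 58.87515
         3 89.05199 71.57067
         4 92.42080 80.42774
         5 94.58354 88.32450
         6 95.59347 91.33031
```

Reading the output: subject 23 minimized the mean post-registration RMS
to the rest of the cohort and served as template; the first nrSSM mode
(dominated by the size factor of the generator) carries 57% of the
total variance, and six modes carry >95%. The rSSM curve pools the
modes of the two curvature regions (convex caps/flares vs the saddle
waist), so its leading components are region-local. `report` also
holds per-mode ±2SD distance-map summaries and Gaussian-curvature
tables; `outDir` receives the mean and ±2SD meshes (PLY), per-vertex
curvature/labels (CSV), all tables (CSV) and `report.json`.

Individual stages are exported — `readMesh()`, `cpdRigid()`,
`selectTemplate()`, `establishCorrespondence()`,
`generalizedProcrustes()`, `gaussianCurvature()`, `partitionRegions()`,
`fitSSM()`, `fitRSSM()`, `sdModel()`, `projectShape()`,
`distanceMap()` — and a thin command-line front end lives at
`inst/scripts/rssm.R` (`run`, `simulate`, `curvature`, `compare`).

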