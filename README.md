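# geograd

Gradients of connectivity distance on cortical surface meshes.

A recurring organizational principle of the primate cortex is that the
further a region lies from primary sensory-motor cortex, the more distant —
measured along the cortical sheet — the regions it connects with.
`geograd` implements the complete analysis chain for testing this gradient
on triangulated surface meshes, for two complementary measures of
connectivity, together with a synthetic-data module that makes every stage
testable end to end without any external downloads.

**Who it is for:** researchers analyzing surface-based functional
connectivity (resting-state fMRI projected to a hemisphere mesh) and/or
weighted retrograde tract-tracing connectomes (labeled-neuron counts per
injection, as in the macaque M132-atlas databases), who want the
connectivity-distance gradient analysis as tested, reusable R functions.

## The measures and models

For vertices v, u on a mesh, let d(v, u) be the geodesic (on-surface)
distance in mm, computed by Dijkstra's algorithm on the mesh edge graph
augmented with triangle-pair unfolding edges (median error ≈ 1.4% against
analytic great-circle distances on a sphere mesh).

* **Functional connectivity distance** of vertex v: mean of d(v, u) over
  the top 2% of vertices u by Pearson correlation with v's time series
  (node-wise threshold, self excluded; frames with framewise displacement
  above 0.2 mm are censored first). Maps are averaged across subjects,
  then across each atlas area's vertices.
* **Structural connectivity distance** of a tracer injection: the
  labeled-neuron-count-weighted mean geodesic distance from the injection
  site to the centroids (geodesic medians) of its extrinsic source areas:
  `sum_a n_a d(site, c_a) / sum_a n_a`.
* **Gradient GLM:** connectivity distance ~ geodesic distance from the
  closest primary-area border (functional: 91 areas, residual df 89;
  structural: 29 injections plus region-size and geometric-centrality
  covariates, residual df 25). Outliers are flagged at |externally
  studentized residual| > 2.
* **Anchor searches:** distance-from-random-anchor-set GLMs, either
  sampled (per-vertex mean signed R² over sets containing the vertex) or
  optimized by 1-mm hill climbing with restarts (per-vertex count of
  membership in final stable sets, split by the sign of the relationship).

## Worked example

The `analysis/` scripts run the whole study on synthetic data with a
planted gradient (β_true = 0.3 mm/mm, anchored at 4 designated primary
areas on a 2,562-vertex sphere):

```sh
Rscript analysis/01_simulate.R
Rscript analysis/02_functional_cd.R
Rscript analysis/03_structural_cd.R
Rscript analysis/04_anchor_search.R
```

which prints (stage 2 and 3 excerpts):

```
functional gradient: F(1, 89) = 953.6, R2 = 0.91; beta = 0.110 mm/mm (t = 30.9, p = 2.4e-49)
outlier areas (|studentized residual| > 2): 3, 16, 36
structural gradient: F(3, 25) = 74.40, R2 = 0.90; beta = 0.364 mm/mm (t = 12.4, p = 3.8e-12)
```

Reading the numbers: both measures of connectivity distance increase with
distance from the primary-area borders — the planted gradient is recovered
with the expected model shapes (F(1, 89) functional, F(3, 25) structural).
The fitted functional slope is attenuated relative to β_true because only
part of each vertex's top-2% correlates are long-range partners; the
structural slope is close to β_true plus the geometric growth of centroid
distances. Stage 4 then localizes the anchors without assuming them:

```
random search (2000 samples, 0 degenerate skipped): peak vertex 835, 0.0 mm from the nearest primary area
hill climbing (100 restarts, 0 failed): peak vertex 2054 included in 17 stable sets, 0.0 mm from the nearest primary area
```

Equivalent calls in R, starting from your own data:

```r
library(geograd)
mesh <- read_surface_csv("vertices.csv", "faces.csv")   # or read_gifti_surface()
parc <- read_labels_csv("labels.csv", "label_names.csv")
fun  <- run_functional_pipeline(mesh, parc, subjects, primary = c("V1", "Core", "3", "F1"))
print(fun$glm)
recs <- read_tracer_csv("tracer_counts.csv", "injection_sites.csv", parc)
stru <- run_structural_pipeline(mesh, parc, recs, primary = c("V1", "Core", "3", "F1"))
flag_outliers(stru$glm)
```

## Layout

* `R/`, `src/` — the package: mesh geometry and geodesics, functional and
  structural connectivity distance, gradient GLMs, anchor searches, the
  synthetic-data generator, CSV/GIFTI readers and writers, run manifests.
* `analysis/` — numbered driver scripts for the full synthetic study;
  outputs under `results/`.
* `tests/testthat/` — unit, property and end-to-end suites, with
  independent brute-force oracles in `helper-fixtures.R`.
* `vignettes/connectivity-distance-gradients.Rmd` — the methods vignette:
  model and measure definitions, design decisions, generator assumptions,
  numerical choices, limitations.
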