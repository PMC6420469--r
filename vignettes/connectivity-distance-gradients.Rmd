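---
title: "Connectivity-distance gradients on cortical surface meshes: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Connectivity-distance gradients on cortical surface meshes: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The question and the quantities

A recurring organizational principle of the primate cerebral cortex is that
the further a region lies from primary sensory-motor cortex, the more
distant — along the cortical sheet — the regions it is connected with.
`geograd` implements the full analysis chain for testing this *gradient of
connectivity distance* on triangulated cortical surface meshes, for two
complementary measures of connectivity:

* **Functional connectivity distance** (`fc_distance_map()`): for each
  surface vertex, correlate its BOLD-like time series with every other
  vertex (Pearson product-moment), keep the top 2% most correlated vertices
  (a node-wise threshold, so that nodes with globally weaker correlations
  are not penalized), and average the geodesic distances to them. Maps are
  averaged across subjects first and across the vertices of each atlas area
  second (`aggregate_maps()`); the order matters when vertices are missing
  and is fixed.
* **Structural connectivity distance** (`sc_distance()`): for each
  retrograde tracer injection, the mean geodesic distance from the
  injection site to its labeled (projecting) neurons. Since individual
  neuron positions are not recorded, each source area's centroid — the
  geodesic median of its vertices — stands in for its neurons, making the
  measure the labeled-neuron-count-weighted mean centroid distance.
  Intrinsic neurons (those within the injected area) are excluded, which
  makes the measure invariant to the overall count scale but biased upward
  for large areas — hence the region-size covariate below.

The spatial predictor for both is the **geodesic distance from the closest
border of a primary area** (`distance_from_region_borders()`): primary
visual, auditory, somatosensory and motor cortex in the real macaque data;
four designated anchor areas in the synthetic data. Vertices inside a
primary area are assigned distance 0 rather than a signed (negative)
distance, so the gradient is anchored *at* primary cortex and the predictor
is defined everywhere.

## Geodesic distances

All distances are shortest paths constrained to the cortical surface, in
millimetres. The implementation is Dijkstra's algorithm (via igraph) on the
mesh edge graph augmented with *unfolding* edges: for every interior edge,
the two triangles sharing it are rotated into a common plane and the two
opposite vertices are joined by their planar straight-line distance
whenever that segment crosses the shared edge. These face-crossing edges
let paths cut across triangles instead of zig-zagging along the lattice.
The accuracy contract is stated on a sphere, where the truth is the
analytic great-circle arc: on an order-4 icosphere the median relative
error over random vertex pairs must be at most 3%; the augmented graph
achieves about 1.4% (the plain edge graph fails at about 7%, which is why
it is not acceptable here). An exact polyhedral-geodesic algorithm would
push the error to zero but adds substantial implementation surface for no
benefit at the mesh resolutions used; the contract, not the algorithm, is
what downstream results depend on.

Meshes must be a single connected component — one hemisphere at a time —
and this is enforced at construction rather than letting infinities
surface mid-pipeline. All vertex indices are 1-based inside R; the CSV and
GIFTI interchange formats use 0-based indices, converted on read/write.

## The gradient models

`fit_glm()` is ordinary least squares with the full reporting surface the
analyses need: raw-unit coefficients (mm of connectivity distance per mm of
distance from primary cortex) with standard errors, t statistics, two-sided
p values and 95% confidence intervals; standardized coefficients alongside
(the analysis literature is often ambiguous about which scale a printed
beta is on, so both are exposed and labelled); the omnibus F with its
degrees of freedom; R²; and externally studentized residuals.

The **functional model** regresses the 91 per-area mean connectivity
distances on the per-area mean border distance: one predictor plus
intercept, residual df = 89. The **structural model** regresses the 29
per-injection connectivity distances on the site's border distance plus two
covariates of no interest — the injected region's vertex count (the
intrinsic-neuron exclusion mechanically inflates connectivity distance for
large areas) and the site's geometric centrality, its mean geodesic
distance to all vertices (peripherally placed sites have longer distances
to everything) — residual df = 25. A covariate that is constant across
injections is dropped with a warning instead of failing the fit; a
rank-deficient design is an error.

Outliers are observations with |externally studentized residual| > 2.
"Studentized" is ambiguous between the internal and external variant;
the external one is used because each observation is scaled by a fit that
excludes it and follows an exact t distribution, and the tests pin it to an
explicit leave-one-out refit oracle. With perfectly collinear data the
residual standard error collapses and raw studentized residuals become
numerical noise; the implementation reports them as zero in that case (no
observation deviates from a perfect fit).

## Hypothesis-free anchor search

Both searches ask whether some *other* set of cortical locations anchors
the structural gradient better than primary cortex. A candidate anchor set
replaces the predictor by each site's geodesic distance to the nearest
anchor, keeping the covariate structure; the statistic is the signed
variance explained, sign(distance coefficient) × R². The sign convention
separates "connectivity distance grows away from these anchors" (positive)
from the inverse relationship (negative). The objective optimized during
hill climbing is |signed R²|, with the sign reported — whether the original
analysis optimized raw or signed variance explained is ambiguous, and
optimizing the magnitude finds both kinds of anchor while the sign
disambiguates them afterwards.

* `random_anchor_search()` draws anchor sets of size uniform in 3–5
  (distinct vertices) and maps each vertex's mean signed R² across the
  samples that contained it. Samples whose predictor is degenerate (all
  sites equidistant) are skipped and counted.
* `hill_climb_search()` starts from a random set and repeatedly accepts the
  single best strictly-improving move of one anchor to a candidate vertex,
  stopping at a stable set. Coordinate ascent (one anchor per iteration)
  was chosen over simultaneous moves because it makes the accepted-move
  sequence well defined and the objective trajectory provably monotone; the
  monotonicity is asserted per restart in the tests. Candidate moves are
  vertices within 1 mm geodesic offset; at mesh resolutions where edges are
  longer than the step (the default sphere has ≈2 mm edges) the candidate
  set falls back to the full 1-ring of mesh neighbours — the minimal moves
  the mesh admits. A literal "single nearest neighbour" fallback would
  leave one move direction per anchor and stall the search. Ties keep the
  incumbent; a restart exceeding the iteration cap is recorded as failed.
  The map counts final-set membership per vertex, split by the sign of the
  final signed R².

With several true anchors planted far apart, the two procedures can
legitimately peak on *different* members of the anchor set; consistency
between them is therefore checked as "each peak lies within 10 mm of the
planted anchors, and the hill-climb peak lies within 10 mm of the random
map's top vertices", not as literal peak-to-peak distance.

Scaled-down defaults (2,000 samples / 100 restarts) are used in the
analysis scripts and tests; the full-scale analysis (100,000 samples /
1,000 restarts) is a parameter change away and scales linearly.

## The synthetic study

`simulate_dataset()` generates everything the pipeline consumes, with known
ground truth. The defaults define the study conditions and mirror the
real-data design sizes: an order-4 geodesic icosphere (2,562 vertices,
radius 30 mm — the scale of a macaque hemisphere) carved into 91
geodesic-Voronoi areas; 4 primary areas chosen by farthest-point sampling
so they are widely spaced like the primary fields; 10 subjects × 2 scans ×
250 timepoints; 29 tracer injections.

**Time series.** Each subject's series follow a signal model chosen so that
the planted effect is a gradient of *connection length*:
x_v = f_v + w·f_p(v) + √ε·η_v, where f is a Gaussian field with local
exponential covariance exp(−d/λ0), p(v) is a long-range partner at geodesic
offset ρ(v) = ρ0 + β_true·dist_primary(v) in a random (seeded) tangent
direction, and η is white noise. The implied covariance
(I + wP) S (I + wP)ᵀ + εI is positive semidefinite by construction, so
sampling needs one Cholesky factorization of S. Two design points deserve
emphasis. First, the naive alternative — making the *decay length* of a
monotone distance kernel grow with distance from primary cortex — cannot
plant this effect through a rank-based top-k threshold: the k strongest
correlates of a row-monotone kernel are always the k nearest vertices, and
after the symmetrization any valid covariance requires, vertices *near*
primary cortex inherit the far zone's long-range correlations, inverting
the intended gradient (we measured exactly this inversion before adopting
the partner model). Second, the partner directions must be isotropic: an
early implementation displaced all partners along meridians toward a fixed
pole, and that global axis imprinted a systematic large-scale texture on
the null (β_true = 0) maps — visible as fixed-design null t statistics
clustering at a nonzero value — which is incompatible with the generator's
contract that the null map be flat up to noise. Random per-vertex
directions drawn from the dataset seed restore isotropy; under the null
the slope's 95% CI covers zero at nominal rates.

**Tracer counts.** Counts for extrinsic areas are
Poisson(N0·exp(−d(site, centroid)/λ(site))) with
λ(site) = λ0 + β_true·dist_primary(site): the exponential decay of
connection strength with distance, with a decay length that grows away
from primary cortex. Here the decay-length mechanism works as intended
because the weighted-mean measure uses the counts' *values*, not their
ranks. An injection drawing all-zero counts (possible at tiny N0) is
redrawn with a doubled scale, with a message.

**Defaults and units.** λ0 = 5 mm matches the space constant of the
exponential distance rule reported for macaque cortico-cortical
connectivity; ρ0 = 5 mm is a baseline partner offset so even primary-area
vertices have some long-range coupling; w = 0.8 keeps partner correlations
below local ring correlations (patches supplement, not replace, local
coherence); ε = 0.2 is measurement noise; β_true = 0.3 mm/mm plants a
gradient that is unambiguous at the study size (recovered functional slope
≈ 0.11 mm/mm after attenuation through the top-k mixture; tracer slope
≈ 0.4); N0 = 1000 expected neurons at zero distance. Framewise
displacement is gamma-distributed with per-frame mean 0.06 mm, so a small
fraction of frames (a handful per 500) exceeds the inclusive 0.2 mm
censoring threshold — matching the lightly-moving awake-scan regime the
censoring rule was designed for, where mean FD sits well below the
threshold. All stage seeds derive from one top-level seed; every
generator is bit-reproducible given it.

**What the generator does not emulate.** Folded cortical geometry (the
sphere has no sulci, so geodesic and Euclidean orderings differ less than
on real cortex), hemodynamics and scanner noise spectra, laminar tracer
biology, inter-subject anatomical variability (all subjects share one
mesh), and inter-areal heterogeneity beyond the planted gradient. Passing
tests therefore certify the *computational chain* — measures, models,
searches recover what was planted under realistic sizes and noise — not
that real cortex follows the gradient.

## Numerical choices

* Correlation matrices are computed by standardized `tcrossprod` (BLAS);
  equality with the textbook formula is pinned in tests. Zero-variance
  vertices are excluded with a warning and propagate as missing through
  maps and parcel means; an area losing all vertices is reported missing,
  not zero.
* The node-wise threshold keeps k = round(q·(N−1)) targets (self excluded,
  floor of one); ties at the cutoff resolve to the lower vertex index, so
  maps are deterministic. Because only correlation ranks enter, the map is
  invariant under strictly increasing transforms of the correlations —
  also pinned in tests, and the reason no Fisher z transform is applied.
* Area centroids are geodesic medians with ties broken by lowest vertex
  index; centroid computations reuse one cached all-pairs distance matrix.
* Frame censoring is inclusive (FD ≤ threshold keeps the frame) and applied
  per scan before concatenation.
* The per-criterion simulation sizes used by the test suite — 50 seeded
  runs per recovery arm, 1,000 null simulations for calibration, 2,000
  random samples and 100 restarts for the searches — were chosen as the
  smallest sizes at which the binomial uncertainty of the pass rates is
  well below the margins being asserted.

## Known limitations

* Inference is plain OLS, as in the analyses this package implements;
  spatial autocorrelation of surface maps is not corrected for (no spin
  tests), so p values on smooth real-world maps will be somewhat
  anti-conservative. The synthetic null keeps nominal coverage because its
  planted structure is isotropic.
* The geodesic approximation is a graph metric; its ~1–3% error is
  negligible relative to the effects studied but is not exact.
* The hill climb is a local optimizer with restarts; it makes no global
  optimality claim — which is precisely why the restart-count map, not any
  single run, is the result.
* Injection sites are snapped to the nearest mesh vertex; the snap distance
  is available and should be checked when importing real coordinate data.
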