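---
title: "Statistical parametric mapping of organ surface shape with meshspm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Statistical parametric mapping of organ surface shape with meshspm}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(meshspm)
```

## The model

meshspm analyses local organ shape on *corresponded* triangle meshes: every
subject's surface shares the template's vertex count and face topology, so
vertex `v` refers to the same anatomical location in every subject. The
per-subject phenotype is the signed surface-to-surface (S2S) distance

\[
s_i(v) \;=\; \pm\,\lVert x_i(v) - \bar x(v) \rVert,
\]

the Euclidean distance between subject vertex `x_i(v)` and template vertex
`x̄(v)`, signed by the projection of the displacement onto the template's
outward vertex normal: positive for outward expansion, negative for inward
shrinkage. The sign convention is one of two defensible choices (the other
being a pure normal projection for the magnitude as well); we keep the
Euclidean magnitude because it stays honest when registration leaves a
tangential component, and the two coincide exactly for normal-direction
deformations — which is the regime of the synthetic generator, making the
ground truth analytically known. The alternative is a one-line change in
`s2s_distance()`.

At every vertex the same linear model is fitted (mass univariate
regression),

\[
s_i(v) = \beta_0(v) + \textstyle\sum_k \beta_k(v)\, x_{ik} + \varepsilon_i(v),
\]

sharing one pseudoinverse across vertices. Three nested covariate models
are built by `build_design()`: model 1 (age, sex, ethnicity, BMI, WHR,
liver fat as PDFF, liver iron), model 2 (plus AST:ALT, FIB-4, liver
disease, type-2 diabetes, optionally the four disease interactions
age x disease and PDFF x disease, with products formed after centering the
continuous partner), and model 3 (plus scan hour-of-day indicators).
Standardised coefficients (per SD of the covariate) are kept alongside the
native mm-per-unit maps.

## TFCE, permutation and FDR

t-maps are spatially enhanced with threshold-free cluster enhancement:

\[
\mathrm{TFCE}(v) = \sum_{h} e(v,h)^{E}\, h^{H}\, \Delta h ,
\]

where `e(v, h)` is the extent of the edge-connected component of
`{u : t(u) >= h}` containing `v`. We use the canonical exponents `E = 0.5`,
`H = 2` and 100 equal threshold steps up to `max(|t|)`; negative values are
enhanced on `-t` and subtracted, so the output is signed. Extent is
area-weighted by default (summed barycentric vertex areas), which makes
the statistic invariant to mesh resolution; a vertex-count mode is kept
because it is the natural unit for brute-force verification.

Inference uses Freedman–Lane permutation per covariate of interest: the
nuisance-only model is fitted, its residual rows permuted, pseudo-data
reconstituted, and the full-model TFCE map recomputed; the two-sided
p-value at a vertex counts permuted `|TFCE|` values at least as large as
the observed one, with the observed map included so p is never 0. Vertex
p-values are Benjamini–Hochberg adjusted separately per covariate, and the
significance mask is `q < alpha` (default 0.05). We read captions of the
form "significant (p < 0.05) after adjustment" as referring to the
FDR-adjusted quantity, which is what the mask implements. Sign-split
significance areas report the percentage of vertices significant with
negative and positive coefficients, with median (IQR) of the coefficient
over each significant sign subset — the subset convention matches the
split-by-sign presentation; a flag to summarise over all vertices instead
would be a trivial extension of `significance_area()`.

Permutation streams are derived deterministically from one master seed per
covariate, so results are reproducible and independent of the order in
which covariates are tested.

## The synthetic cohort generator

Because the motivating population data are access-controlled, every stage
is exercised on synthetic cohorts with known ground truth. The template is
a deterministic liver-like surface: a UV-sphere triangulation (vertex
count within 10% of the requested target; ~2,000 by default, ~18,000
supported) radially mapped to a superellipsoid with semi-axes 85, 60 and
45 mm plus two to three seeded lobe protrusions. Covariates mimic a
middle-aged imaging cohort (age 44–82, ~49% male, ~98% ancestry-indicator
positive, BMI ~27 correlated with WHR, log-normal PDFF elevated under T2D,
FIB-4 derived from simulated AST/ALT/platelets so its positive age
correlation arises from the formula itself), with disease prevalences
0.013 (liver disease) and 0.053 (T2D).

Ground-truth effect maps are geodesic-radial bumps with per-unit
amplitudes taken from the magnitudes the method is expected to resolve:
age −0.11 mm/yr, BMI +0.30 mm/unit and PDFF +0.26 mm/% as broad fields
(140 mm geodesic radius), T2D +2.4 mm and liver disease −2.1/+1.95 mm as
regional fields (55 mm), PDFF×T2D +0.10 mm/% and age×T2D −0.03 mm/yr.
The bump kernel is flat over the inner half radius and cosine-tapers to
exactly zero at the radius. We chose this Tukey-style kernel over a
Gaussian so that "support" — the set of vertices with non-zero effect,
recorded exactly — means the region where the effect is practically
present; a Gaussian tail would make support recovery ill-posed at its
fringe regardless of sample size.

Subjects displace template vertices along the outward normal by the linear
combination of effect maps plus spatially correlated Gaussian noise
(white noise smoothed on the mesh graph, rescaled to a 2 mm marginal SD,
correlation length 15 mm; the iteration count maps the correlation length
onto the mean edge length, an approximation adequate at these scales).
Purely vertex-independent noise would make cluster enhancement trivially
powerful; smooth noise produces false clusters and genuinely stresses the
permutation inference. Because displacement is purely normal, the S2S
field recomputed from the generated meshes equals the constructed
displacement to numerical precision — this validates the sign convention
on the generator's regime and is asserted in the tests.

What the generator does *not* emulate: registration error and its spatial
correlation structure, segmentation artefacts (beyond a QC-testing outlier
switch), non-normal tangential deformation, and covariate measurement
error. Passing tests therefore demonstrate correctness of the statistical
machinery under the stated model, not robustness to real-data artefacts.

## Quality control

`apply_qc()` applies a fixed exclusion order: missing required covariates;
liver volume outside the `[0.1%, 99.9%]` cohort quantiles (always flagged
in the report; excluded when `auto_exclude_volume` is set — an automated,
logged surrogate for visual review, which cannot be reproduced
deterministically); and any vertex S2S outside a plausibility window of
[−60, +80] mm, chosen to bracket the plausible organ range with margin.
Quantile thresholds are resolved to absolute numbers and echoed in the
report, so re-applying the resolved rules to QC output is a no-op — a
data-dependent quantile rule re-applied naively is never idempotent.
Quantiles use the inverse-ECDF definition (type 1), which at small n
flags nothing, matching the intent that only genuine extremes are
reviewed.

## Disease prediction

Cases are matched 1:1 to controls under hard calipers (age ±1 yr, same
sex, BMI ±2 kg/m²) by a deterministic greedy pass ordered by scarcity
(cases with the fewest eligible controls first, each taking the eligible
control minimising |ΔBMI| then |Δage|); a reference optimal-matching
implementation was not available, and at 1:1 with hard calipers the greedy
solution is near-optimal while being exactly reproducible. Shape features
are sparse-PCA scores of the matched cohort's S2S matrix (cases and
controls fitted jointly), computed by alternating minimisation of the
variable-projection elastic-net objective with an SVD initialisation, so
zero penalties reproduce standard PCA exactly; components are ordered by
explained variance and signed so each loading's largest-magnitude entry is
positive. Default penalties are l1 = 1e-3 and ridge = 1e-6 on the centred
matrix. The mode count is the smallest K whose cumulative explained
variance reaches 90%.

Logistic models are evaluated with leave-one-out cross-validation: the
volume model uses the ten clinical covariates, the S2S model adds the
selected scores. Classes use a 0.5 cutoff (the matched cohorts are
balanced); a Youden-optimal cutoff is a one-line change. AUCs come from
the Mann–Whitney identity with DeLong confidence intervals, and the two
models are compared with DeLong's paired test. When a fold separates, it
is refitted with a 1e-6 ridge.

## Numerical choices and degenerate inputs

* Vertex normals are angle-weighted averages of incident face normals
  (robust to irregular triangulations); a zero-area one-ring is an error.
* Rigid alignment is closed-form Kabsch/Umeyama with reflections excluded;
  subjects are aligned without scaling, the scaling flag exists for
  template experiments. Generalized Procrustes means iterate align/average
  to 1e-4 mm RMS motion, at most 50 iterations.
* Isosurface extraction uses the marching-tetrahedra variant (Kuhn 6-tet
  cube decomposition) of marching cubes, which has no ambiguous cases;
  crossings sit at edge midpoints of the binary field, the volume is
  zero-padded so surfaces close, orientation is fixed by breadth-first
  traversal plus a signed-volume check. Laplacian smoothing defaults to
  10 umbrella iterations with step 0.5 (plain filter, no shrinkage
  correction), exposed in the call.
* Voxelization tests voxel centres by z-ray parity with a tiny
  deterministic ray offset to avoid edge-grazing ties; columns with an odd
  crossing count (grazing contact) are skipped.
* Zero residual variance at a vertex gets a 1e-12 SE floor and a warning
  rather than an error, so noiseless validation cohorts remain usable.
* A constant covariate column (e.g. a single-ancestry draw at small N) is
  dropped with a warning, mirroring how an unused factor level would
  disappear; genuine collinearity between varying columns is an error
  naming the columns. Interactions with a constant flag are an error.

## Problem sizes used by the test-suite and acceptance script

Unit tests run on meshes of 12–600 vertices and cohorts of 10–200
subjects. The validation suite uses: TFCE-oracle equivalence on 100 random
fields over meshes of at most 50 vertices; noiseless recovery at N = 100,
V = 1000; effect localization at the default study conditions (N = 300,
V ≈ 2000, σ = 2 mm, 500 permutations); error control over 100 null
cohorts (N = 100, V = 500, 200 permutations); a 10^5-replicate bootstrap
for the DeLong reference; 1,000 random pools for the matching audit; and
two full pipeline replicates for the determinism check. These sizes were
chosen so the whole suite completes in minutes on a single core while
leaving each check statistically meaningful.

## Known limitations

* The corresponded-mesh contract is assumed, not produced: voxel-level
  nonrigid template-to-subject registration is out of scope, and real
  cohorts must arrive already corresponded.
* At the default prevalences, a desk-scale cohort contains only a handful
  of liver-disease cases (~4 at N = 300), so rare-disease effect maps and
  disease interactions are not recoverable at that scale — population-scale
  sample sizes are precisely what makes those effects detectable. The
  localization checks document this honestly rather than enriching the
  default conditions.
* The prediction stage's synthetic demonstration enriches disease
  prevalence (a case-control design choice, as any matched study does);
  its AUCs are not comparable to population prevalence settings.
* Smooth noise is stationary over the mesh; real registration error is
  not.
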