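---
title: "Methods: WMH burden, longitudinal cortical thinning, and memory"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: WMH burden, longitudinal cortical thinning, and memory}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wmhspc)
```

This vignette is the package's own account of the models it implements,
the choices made where the underlying methodology left the design open,
and what the synthetic-data tests do and do not establish.

## The scientific question

Small-vessel cerebrovascular disease, visible as white matter
hyperintensities (WMH) on T2-FLAIR MRI, may drive cortical
neurodegeneration in an Alzheimer-like spatial pattern, and through it,
memory decline. The analysis chain that operationalizes this question
is: quantify WMH burden per lobe at baseline; measure annualized
cortical thinning between two scans per surface vertex; regress
thinning on WMH with demographic and genetic covariates under
clusterwise multiple-comparison control; then relate the surviving
clusters' mean thinning to delayed-recall memory and ask whether the
WMH–thinning association differs across racial/ethnic groups, which is
of particular interest because cerebrovascular burden is unequally
distributed across them.

## WMH segmentation

A single Gaussian N(mu, sigma^2) is fit to in-mask FLAIR intensities
and voxels with intensity **strictly greater** than `mu + z * sigma`
(default z = 2.1) are labeled. Two fitting methods are exposed because
the convention behind the 2.1 SD rule does not pin one down:

* `"moments"` (default): in-mask mean and population (1/n) SD. The 1/n
  convention matters only in toy examples; at brain-volume n the two
  denominators are indistinguishable.
* `"trimmed"`: mean/SD after removing a fraction of each intensity tail
  (default 5%), with sigma rescaled by the truncated-normal variance
  factor `1 - 2 z_f phi(z_f) / (1 - 2f)` so it estimates the
  full-distribution SD. With heavy lesion loads the hyperintense tail
  inflates the moments sigma (and thus the threshold); trimming resists
  this. The moments fit stays the default because it is the simpler
  reading of "a Gaussian fit to voxel intensity values", and because
  the inflation is conservative (it can only shrink the labeled set).

Manual editing of false positives is replaced by an automated
minimum-component-size filter (default 5 voxels at 26-connectivity)
plus an optional exclusion mask; interactive edits are not
reproducible, size filtering is. Ties exactly at the threshold are
excluded (strict inequality). Volumes are `count x voxel volume`,
reported in cm³ from the NIfTI voxel dimensions; the lobar atlas is
assumed already in subject space (identity transform) — nonlinear
coregistration is out of scope.

## Symmetrized percent change

Thinning between two timepoints is measured as

$$\mathrm{SPC} = \frac{100\,(T_2 - T_1)}{\Delta t \cdot \tfrac12 (T_1 + T_2)} \quad [\%/\text{yr}]$$

i.e. annualized change relative to the two-timepoint *average*
thickness. One printed form of this formula in the source literature
has inconsistent bracketing ("… × [1 / 0.5 × {T1 + T2}]"); we follow
the prose definition — 100 × rate / average thickness — which is also
the standard two-timepoint longitudinal convention. SPC is
antisymmetric in the timepoints, invariant to a common scale factor,
and bounded by ±200/Δt for positive thickness; all three are tested as
properties, and the package refuses nonpositive thickness or intervals.

## Vertexwise GLM and clusterwise Monte Carlo correction

At each mesh vertex, per-subject SPC is regressed by OLS on a focal WMH
volume plus the primary covariates (age, sex/gender, APOE ε4 carriage,
baseline entorhinal thickness); t = b/SE with n − k residual degrees of
freedom (no smoothness correction of df). Supra-threshold vertices at
the two-tailed cluster-forming threshold (default p < .01) are
partitioned into edge-connected components **separately for positive
and negative signs** — adjacent vertices of opposite sign never merge —
and the null distribution of the *maximum* cluster extent is taken over
both signs, the standard two-tailed clusterwise convention.

Two null generators are provided:

* `"residual-permutation"` (default): Freedman–Lane. The focal column
  is removed, reduced-model residuals are permuted across subjects and
  added back to the reduced fit, and the full model is refit. This
  inherits the data's actual spatial covariance, which matters because
  cluster sizes are driven by it.
* `"smooth-noise"`: the literal "Monte Carlo simulation" variant —
  standardized Gaussian fields smoothed on the mesh and thresholded at
  the two-tailed normal quantile. The smoothing level is estimated by
  matching the lag-1 neighbor correlation of the model residuals
  (calibrated against candidate iteration counts on the same mesh)
  unless set explicitly.

Clusterwise p uses the `(1 + #{null ≥ obs}) / (N + 1)` estimator, which
cannot return 0; fewer than 100 iterations are refused because the tail
estimate is unstable. Extent is vertex count by default; surface area
(one third of incident triangle areas per vertex) is computed alongside.
Everything is seeded and byte-reproducible.

## Association models

Cluster-mean SPC (unweighted vertex mean per subject) feeds three model
families, all classical OLS with t confidence intervals (no robust SEs,
as none were specified in the source methodology):

* **Memory**: delayed recall ~ cluster SPC + covariates + test-to-scan
  gap.
* **Interaction**: cluster SPC ~ WMH + group + group×WMH + covariates,
  with non-Hispanic White as the reference category and sex coded with
  men as reference (women's coefficients then appear as positive
  slower-thinning effects).
* **Stratified**: the same slope fit within each group; on noiseless
  data the Black-stratum slope equals main effect + Black×WMH exactly,
  which is tested.
* **Group differences**: one-way ANCOVA F tests per measure (covariates
  age, sex/gender, APOE ε4), with per-group raw means/SDs.

Standardized coefficients use β = b·SD(x)/SD(y), applied to every
non-intercept column (indicator variables included); whether one should
z-score indicators is a matter of convention, and this choice is
documented rather than hidden. Covariate sets are selected by tag —
`primary`, `primary-minus-entorhinal`, `primary-plus-education` — so the
main and sensitivity specifications differ by configuration only.
No multiplicity control is applied across the secondary models, since
none was specified.

## The synthetic world

The generators' defaults *are* the cohort the package emulates
(n = 303): age 73.16 (5.19) y; 60% women; group probabilities
96/113/94 over White/Black/Hispanic; APOE ε4 carriage 101/303;
education 12.80 (4.80) y; baseline entorhinal thickness 3.30 (0.31) mm;
inter-scan interval 4.1 (2.4) y truncated at 0.5 y; total WMH 4.81
(5.36) cm³. Choices the descriptive table does not determine:

* **WMH distribution**: log-normal re-parameterized to the target
  mean/SD (strongly right-skewed mean/SD imply a skewed law; none was
  reported). Lobar volumes are a Dirichlet split (concentration 10) of
  the total with mean shares proportional to the lobar means
  2.04/0.31/1.30/0.40 cm³, the remainder unassigned. The per-lobe SDs
  are therefore emergent, not targeted. The printed temporal-lobe SD of
  0.14 is inconsistent with the per-group values printed elsewhere
  (0.32–0.54) and is likely a typo; since the Dirichlet split does not
  consume per-lobe SDs, nothing depends on it.
* **Planted effects**: vertexwise SPC = linear predictor in the
  covariates everywhere, plus a WMH slope and group×WMH interaction
  confined to a planted cluster (default: the 2-hop, 16-vertex
  neighborhood of vertex 1), plus smooth residual noise (SD 1 %/y —
  within the 0.6–2.4 %/y range of observed cluster-SPC SDs). Timepoint-2
  thickness is obtained by *inverting* the SPC formula,
  `T2 = T1 (1 + r)/(1 − r)` with `r = SPC·Δt/200`, so the realized SPC
  equals the planted one exactly — the closure every truth-recovery
  test relies on. Because a linear predictor is unbounded while SPC is
  not, the rare extreme joint tails of WMH and interval (~1e-4 of
  subjects) are saturated at 95% of the bound and the realized value is
  recomputed there; cortex cannot lose more than itself.
* **Noise smoothness**: k passes of neighbor-mean smoothing,
  rescaled to unit marginal SD. The default k = 2 (lag-1 neighbor
  correlation ≈ 0.78 on the 642-vertex icosphere) was chosen so the
  noise correlation length stays well below the planted cluster's
  diameter: at k = 5 (correlation ≈ 0.90) null supra-threshold patches
  on so coarse a mesh rival genuine clusters in size, which mimics not
  real cortical analyses (where significant clusters span hundreds of
  vertices at the noise FWHM) but an inference regime the scaled-down
  mesh cannot represent.
* **Memory model**: score = 18 + 0.3·(cluster-mean SPC) − 0.15·age +
  N(0, 2) — a delayed-recall-like scale with mean ≈ 7 and an
  age gradient, the 0.3 slope matching the order of the reported
  unstandardized coefficient (0.335).
* **Geometry**: the mesh is an icosphere (12 → 642 vertices by
  subdivision), the brain mask an ellipsoid, lesions non-overlapping
  spheres (defaults: 12 of radius 4.5 voxels ≈ 4.6 cm³, the Table-level
  total burden), the lobar "atlas" an octant partition. These are
  deliberately topology-trivial: verifiable, not anatomical.

What a green test establishes: the *algorithms* are correct (exact
arithmetic, oracle equivalence, truth closure), calibrated (type-I and
family-wise error), and powered against planted effects *in this stated
world*. What it does not establish: behaviour under real FLAIR
artifacts (bias fields, partial-volume effects, scanner noise spectra),
real cortical geometry and registration error, or the magnitude of any
coefficient in the motivating cohort — those numbers derive from
private clinical data and are not reproducible at desk scale.

## Numerical choices and degenerate inputs

* Moments fit uses the population (1/n) SD; threshold comparisons are
  strict (`>`); zero in-mask variance is an error, not a zero-sigma fit.
* Vertexwise OLS solves the normal equations once per design
  (Cholesky), applied to all vertices as a matrix product; zero
  residual variance yields SE = 0 and an infinite t for nonzero
  coefficients — the noiseless closure cases — rather than NaN.
* Rank-deficient designs fail naming the collinear columns (QR pivot).
* Cluster p values are floored at 1/(N+1); iteration counts below 100
  are refused.
* Lesion placement failure (mask capacity exhausted) is an explicit
  error, never silent truncation; seeds fully determine every output,
  and pipeline manifests hash every artifact so reruns are verifiable.

## Known limitations

Surface reconstruction, longitudinal registration, skull stripping and
atlas coregistration are consumed, not performed. Only two timepoints
are supported (no mixed-effects trajectories). The smooth-noise null
thresholds synthetic fields at the normal, not t, quantile — acceptable
at the residual df used here, and the permutation null is the default
precisely because it needs no such approximation. Cluster-extent
inference is in vertex count on a mesh whose vertex areas are nearly
uniform; on strongly non-uniform meshes area-based extent (computed but
not defaulted) would be preferable.
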