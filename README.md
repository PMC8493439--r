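# wmhspc

White matter hyperintensities (WMH) — bright regions on T2-FLAIR MRI —
are the radiological footprint of small-vessel cerebrovascular disease,
and their burden (especially in the parietal lobes) has been linked to
an Alzheimer-like pattern of cortical neurodegeneration and to memory
decline in older adults. `wmhspc` packages that entire analysis chain as
tested, scriptable R code for neuroimaging researchers who want to run
it on their own data or study its statistical behaviour on synthetic
cohorts with known ground truth:

1. **WMH segmentation** — a single Gaussian is fit to brain-masked FLAIR
   intensities and voxels above `mu + 2.1 sigma` are labeled; small
   connected components are removed (automated stand-in for manual
   editing) and labeled volume is aggregated in cm³, in total and within
   frontal/temporal/parietal/occipital lobes of a coregistered atlas.
2. **Longitudinal thinning** — symmetrized percent change of cortical
   thickness between two scans,
   `SPC = 100 (T2 − T1) / (Δt · ½(T1 + T2))` in %/year.
3. **Vertexwise inference** — per-vertex OLS of SPC on a WMH predictor
   plus covariates (age, sex/gender, APOE ε4, baseline entorhinal
   thickness), with two-tailed clusterwise Monte Carlo correction
   (cluster-forming threshold p < .01; Freedman–Lane residual
   permutation or smooth-noise simulation) on a triangulated mesh.
4. **Association models** — cluster-mean thinning vs delayed recall,
   race/ethnicity × WMH interactions, stratified fits, and
   covariate-adjusted group comparisons, reported as standardized and
   unstandardized coefficients with 95% CIs.
5. **Synthetic data** — seeded generators for FLAIR-like volumes with
   planted lesions and for two-timepoint cohorts whose covariate
   marginals, WMH distributions and planted vertexwise effects are fully
   specified, so every stage can be validated against known truth.

## Worked example

```r
library(wmhspc)
mesh <- icosphere(3)                     # 642-vertex surface stand-in

# segment a synthetic FLAIR volume with planted lesions
sim <- simulate_flair(image_sim_config(seed = 1))
seg <- regional_volumes(segment_wmh(sim$volume, segmentation_params()),
                        sim$atlas, sim$volume)
seg
#> wmh_result: mu = 103.9, sigma = 17.82, threshold = 141.3, 4668 voxels labeled
#>   total WMH volume: 4.6680 cm^3
#>   lobar: frontal 1.3360, temporal 1.2270, parietal 0.9350, occipital 1.1700, unassigned 0.0000

# cohort with a planted parietal-WMH -> thinning cluster
co  <- simulate_cohort(cohort_sim_config(n = 303, seed = 1), mesh)
fit <- fit_vertexwise(co$spc, build_design(co$table, "wmh_parietal"))
ccfg <- cluster_config(iterations = 500, seed = 1)
cl  <- monte_carlo_cluster_p(find_clusters(fit$t, mesh, ccfg, fit$df),
                             fit, mesh, ccfg)
cl
#> cluster_result: 4 cluster(s), |t| > 2.592 (df = 297)
#>  cluster sign n_vertices       area     peak_t           p
#>        1   -1         16 0.29330477 -19.977402 0.003992016
#>        2    1          2 0.04081879   2.855166 0.786427146
#>        ...

# memory model on the significant cluster's mean thinning
co$table$cluster1_spc <- extract_cluster_mean_spc(co$spc, cl, 1)
fit_memory_model(co$table, "cluster1_spc")
#> fit_summary: n = 303, residual df = 296, sigma = 1.986
#>          term        b std_beta      se ci_lower ci_upper       t        p
#>     intercept 13.77000       NA 2.03000   9.7750 17.76000  6.7840 6.37e-11
#>  cluster1_spc  0.30070  0.19100 0.08807   0.1274  0.47410  3.4150 7.28e-04
#>           age -0.08507 -0.20800 0.02298  -0.1303 -0.03984 -3.7020 2.55e-04
#>  ...
```

Reading the output: the fitted intensity Gaussian (`mu`, `sigma`) sets
the labeling threshold at 2.1 SD; total lesion load (~4.7 cm³) matches
the planted burden. The vertexwise model finds one large negative
cluster — more parietal WMH, faster thinning — whose clusterwise Monte
Carlo p (0.004) survives correction while the small noise clusters do
not; it is exactly the 16-vertex planted cluster. The memory model then
recovers the planted cluster-SPC coefficient (0.30: slower thinning,
better delayed recall) with its 95% CI and a standardized β of 0.19.

`run_pipeline()` chains all stages from files on disk (NIfTI volumes,
OFF mesh, CSV cohort and thickness maps) and writes every intermediate
artifact plus a `manifest.json` of parameters, seeds and md5 hashes;
two runs with the same config are byte-identical.

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

re-runs the complete pipeline from scratch on a seeded synthetic
dataset — image simulation, segmentation, lobar volumes, SPC, vertexwise
GLM, clusterwise Monte Carlo correction, cluster extraction and the
association models — logging the completed stages, and writes the result
JSON to `--out`.
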