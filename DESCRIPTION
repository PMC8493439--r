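Package: wmhspc
Title: White Matter Hyperintensity Burden and Longitudinal Cortical
    Thinning Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: An end-to-end, fully scriptable pipeline linking regional
    white matter hyperintensity (WMH) burden on FLAIR MRI to longitudinal
    cortical thinning and memory performance. Provides Gaussian-threshold
    WMH segmentation with lobar volumetry, symmetrized percent change
    (SPC) of cortical thickness between two timepoints, vertexwise general
    linear models with two-tailed clusterwise Monte Carlo correction on a
    triangulated surface mesh, and downstream association models
    (memory outcomes, race/ethnicity-by-WMH interactions, stratified
    fits, and covariate-adjusted group comparisons). A seeded synthetic
    data module generates FLAIR-like volumes, lobar atlases, surface
    meshes, and cohorts with planted effects so that every stage is
    testable without access to clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    igraph,
    Matrix
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
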