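# Pipeline orchestration: segmentation -> regional volumes -> SPC ->
# vertexwise GLM -> cluster correction -> cluster-mean extraction ->
# association models, with a JSON run manifest (inputs, parameters, seeds,
# md5 hashes of every artifact) sufficient to re-execute the identical run.

.required_cohort_cols <- c("id", "age", "female", "group", "apoe4",
                           "entorhinal", "interval", "test_gap", "memory",
                           "wmh_total", "wmh_frontal", "wmh_temporal",
                           "wmh_parietal", "wmh_occipital")

#' Read and validate a cohort CSV
#'
#' @param path CSV path (comma-separated, UTF-8, header row).
#' @return data.frame with `group` as a factor (White reference).
#' @export
read_cohort_csv <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(.required_cohort_cols, names(tab))
  if (length(miss))
    stop("cohort CSV is missing required column(s): ",
         paste(miss, collapse = ", "))
  bad <- setdiff(unique(tab$group), c("White", "Black", "Hispanic"))
  if (length(bad)) stop("unknown group code(s) in cohort CSV: ",
                        paste(bad, collapse = ", "))
  tab$group <- factor(tab$group, levels = c("White", "Black", "Hispanic"))
  if (any(tab$interval <= 0)) stop("cohort CSV: interval must be > 0")
  if (any(tab[, grep("^wmh_", names(tab))] < 0))
    stop("cohort CSV: WMH volumes must be >= 0")
  tab
}

#' Pipeline configuration
#'
#' @param flair,mask,atlas NIfTI paths of the exemplar FLAIR image, brain
#'   mask and lobar atlas (the imaging arm).
#' @param mesh OFF path of the surface mesh.
#' @param cohort Cohort CSV path.
#' @param t1_maps,t2_maps Per-vertex thickness CSV paths (subjects x
#'   vertices, rows aligned with the cohort CSV).
#' @param out_dir Output directory.
#' @param seg_params A [segmentation_params()].
#' @param clust_config A [cluster_config()]; its seed is overridden by
#'   `seed`.
#' @param wmh_predictor WMH column driving the vertexwise model.
#' @param covariates Covariate set tag (see [covariate_set()]).
#' @param seed Global seed propagated to every stochastic stage.
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(flair, mask, atlas, mesh, cohort,
                            t1_maps, t2_maps, out_dir,
                            seg_params = segmentation_params(),
                            clust_config = cluster_config(),
                            wmh_predictor = "wmh_parietal",
                            covariates = "primary",
                            seed = 1L) {
  clust_config$seed <- as.integer(seed)
  structure(list(paths = list(flair = flair, mask = mask, atlas = atlas,
                              mesh = mesh, cohort = cohort,
                              t1_maps = t1_maps, t2_maps = t2_maps),
                 out_dir = out_dir, seg_params = seg_params,
                 clust_config = clust_config,
                 wmh_predictor = wmh_predictor, covariates = covariates,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE))
}

#' Run the full pipeline
#'
#' Executes the seven analysis stages on the configured inputs and writes
#' every intermediate artifact plus `manifest.json` into the output
#' directory. Any stage failure aborts with the stage name and cause;
#' artifacts of completed stages are retained.
#'
#' @param config A [pipeline_config()].
#' @return The run manifest (named list), invisibly.
#' @export
run_pipeline <- function(config) {
  for (nm in names(config$paths))
    if (!file.exists(config$paths[[nm]]))
      stop("pipeline stage '", .stage_for_input(nm), "' failed: input '",
           nm, "' not found: ", config$paths[[nm]], call. = FALSE)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  stages <- character(0)
  artifacts <- character(0)
  emit <- function(name, writer) {
    path <- file.path(config$out_dir, name)
    writer(path)
    artifacts[[name]] <<- name
    path
  }

  flair <- .stage("segmentation", {
    img <- read_nifti(config$paths$flair)
    msk <- read_nifti(config$paths$mask)
    flair_volume(img$data, msk$data > 0, img$voxdim)
  })
  seg <- .stage("segmentation", segment_wmh(flair, config$seg_params))
  emit("wmh_mask.nii.gz", function(p)
    write_nifti(seg$lesion_mask, p, flair$voxdim, "uint8"))
  stages <- c(stages, "segmentation")

  seg <- .stage("regional_volumes", {
    atl <- lobar_atlas(read_nifti(config$paths$atlas)$data)
    regional_volumes(seg, atl, flair)
  })
  emit("wmh_volumes.json", function(p)
    jsonlite::write_json(list(mu = seg$mu, sigma = seg$sigma,
                              threshold = seg$threshold,
                              n_labeled = seg$n_labeled,
                              total_cm3 = seg$total_volume_cm3,
                              lobar_cm3 = as.list(seg$lobar_volumes_cm3)),
                         p, auto_unbox = TRUE, digits = NA))
  stages <- c(stages, "regional_volumes")

  mesh <- .stage("spc", read_off(config$paths$mesh))
  cohort <- .stage("spc", read_cohort_csv(config$paths$cohort))
  spc <- .stage("spc", {
    t1 <- read_vertex_maps(config$paths$t1_maps)
    t2 <- read_vertex_maps(config$paths$t2_maps)
    if (nrow(t1) != nrow(cohort) || !identical(dim(t1), dim(t2)))
      stop("thickness maps do not align with the cohort table")
    if (ncol(t1) != n_vertices(mesh))
      stop("thickness maps do not match the mesh vertex count")
    t(vapply(seq_len(nrow(t1)), function(i)
      symmetrized_percent_change(t1[i, ], t2[i, ], cohort$interval[i]),
      numeric(ncol(t1))))
  })
  emit("spc_maps.csv", function(p) write_vertex_maps(spc, p))
  stages <- c(stages, "spc")

  fit <- .stage("vertexwise_glm", {
    design <- build_design(cohort, config$wmh_predictor,
                           covariate_set(config$covariates))
    fit_vertexwise(spc, design)
  })
  emit("vertexwise_stats.csv", function(p)
    utils::write.csv(data.frame(vertex = seq_along(fit$t), beta = fit$beta,
                                se = fit$se, t = fit$t, p = fit$p), p,
                     row.names = FALSE))
  stages <- c(stages, "vertexwise_glm")

  clusters <- .stage("cluster_correction", {
    cl <- find_clusters(fit$t, mesh, config$clust_config, fit$df)
    monte_carlo_cluster_p(cl, fit, mesh, config$clust_config)
  })
  emit("clusters.tsv", function(p)
    utils::write.table(clusters$table, p, sep = "\t", row.names = FALSE,
                       quote = FALSE))
  stages <- c(stages, "cluster_correction")

  sig <- which(clusters$table$p < config$clust_config$alpha)
  cohort2 <- .stage("cluster_means", {
    co <- cohort
    for (ci in sig)
      co[[paste0("cluster", ci, "_spc")]] <-
        extract_cluster_mean_spc(spc, clusters, ci)
    co
  })
  emit("cohort_with_clusters.csv", function(p)
    utils::write.csv(cohort2, p, row.names = FALSE))
  stages <- c(stages, "cluster_means")

  models <- .stage("association_models", {
    res <- list()
    for (ci in sig) {
      col <- paste0("cluster", ci, "_spc")
      res[[col]] <- list(
        memory = fit_memory_model(cohort2, col, config$covariates)$coefficients,
        interaction = fit_interaction_model(cohort2, col,
                                            config$wmh_predictor,
                                            config$covariates)$coefficients,
        stratified = stratified_table(cohort2, stats::setNames(col, col),
                                      config$wmh_predictor,
                                      config$covariates))
    }
    res$group_differences <- group_difference_tests(
      cohort2, c("wmh_total", "wmh_frontal", "wmh_temporal", "wmh_parietal",
                 "wmh_occipital", if (length(sig))
                   paste0("cluster", sig, "_spc")))
    res
  })
  emit("association_models.json", function(p)
    jsonlite::write_json(models, p, digits = NA, dataframe = "rows"))
  stages <- c(stages, "association_models")

  hashes <- tools::md5sum(file.path(config$out_dir, unlist(artifacts)))
  names(hashes) <- unlist(artifacts)
  input_hashes <- tools::md5sum(unlist(config$paths))
  names(input_hashes) <- basename(unlist(config$paths))
  manifest <- list(
    package = "wmhspc",
    version = as.character(utils::packageVersion("wmhspc")),
    seed = config$seed,
    parameters = list(
      segmentation = unclass(config$seg_params),
      clusters = unclass(config$clust_config),
      wmh_predictor = config$wmh_predictor,
      covariates = config$covariates),
    stages_complete = stages,
    inputs = as.list(input_hashes),
    artifacts = as.list(hashes),
    significant_clusters = clusters$table[sig, , drop = FALSE])
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows",
                       pretty = TRUE)
  invisible(manifest)
}

.stage_for_input <- function(input) {
  switch(input,
         flair = , mask = , atlas = "segmentation",
         mesh = , cohort = , t1_maps = , t2_maps = "spc",
         "inputs")
}
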