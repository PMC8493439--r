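# Synthetic two-timepoint cohorts with planted effects. Covariate marginals
# default to the descriptive statistics of a community-based aging cohort
# (n = 303, mean age 73.16 y, 60% women, three racial/ethnic groups, 33%
# APOE e4 carriers, right-skewed WMH volumes). Vertexwise annualized
# thinning (SPC, %/y) follows a linear model in the covariates, with a
# WMH slope and a group-by-WMH interaction confined to a planted cluster
# of mesh vertices; thickness at timepoint 2 is constructed so that the
# realized SPC is exact by inversion of the SPC formula. A memory score
# depends linearly on the cluster-mean SPC. All planted coefficients are
# returned as ground truth.

#' Cohort simulation configuration
#'
#' Defaults reproduce the marginal distributions of the motivating cohort:
#' age 73.16 (5.19) y, 60% women, group probabilities 96/113/94 over
#' White/Black/Hispanic, APOE e4 carriage 101/303, education 12.80 (4.80)
#' y, baseline entorhinal thickness 3.30 (0.31) mm, inter-scan interval
#' 4.1 (2.4) y truncated at 0.5 y, and total WMH 4.81 (5.36) cm^3
#' (log-normal, re-parameterized to hit that mean/SD) split across lobes
#' by a Dirichlet draw with mean shares proportional to the lobar means
#' 2.04/0.31/1.30/0.40 (remainder unassigned).
#'
#' @param n Number of subjects (>= 2).
#' @param age_mean,age_sd Age marginal (years).
#' @param p_female Proportion of women.
#' @param group_probs Named probabilities over `White`, `Black`,
#'   `Hispanic`; must sum to 1.
#' @param p_apoe4 APOE e4 carrier probability.
#' @param education_mean,education_sd Education marginal (years,
#'   truncated at 0).
#' @param entorhinal_mean,entorhinal_sd Baseline entorhinal thickness
#'   marginal (mm).
#' @param interval_mean,interval_sd,interval_min Inter-scan interval
#'   marginal (years), normal truncated below at `interval_min`.
#' @param wmh_total_mean,wmh_total_sd Total WMH volume marginal (cm^3),
#'   log-normal.
#' @param lobe_means Named mean lobar WMH volumes (cm^3) for frontal,
#'   temporal, parietal, occipital; together with the unassigned
#'   remainder of `wmh_total_mean` they set the Dirichlet mean shares.
#' @param dirichlet_conc Dirichlet concentration for the lobar split.
#' @param beta Named coefficients of the vertexwise SPC model applied at
#'   every vertex: `intercept` (%/y), `age` (per year), `female`,
#'   `apoe4`, `entorhinal` (per mm).
#' @param cluster_wmh_slope WMH slope (%/y per cm^3) applied only at the
#'   planted cluster vertices.
#' @param wmh_predictor Which WMH volume drives the planted effect:
#'   `"total"`, `"frontal"`, `"temporal"`, `"parietal"` or `"occipital"`.
#' @param interaction Named extra WMH slopes (relative to White) inside
#'   the planted cluster: `Black`, `Hispanic`.
#' @param cluster_vertices Integer vertex indices of the planted cluster,
#'   or `NULL` to use a 2-hop neighborhood of vertex 1 of the mesh.
#' @param spc_resid_sd Residual SD of SPC after spatial smoothing (%/y).
#' @param smooth_iters Neighbor-mean smoothing passes applied to the
#'   vertexwise noise. The default (2) keeps the noise correlation length
#'   well below the diameter of a planted cluster on meshes of a few
#'   hundred vertices; larger values make noise fields whose connected
#'   supra-threshold patches rival genuine clusters in size.
#' @param baseline_mean,baseline_sd Mean cortical thickness (mm) and SD of
#'   the smooth between-subject/spatial baseline variation.
#' @param gamma Named memory-model coefficients: `intercept`,
#'   `cluster_spc` (points per %/y), `age` (points per year).
#' @param memory_sd Residual SD of the memory score.
#' @param test_gap_mean,test_gap_sd Time between memory testing and the
#'   second scan (years), normal truncated at 0.
#' @param seed Integer random seed.
#' @return An object of class `cohort_sim_config`.
#' @export
cohort_sim_config <- function(
    n = 303,
    age_mean = 73.16, age_sd = 5.19,
    p_female = 181 / 303,
    group_probs = c(White = 96, Black = 113, Hispanic = 94) / 303,
    p_apoe4 = 101 / 303,
    education_mean = 12.80, education_sd = 4.80,
    entorhinal_mean = 3.30, entorhinal_sd = 0.31,
    interval_mean = 4.1, interval_sd = 2.4, interval_min = 0.5,
    wmh_total_mean = 4.81, wmh_total_sd = 5.36,
    lobe_means = c(frontal = 2.04, temporal = 0.31,
                   parietal = 1.30, occipital = 0.40),
    dirichlet_conc = 10,
    beta = c(intercept = -0.3, age = -0.01, female = 0.1,
             apoe4 = -0.15, entorhinal = 0.1),
    cluster_wmh_slope = -0.51,
    wmh_predictor = "parietal",
    interaction = c(Black = -0.3, Hispanic = 0),
    cluster_vertices = NULL,
    spc_resid_sd = 1.0,
    smooth_iters = 2L,
    baseline_mean = 2.5, baseline_sd = 0.25,
    gamma = c(intercept = 18, cluster_spc = 0.3, age = -0.15),
    memory_sd = 2,
    test_gap_mean = 0.6, test_gap_sd = 0.4,
    seed = 1L) {
  if (n < 2) stop("need n >= 2 subjects")
  if (abs(sum(group_probs) - 1) > 1e-8 || any(group_probs < 0) || any(group_probs > 1))
    stop("group_probs must be probabilities summing to 1")
  if (p_female < 0 || p_female > 1 || p_apoe4 < 0 || p_apoe4 > 1)
    stop("probabilities must lie in [0, 1]")
  if (interval_min <= 0) stop("interval_min must be > 0")
  if (spc_resid_sd < 0 || memory_sd < 0) stop("residual SDs must be >= 0")
  if (!wmh_predictor %in% c("total", .lobe_names)) stop("unknown wmh_predictor")
  if (sum(lobe_means) > wmh_total_mean)
    stop("lobar means exceed the total WMH mean")
  structure(as.list(environment()), class = "cohort_sim_config")
}

# Truncated-normal draws by inverse-CDF (exact, vectorized).
.rtruncnorm <- function(n, mean, sd, lower) {
  plo <- stats::pnorm(lower, mean, sd)
  stats::qnorm(plo + stats::runif(n) * (1 - plo), mean, sd)
}

.rdirichlet <- function(n, alpha) {
  g <- matrix(stats::rgamma(n * length(alpha), shape = alpha), nrow = n, byrow = TRUE)
  g / rowSums(g)
}

#' Vertices within a graph radius on a mesh
#'
#' @param mesh A `surface_mesh`.
#' @param center Seed vertex index.
#' @param hops Number of edge hops to include.
#' @return Sorted integer vertex indices (includes `center`).
#' @export
mesh_ball <- function(mesh, center = 1L, hops = 2L) {
  current <- as.integer(center)
  seen <- current
  for (h in seq_len(hops)) {
    current <- setdiff(unique(unlist(mesh$adjacency[current])), seen)
    seen <- c(seen, current)
  }
  sort(seen)
}

# Smooth unit-variance noise: iid normal smoothed on the mesh, rescaled so
# the pooled marginal SD is 1 (smoothing shrinks variance).
.smooth_noise <- function(n, mesh, iterations) {
  z <- matrix(stats::rnorm(n * n_vertices(mesh)), nrow = n)
  if (iterations > 0) {
    z <- smooth_vertex_field(z, mesh, iterations)
    z <- z / stats::sd(as.vector(z))
  }
  z
}

#' Simulate a two-timepoint cohort on a mesh
#'
#' Draws covariates from the configured marginals, constructs per-vertex
#' SPC as the planted linear model plus smooth residual noise, inverts the
#' SPC formula to obtain timepoint-2 thickness, and generates a memory
#' score from the cluster-mean SPC. The returned truth record contains
#' every planted coefficient.
#'
#' @param config A [cohort_sim_config()].
#' @param mesh A `surface_mesh` (nonempty).
#' @return An object of class `wmh_cohort`: `table` (data.frame of
#'   per-subject covariates, WMH volumes and memory score), `t1`, `t2`
#'   (n-by-V thickness matrices, mm), `spc` (n-by-V realized SPC, %/y),
#'   and `truth` (planted coefficients, cluster vertices, config).
#' @export
simulate_cohort <- function(config, mesh) {
  set.seed(config$seed)
  n <- config$n
  nv <- n_vertices(mesh)

  age <- stats::rnorm(n, config$age_mean, config$age_sd)
  female <- as.integer(stats::runif(n) < config$p_female)
  group <- factor(sample(names(config$group_probs), n, replace = TRUE,
                         prob = config$group_probs),
                  levels = c("White", "Black", "Hispanic"))
  apoe4 <- as.integer(stats::runif(n) < config$p_apoe4)
  education <- .rtruncnorm(n, config$education_mean, config$education_sd, 0)
  entorhinal <- stats::rnorm(n, config$entorhinal_mean, config$entorhinal_sd)
  interval <- .rtruncnorm(n, config$interval_mean, config$interval_sd,
                          config$interval_min)
  test_gap <- .rtruncnorm(n, config$test_gap_mean, config$test_gap_sd, 0)

  # log-normal re-parameterized to the target mean/SD of total WMH
  cv2 <- (config$wmh_total_sd / config$wmh_total_mean)^2
  sdlog <- sqrt(log1p(cv2))
  meanlog <- log(config$wmh_total_mean) - sdlog^2 / 2
  wmh_total <- stats::rlnorm(n, meanlog, sdlog)
  share_means <- c(config$lobe_means,
                   unassigned = config$wmh_total_mean - sum(config$lobe_means))
  share_means <- share_means / sum(share_means)
  shares <- .rdirichlet(n, config$dirichlet_conc * share_means)
  wmh_lobar <- shares[, 1:4, drop = FALSE] * wmh_total
  colnames(wmh_lobar) <- names(config$lobe_means)

  cluster <- config$cluster_vertices
  if (is.null(cluster)) cluster <- mesh_ball(mesh, 1L, 2L)
  cluster <- sort(unique(as.integer(cluster)))
  if (any(cluster < 1 | cluster > nv))
    stop("planted cluster vertices outside the mesh")

  wmh_pred <- if (config$wmh_predictor == "total") wmh_total
              else wmh_lobar[, config$wmh_predictor]
  b <- config$beta
  subj_lp <- b[["intercept"]] + b[["age"]] * age + b[["female"]] * female +
    b[["apoe4"]] * apoe4 + b[["entorhinal"]] * entorhinal
  cluster_lp <- config$cluster_wmh_slope * wmh_pred +
    config$interaction[["Black"]] * (group == "Black") * wmh_pred +
    config$interaction[["Hispanic"]] * (group == "Hispanic") * wmh_pred

  eta <- matrix(subj_lp, nrow = n, ncol = nv)
  eta[, cluster] <- eta[, cluster] + cluster_lp
  spc <- eta
  if (config$spc_resid_sd > 0)
    spc <- spc + config$spc_resid_sd *
      .smooth_noise(n, mesh, config$smooth_iters)

  t1 <- config$baseline_mean +
    config$baseline_sd * .smooth_noise(n, mesh, config$smooth_iters)
  t1 <- pmax(t1, 0.5)
  # SPC is bounded by +/-200/interval for positive thickness; an unbounded
  # linear predictor in WMH can exceed that in extreme tail draws. Saturate
  # at 95% of the bound (cortex cannot lose more than itself) and recompute
  # the realized SPC there, so SPC(t1, t2, dt) always equals `spc` exactly.
  r <- spc * interval / 200       # interval recycles down columns (by row)
  clip <- abs(r) > 0.95
  if (any(clip)) {
    rows <- ((which(clip) - 1L) %% n) + 1L
    r[clip] <- sign(r[clip]) * 0.95
    spc[clip] <- 200 * r[clip] / interval[rows]
  }
  t2 <- t1 * (1 + r) / (1 - r)

  cluster_spc <- rowMeans(spc[, cluster, drop = FALSE])
  g <- config$gamma
  memory <- g[["intercept"]] + g[["cluster_spc"]] * cluster_spc +
    g[["age"]] * age + stats::rnorm(n, 0, config$memory_sd)

  tab <- data.frame(
    id = sprintf("S%04d", seq_len(n)),
    age = age, female = female, group = group, apoe4 = apoe4,
    education = education, entorhinal = entorhinal,
    interval = interval, test_gap = test_gap,
    wmh_total = wmh_total, wmh_lobar,
    memory = memory,
    stringsAsFactors = FALSE)
  names(tab)[match(names(config$lobe_means), names(tab))] <-
    paste0("wmh_", names(config$lobe_means))

  structure(list(
    table = tab, t1 = t1, t2 = t2, spc = spc,
    truth = list(beta = b, cluster_vertices = cluster,
                 n_saturated = sum(clip),
                 cluster_wmh_slope = config$cluster_wmh_slope,
                 wmh_predictor = config$wmh_predictor,
                 interaction = config$interaction,
                 gamma = g, cluster_spc = cluster_spc,
                 config = config)),
    class = "wmh_cohort")
}

#' @export
print.wmh_cohort <- function(x, ...) {
  cat("wmh_cohort:", nrow(x$table), "subjects,",
      ncol(x$spc), "vertices; planted cluster of",
      length(x$truth$cluster_vertices), "vertices on", x$truth$wmh_predictor,
      "WMH\n")
  invisible(x)
}

#' Write a simulated cohort to disk
#'
#' Writes the cohort table as CSV, the thickness and SPC maps as per-vertex
#' CSV matrices, the mesh as ASCII OFF, and the planted truth as JSON.
#'
#' @param cohort A `wmh_cohort`.
#' @param mesh The `surface_mesh` the cohort was simulated on.
#' @param dir Output directory (created if needed).
#' @return Named character vector of file paths, invisibly.
#' @export
write_cohort <- function(cohort, mesh, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(cohort = file.path(dir, "cohort.csv"),
             t1 = file.path(dir, "thickness_t1.csv"),
             t2 = file.path(dir, "thickness_t2.csv"),
             mesh = file.path(dir, "mesh.off"),
             truth = file.path(dir, "truth.json"))
  utils::write.csv(cohort$table, paths["cohort"], row.names = FALSE)
  write_vertex_maps(cohort$t1, paths["t1"])
  write_vertex_maps(cohort$t2, paths["t2"])
  write_off(mesh, paths["mesh"])
  truth <- cohort$truth
  truth$config <- NULL
  jsonlite::write_json(truth, paths["truth"], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}

#' Write/read per-vertex maps as CSV
#'
#' Maps are stored as a matrix with one row per subject and one column per
#' vertex (columns `v1`, `v2`, ...).
#'
#' @param maps Numeric matrix, subjects by vertices.
#' @param path CSV path.
#' @return `path` (write) or the matrix (read), invisibly for write.
#' @export
write_vertex_maps <- function(maps, path) {
  df <- as.data.frame(maps)
  names(df) <- paste0("v", seq_len(ncol(df)))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_vertex_maps
#' @export
read_vertex_maps <- function(path) {
  as.matrix(utils::read.csv(path))
}
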