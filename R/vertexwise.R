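# Vertexwise general linear model of annualized cortical thinning (SPC) on
# a WMH predictor plus covariates, with two-tailed clusterwise Monte Carlo
# correction on the mesh. Positive and negative supra-threshold maps are
# clustered separately; the null distribution of the maximum cluster extent
# is taken over both signs, matching the two-tailed convention of
# surface-based cluster inference.

#' Build a design matrix from a cohort table
#'
#' Assembles the standard design: intercept, a focal WMH predictor, and the
#' covariates age, sex/gender (woman = 1), APOE e4 carriage and baseline
#' entorhinal thickness; optionally group indicators (White reference) and
#' group-by-WMH products.
#'
#' @param table Cohort data.frame (as in `wmh_cohort$table`).
#' @param predictor Name of the focal WMH column (e.g. `"wmh_parietal"`).
#' @param covariates Character vector of covariate column names.
#' @param group_terms Add group main effects and group-by-predictor
#'   interactions (logical).
#' @return List with `X` (numeric matrix, named columns), `focal` (focal
#'   column name).
#' @export
build_design <- function(table, predictor = "wmh_total",
                         covariates = c("age", "female", "apoe4", "entorhinal"),
                         group_terms = FALSE) {
  needed <- c(predictor, covariates, if (group_terms) "group")
  miss <- setdiff(needed, names(table))
  if (length(miss)) stop("cohort table is missing columns: ",
                         paste(miss, collapse = ", "))
  X <- cbind(intercept = 1, as.matrix(table[, c(predictor, covariates)]))
  if (group_terms) {
    gb <- as.numeric(table$group == "Black")
    gh <- as.numeric(table$group == "Hispanic")
    X <- cbind(X, Black = gb, Hispanic = gh,
               `Black:wmh` = gb * table[[predictor]],
               `Hispanic:wmh` = gh * table[[predictor]])
  }
  list(X = X, focal = predictor)
}

.check_full_rank <- function(X) {
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop("design matrix is rank deficient; collinear columns: ",
         paste(bad, collapse = ", "))
  }
  invisible(qrX)
}

# t-map for one focal column given precomputed solve pieces.
.tmap <- function(Y, X, A, cinv, focal_idx, df) {
  B <- A %*% Y
  resid <- Y - X %*% B
  rss <- colSums(resid^2)
  se <- sqrt(pmax(rss, 0) / df * cinv)
  tv <- B[focal_idx, ] / se
  tv[se == 0] <- ifelse(B[focal_idx, se == 0] == 0, 0, Inf *
                          sign(B[focal_idx, se == 0]))
  list(beta = B[focal_idx, ], se = se, t = tv, B = B)
}

#' Fit the vertexwise GLM
#'
#' Ordinary least squares at each vertex of per-subject SPC maps on a
#' shared design matrix; reports the focal predictor's coefficient,
#' standard error, t statistic (df = n - k) and two-tailed p per vertex.
#'
#' @param spc n-by-V matrix of per-subject SPC maps (rows align with
#'   design rows).
#' @param design Output of [build_design()] (or a list with `X`, `focal`).
#' @return Object of class `vertexwise_fit`: vectors `beta`, `se`, `t`,
#'   `p` (length V), scalar `df`, plus `X`, `Y`, `focal` retained for the
#'   Monte Carlo stage.
#' @export
fit_vertexwise <- function(spc, design) {
  X <- design$X
  if (nrow(X) != nrow(spc))
    stop("design rows and SPC map rows disagree")
  if (nrow(X) <= ncol(X) + 1)
    stop("need more subjects than design columns + 1")
  .check_full_rank(X)
  focal_idx <- match(design$focal, colnames(X))
  if (is.na(focal_idx)) stop("focal column not in design: ", design$focal)
  df <- nrow(X) - ncol(X)
  xtx_inv <- chol2inv(chol(crossprod(X)))
  A <- xtx_inv %*% t(X)
  cinv <- xtx_inv[focal_idx, focal_idx]
  tm <- .tmap(spc, X, A, cinv, focal_idx, df)
  p <- 2 * stats::pt(-abs(tm$t), df)
  structure(list(beta = tm$beta, se = tm$se, t = tm$t, p = p, df = df,
                 X = X, Y = spc, focal = design$focal,
                 focal_idx = focal_idx, A = A, cinv = cinv),
            class = "vertexwise_fit")
}

#' Clusterwise inference configuration
#'
#' @param cft Two-tailed cluster-forming significance threshold (default
#'   .01, applied to the vertexwise t statistics).
#' @param iterations Monte Carlo iterations (>= 100; default 1000).
#' @param alpha Clusterwise significance level (default .05).
#' @param method Null-generation method: `"residual-permutation"`
#'   (Freedman-Lane permutation of reduced-model residuals; default) or
#'   `"smooth-noise"` (synthetic smoothed Gaussian fields, smoothness
#'   estimated from the residual lag-1 neighbor correlation unless
#'   `smooth_iters` is given).
#' @param smooth_iters Smoothing passes for the smooth-noise null
#'   (`NULL` = estimate from residuals).
#' @param seed Integer seed for the Monte Carlo stage.
#' @return Object of class `cluster_config`.
#' @export
cluster_config <- function(cft = 0.01, iterations = 1000L, alpha = 0.05,
                           method = c("residual-permutation", "smooth-noise"),
                           smooth_iters = NULL, seed = 1L) {
  method <- match.arg(method)
  if (cft <= 0 || cft >= 1 || alpha <= 0 || alpha >= 1)
    stop("thresholds must lie in (0, 1)")
  if (iterations < 100)
    stop("refusing fewer than 100 Monte Carlo iterations (unstable tail)")
  structure(list(cft = cft, iterations = as.integer(iterations),
                 alpha = alpha, method = method, smooth_iters = smooth_iters,
                 seed = as.integer(seed)),
            class = "cluster_config")
}

# Connected components of a vertex subset under mesh edge adjacency.
.vertex_components <- function(vertices, mesh) {
  if (length(vertices) == 0) return(list())
  e <- mesh$edges
  keep <- e[e[, 1] %in% vertices & e[, 2] %in% vertices, , drop = FALSE]
  id <- match(seq_len(n_vertices(mesh)), vertices)
  g <- igraph::make_empty_graph(n = length(vertices), directed = FALSE)
  if (nrow(keep))
    g <- igraph::add_edges(g, rbind(id[keep[, 1]], id[keep[, 2]]))
  comp <- igraph::components(g)$membership
  unname(split(vertices, comp))
}

# One-third of incident triangle areas, per vertex.
.vertex_areas <- function(mesh) {
  v <- mesh$vertices; f <- mesh$faces
  a <- v[f[, 2], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  b <- v[f[, 3], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  cr <- cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
              a[, 3] * b[, 1] - a[, 1] * b[, 3],
              a[, 1] * b[, 2] - a[, 2] * b[, 1])
  fa <- 0.5 * sqrt(rowSums(cr^2))
  va <- numeric(n_vertices(mesh))
  for (j in 1:3) {
    s <- tapply(fa / 3, f[, j], sum)
    va[as.integer(names(s))] <- va[as.integer(names(s))] + s
  }
  va
}

#' Find supra-threshold clusters
#'
#' Thresholds the vertexwise t map at the two-tailed critical value of the
#' cluster-forming threshold and partitions supra-threshold vertices into
#' edge-connected components, separately for positive and negative signs.
#'
#' @param tmap Numeric vector of vertexwise t statistics.
#' @param mesh A `surface_mesh`.
#' @param config A [cluster_config()].
#' @param df Residual degrees of freedom of the fit.
#' @return Object of class `cluster_result`: `table` (data.frame with
#'   cluster id, sign, n_vertices, area, peak_t, p = NA), `members` (list
#'   of vertex index vectors), `critical_t`, `df`.
#' @export
find_clusters <- function(tmap, mesh, config = cluster_config(), df) {
  if (length(tmap) != n_vertices(mesh))
    stop("t map length does not match mesh vertex count")
  crit <- stats::qt(1 - config$cft / 2, df)
  va <- .vertex_areas(mesh)
  members <- list(); sign_v <- integer(0)
  for (s in c(1, -1)) {
    comps <- .vertex_components(which(s * tmap > crit), mesh)
    members <- c(members, comps)
    sign_v <- c(sign_v, rep(s, length(comps)))
  }
  if (length(members)) {
    ord <- order(-vapply(members, length, integer(1)))
    members <- members[ord]; sign_v <- sign_v[ord]
    tab <- data.frame(
      cluster = seq_along(members),
      sign = sign_v,
      n_vertices = vapply(members, length, integer(1)),
      area = vapply(members, function(v) sum(va[v]), numeric(1)),
      peak_t = vapply(members, function(v) tmap[v][which.max(abs(tmap[v]))],
                      numeric(1)),
      p = NA_real_)
  } else {
    tab <- data.frame(cluster = integer(0), sign = integer(0),
                      n_vertices = integer(0), area = numeric(0),
                      peak_t = numeric(0), p = numeric(0))
  }
  structure(list(table = tab, members = members, critical_t = crit, df = df),
            class = "cluster_result")
}

#' @export
print.cluster_result <- function(x, ...) {
  cat(sprintf("cluster_result: %d cluster(s), |t| > %.3f (df = %d)\n",
              nrow(x$table), x$critical_t, x$df))
  if (nrow(x$table)) print(x$table, row.names = FALSE)
  invisible(x)
}

# Max supra-threshold component extent (vertex count) over both signs.
.max_extent <- function(stat, crit, mesh) {
  mx <- 0L
  for (s in c(1, -1)) {
    idx <- which(s * stat > crit)
    if (length(idx) <= mx) next
    comps <- .vertex_components(idx, mesh)
    if (length(comps))
      mx <- max(mx, max(vapply(comps, length, integer(1))))
  }
  mx
}

# Pick smoothing iterations whose noise lag-1 neighbor correlation best
# matches the residual fields' correlation (calibrated on this mesh).
.estimate_smooth_iters <- function(resid, mesh, max_iters = 12L) {
  target <- .neighbor_correlation(resid, mesh)
  if (!is.finite(target) || target <= 0) return(0L)
  z <- matrix(stats::rnorm(64 * n_vertices(mesh)), nrow = 64)
  best <- 0L; bestd <- abs(.neighbor_correlation(z, mesh) - target)
  zi <- z
  for (k in seq_len(max_iters)) {
    zi <- smooth_vertex_field(zi, mesh, 1)
    d <- abs(.neighbor_correlation(zi, mesh) - target)
    if (d < bestd) { bestd <- d; best <- k }
  }
  best
}

#' Clusterwise Monte Carlo p values
#'
#' Builds the null distribution of the maximum supra-threshold cluster
#' extent (vertex count, over both signs) from `iterations` synthetic null
#' datasets, then assigns each observed cluster the p value
#' `(1 + #null >= observed) / (iterations + 1)`.
#'
#' With `"residual-permutation"` (Freedman-Lane), the focal predictor is
#' removed from the design, the reduced-model residuals are permuted
#' across subjects and added back to the reduced fit, and the full model
#' is refit on each permuted dataset. With `"smooth-noise"`, standardized
#' smoothed Gaussian fields are thresholded at the two-tailed normal
#' quantile of the cluster-forming threshold.
#'
#' @param clusters A `cluster_result` from [find_clusters()].
#' @param fit The `vertexwise_fit` the clusters came from.
#' @param mesh The `surface_mesh`.
#' @param config A [cluster_config()]; `config$seed` makes the stage
#'   reproducible.
#' @return The `cluster_result` with `p` filled in and the sorted null
#'   maxima attached as `null_max_extent`.
#' @export
monte_carlo_cluster_p <- function(clusters, fit, mesh, config = cluster_config()) {
  if (config$iterations < 100)
    stop("refusing fewer than 100 Monte Carlo iterations (unstable tail)")
  set.seed(config$seed)
  n <- nrow(fit$X)
  null_max <- integer(config$iterations)
  if (config$method == "residual-permutation") {
    Z <- fit$X[, -fit$focal_idx, drop = FALSE]
    qz <- qr(Z)
    fitted_z <- qr.fitted(qz, fit$Y)
    resid_z <- fit$Y - fitted_z
    crit <- clusters$critical_t
    for (i in seq_len(config$iterations)) {
      perm <- sample.int(n)
      Ystar <- fitted_z + resid_z[perm, , drop = FALSE]
      tm <- .tmap(Ystar, fit$X, fit$A, fit$cinv, fit$focal_idx, fit$df)
      null_max[i] <- .max_extent(tm$t, crit, mesh)
    }
  } else {
    resid <- fit$Y - fit$X %*% (fit$A %*% fit$Y)
    k <- config$smooth_iters %||% .estimate_smooth_iters(resid, mesh)
    crit <- stats::qnorm(1 - config$cft / 2)
    for (i in seq_len(config$iterations)) {
      z <- .smooth_noise(1, mesh, k)
      null_max[i] <- .max_extent(drop(z), crit, mesh)
    }
  }
  obs <- clusters$table$n_vertices
  clusters$table$p <- vapply(obs, function(x)
    (1 + sum(null_max >= x)) / (config$iterations + 1), numeric(1))
  clusters$null_max_extent <- sort(null_max)
  clusters$config <- config
  clusters
}

#' Cluster-mean SPC per subject
#'
#' Unweighted mean of each subject's SPC over the vertices of one cluster.
#'
#' @param spc n-by-V matrix of SPC maps.
#' @param clusters A `cluster_result`.
#' @param cluster Cluster id (row of `clusters$table`), or an explicit
#'   integer vector of vertex indices.
#' @return Numeric vector, one value per subject.
#' @export
extract_cluster_mean_spc <- function(spc, clusters, cluster = 1L) {
  vertices <- if (is.numeric(cluster) && length(cluster) > 1) {
    as.integer(cluster)
  } else {
    if (length(clusters$members) < cluster)
      stop("no such cluster: ", cluster)
    clusters$members[[cluster]]
  }
  if (length(vertices) == 0) stop("empty cluster")
  if (max(vertices) > ncol(spc)) stop("cluster vertices outside SPC maps")
  rowMeans(spc[, vertices, drop = FALSE])
}
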