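# WMH quantification on brain-extracted FLAIR: a single Gaussian is fit to
# in-mask voxel intensities, voxels brighter than mean + z*SD (z = 2.1 by
# default) are labeled, small connected components are removed, and labeled
# volume is aggregated in total and per lobe (cm^3).

#' FLAIR volume container
#'
#' @param data 3-D numeric array of intensities.
#' @param mask 3-D logical array (brain mask), same shape as `data`.
#' @param voxdim Voxel dimensions in mm (length 3, all positive).
#' @return An object of class `flair_volume`.
#' @export
flair_volume <- function(data, mask, voxdim = c(1, 1, 1)) {
  data <- as.array(data); mask <- as.array(mask)
  if (!identical(dim(data), dim(mask)))
    stop("intensity field and mask have different shapes")
  mask <- array(as.logical(mask), dim = dim(mask))
  if (!any(mask)) stop("brain mask is empty")
  voxdim <- as.numeric(voxdim)
  if (length(voxdim) != 3 || any(voxdim <= 0))
    stop("voxdim must be 3 positive values (mm)")
  structure(list(data = data, mask = mask, voxdim = voxdim),
            class = "flair_volume")
}

#' Segmentation parameters
#'
#' @param z_threshold Threshold in SD units above the fitted mean
#'   (default 2.1).
#' @param fit_method `"moments"` (in-mask mean/SD) or `"trimmed"`
#'   (symmetrically trimmed moments with a truncated-normal SD correction,
#'   robust to the hyperintense tail).
#' @param trim_fraction Fraction trimmed from *each* tail for the trimmed
#'   fit, in [0, 0.5).
#' @param min_component_size Minimum connected-component size in voxels;
#'   smaller supra-threshold components are discarded (automated stand-in
#'   for manual false-positive editing). Default 5.
#' @param connectivity Voxel connectivity: 6, 18 or 26 (default 26).
#' @return An object of class `segmentation_params`.
#' @export
segmentation_params <- function(z_threshold = 2.1, fit_method = c("moments", "trimmed"),
                                trim_fraction = 0.05, min_component_size = 5L,
                                connectivity = 26L) {
  fit_method <- match.arg(fit_method)
  if (z_threshold <= 0) stop("z_threshold must be > 0")
  if (trim_fraction < 0 || trim_fraction >= 0.5)
    stop("trim_fraction must be in [0, 0.5)")
  if (min_component_size < 1) stop("min_component_size must be >= 1")
  if (!connectivity %in% c(6L, 18L, 26L)) stop("connectivity must be 6, 18 or 26")
  structure(list(z_threshold = z_threshold, fit_method = fit_method,
                 trim_fraction = trim_fraction,
                 min_component_size = as.integer(min_component_size),
                 connectivity = as.integer(connectivity)),
            class = "segmentation_params")
}

#' Fit the intensity Gaussian
#'
#' Fits a single Gaussian to the in-mask intensity distribution. The
#' `"moments"` method uses the in-mask mean and population (1/n) standard
#' deviation. The `"trimmed"` method removes the `trim_fraction` of values
#' from each tail before taking moments and rescales the SD by the
#' truncated-normal correction factor so it estimates the full-distribution
#' SD; with lesions present this resists inflation of sigma by the
#' hyperintense tail.
#'
#' @param volume A `flair_volume`.
#' @param params A `segmentation_params`.
#' @return List with `mu` and `sigma` (intensity units).
#' @export
fit_intensity_gaussian <- function(volume, params = segmentation_params()) {
  x <- volume$data[volume$mask]
  if (length(x) < 2) stop("need at least 2 in-mask voxels")
  if (params$fit_method == "trimmed" && params$trim_fraction > 0) {
    q <- stats::quantile(x, c(params$trim_fraction, 1 - params$trim_fraction),
                         names = FALSE, type = 7)
    x <- x[x >= q[1] & x <= q[2]]
  }
  mu <- mean(x)
  sigma <- sqrt(mean((x - mu)^2))
  if (sigma == 0) stop("degenerate input: zero intensity variance inside mask")
  if (params$fit_method == "trimmed" && params$trim_fraction > 0) {
    f <- params$trim_fraction
    z <- stats::qnorm(1 - f)
    # variance of a standard normal truncated to (-z, z)
    vtrunc <- 1 - 2 * z * stats::dnorm(z) / (1 - 2 * f)
    sigma <- sigma / sqrt(vtrunc)
  }
  list(mu = mu, sigma = sigma)
}

# Offsets for 6/18/26 voxel connectivity.
.connectivity_offsets <- function(connectivity) {
  g <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  g <- g[rowSums(abs(g)) > 0, , drop = FALSE]
  if (connectivity == 6L) g <- g[rowSums(abs(g)) == 1, , drop = FALSE]
  if (connectivity == 18L) g <- g[rowSums(abs(g)) <= 2, , drop = FALSE]
  g
}

#' Label connected components in a 3-D binary mask
#'
#' Connected-component labeling over the chosen voxel connectivity, built on
#' an explicit neighbor-edge graph of the foreground voxels.
#'
#' @param mask 3-D logical array.
#' @param connectivity 6, 18 or 26.
#' @return Integer array of the same shape: 0 for background, 1..k component
#'   labels for foreground.
#' @export
label_components_3d <- function(mask, connectivity = 26L) {
  dm <- dim(mask)
  lab <- array(0L, dim = dm)
  idx <- which(mask)
  if (length(idx) == 0) return(lab)
  pos <- arrayInd(idx, dm)
  vox_id <- integer(prod(dm))
  vox_id[idx] <- seq_along(idx)
  offs <- .connectivity_offsets(connectivity)
  offs <- offs[seq_len(nrow(offs) / 2), , drop = FALSE]  # one direction per pair
  edges <- NULL
  for (r in seq_len(nrow(offs))) {
    npos <- sweep(pos, 2, offs[r, ], "+")
    ok <- npos[, 1] >= 1 & npos[, 1] <= dm[1] &
          npos[, 2] >= 1 & npos[, 2] <= dm[2] &
          npos[, 3] >= 1 & npos[, 3] <= dm[3]
    if (!any(ok)) next
    nlin <- npos[ok, 1] + (npos[ok, 2] - 1L) * dm[1] +
            (npos[ok, 3] - 1L) * dm[1] * dm[2]
    nid <- vox_id[nlin]
    hit <- nid > 0L
    if (any(hit))
      edges <- rbind(edges, cbind(which(ok)[hit], nid[hit]))
  }
  g <- igraph::make_empty_graph(n = length(idx), directed = FALSE)
  if (!is.null(edges)) g <- igraph::add_edges(g, t(edges))
  comp <- igraph::components(g)$membership
  lab[idx] <- as.integer(comp)
  lab
}

#' Segment white matter hyperintensities
#'
#' Labels in-mask voxels with intensity strictly greater than
#' `mu + z_threshold * sigma` (ties at the threshold are excluded), then
#' removes connected components smaller than `min_component_size`.
#'
#' @param volume A `flair_volume`.
#' @param params A `segmentation_params`.
#' @param exclusion_mask Optional logical array of voxels to force to
#'   background (stand-in for manual edits).
#' @return Object of class `wmh_result`: `lesion_mask` (logical array),
#'   `mu`, `sigma`, `threshold`, `n_labeled`; volume fields unset until
#'   [regional_volumes()].
#' @export
segment_wmh <- function(volume, params = segmentation_params(),
                        exclusion_mask = NULL) {
  fit <- fit_intensity_gaussian(volume, params)
  thr <- fit$mu + params$z_threshold * fit$sigma
  lesion <- volume$mask & (volume$data > thr)
  if (!is.null(exclusion_mask)) {
    if (!identical(dim(exclusion_mask), dim(lesion)))
      stop("exclusion mask shape mismatch")
    lesion <- lesion & !exclusion_mask
  }
  if (params$min_component_size > 1L && any(lesion)) {
    lab <- label_components_3d(lesion, params$connectivity)
    sizes <- tabulate(lab[lab > 0L])
    keep <- which(sizes >= params$min_component_size)
    lesion <- array(lab %in% keep, dim = dim(lesion))
  }
  structure(list(lesion_mask = lesion, mu = fit$mu, sigma = fit$sigma,
                 threshold = thr, n_labeled = sum(lesion),
                 total_volume_cm3 = NULL, lobar_volumes_cm3 = NULL),
            class = "wmh_result")
}

#' @export
print.wmh_result <- function(x, ...) {
  cat(sprintf("wmh_result: mu = %.4g, sigma = %.4g, threshold = %.4g, %d voxels labeled\n",
              x$mu, x$sigma, x$threshold, x$n_labeled))
  if (!is.null(x$total_volume_cm3)) {
    cat(sprintf("  total WMH volume: %.4f cm^3\n", x$total_volume_cm3))
    lv <- x$lobar_volumes_cm3
    cat("  lobar:", paste(sprintf("%s %.4f", names(lv), lv), collapse = ", "), "\n")
  }
  invisible(x)
}

.lobe_names <- c("frontal", "temporal", "parietal", "occipital")
.lobe_codes <- c(unassigned = 0L, frontal = 1L, temporal = 2L,
                 parietal = 3L, occipital = 4L)

#' Lobar atlas container
#'
#' @param labels 3-D integer array with codes 0 (unassigned), 1 (frontal),
#'   2 (temporal), 3 (parietal), 4 (occipital).
#' @return Object of class `lobar_atlas`.
#' @export
lobar_atlas <- function(labels) {
  labels <- array(as.integer(labels), dim = dim(labels))
  if (!all(labels %in% 0:4))
    stop("atlas labels must be 0 (unassigned) or 1..4 (frontal, temporal, parietal, occipital)")
  structure(list(labels = labels), class = "lobar_atlas")
}

#' Total and lobar WMH volumes
#'
#' Converts labeled voxel counts to cm^3 using the voxel dimensions, in
#' total and within each lobe of the atlas. Labeled voxels outside the four
#' lobes are reported under `unassigned`; the total counts every labeled
#' voxel regardless of lobe.
#'
#' @param result A `wmh_result` from [segment_wmh()].
#' @param atlas A `lobar_atlas` in subject space (identity alignment
#'   assumed).
#' @param volume The `flair_volume` supplying the voxel dimensions.
#' @return The `wmh_result` with `total_volume_cm3` and
#'   `lobar_volumes_cm3` (named: frontal, temporal, parietal, occipital,
#'   unassigned) filled in.
#' @export
regional_volumes <- function(result, atlas, volume) {
  if (!identical(dim(atlas$labels), dim(result$lesion_mask)))
    stop("atlas and lesion mask have different shapes")
  vox_cm3 <- prod(volume$voxdim) / 1000
  labs <- atlas$labels[result$lesion_mask]
  counts <- vapply(.lobe_codes, function(code) sum(labs == code), integer(1))
  vols <- counts * vox_cm3
  result$total_volume_cm3 <- result$n_labeled * vox_cm3
  result$lobar_volumes_cm3 <- vols[c(.lobe_names, "unassigned")]
  result
}
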