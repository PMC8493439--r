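# Synthetic FLAIR-like volumes with planted hyperintense lesions and an
# axis-aligned lobar partition. The signal model matches the assumption
# behind Gaussian-threshold segmentation: in-mask background intensity is
# Gaussian, lesion voxels sit a fixed number of background SDs above the
# mean. Geometry is deliberately simple (ellipsoidal mask, octant lobes):
# the goal is verifiable ground truth, not anatomy.

#' Image simulation configuration
#'
#' @param shape Grid size in voxels per axis (length 3).
#' @param voxdim Isotropic voxel size in mm (scalar).
#' @param background_mean,background_sd Mean and SD of in-mask background
#'   intensity (arbitrary units).
#' @param n_lesions Number of spherical lesions to plant. The default
#'   lesion count and radius give a total lesion load of ~4.6 cm^3 at
#'   1 mm isotropic voxels, matching the mean total WMH volume of the
#'   motivating cohort (4.81 cm^3).
#' @param lesion_radius Lesion radius in voxels.
#' @param lesion_offset_sd Lesion intensity offset above the background
#'   mean, in multiples of the background SD (> 0). Default 6: well clear
#'   of the 2.1 SD labeling threshold, as real WMH are on FLAIR.
#' @param seed Integer random seed; fully determines the output.
#' @return An object of class `image_sim_config`.
#' @export
image_sim_config <- function(shape = c(64, 64, 64), voxdim = 1,
                             background_mean = 100, background_sd = 10,
                             n_lesions = 12, lesion_radius = 4.5,
                             lesion_offset_sd = 6, seed = 1L) {
  if (length(shape) != 3 || any(shape < 8)) stop("shape must be 3 axes of >= 8 voxels")
  if (voxdim <= 0) stop("voxdim must be positive")
  if (background_sd <= 0) stop("background_sd must be positive")
  if (n_lesions < 0) stop("n_lesions must be >= 0")
  if (lesion_offset_sd <= 0) stop("lesion_offset_sd must be > 0")
  if (lesion_radius < 1) stop("lesion_radius must be >= 1 voxel")
  structure(list(shape = as.integer(shape), voxdim = voxdim,
                 background_mean = background_mean, background_sd = background_sd,
                 n_lesions = as.integer(n_lesions), lesion_radius = lesion_radius,
                 lesion_offset_sd = lesion_offset_sd, seed = as.integer(seed)),
            class = "image_sim_config")
}

# Ellipsoidal brain mask centered in the grid, semi-axes 0.4 * shape.
.brain_mask <- function(shape) {
  cx <- (shape + 1) / 2
  ax <- 0.4 * shape
  x <- (seq_len(shape[1]) - cx[1]) / ax[1]
  y <- (seq_len(shape[2]) - cx[2]) / ax[2]
  z <- (seq_len(shape[3]) - cx[3]) / ax[3]
  r2 <- outer(outer(x^2, y^2, "+"), z^2, "+")
  r2 <= 1
}

# Octant partition of the mask into the four lobes (left-right symmetric):
# anterior-superior = frontal, anterior-inferior = temporal,
# posterior-superior = parietal, posterior-inferior = occipital.
.octant_atlas <- function(shape, mask) {
  cy <- (shape[2] + 1) / 2
  cz <- (shape[3] + 1) / 2
  anterior <- rep(seq_len(shape[2]) <= cy, each = shape[1])
  anterior <- array(anterior, dim = shape)
  superior <- rep(seq_len(shape[3]) > cz, each = shape[1] * shape[2])
  superior <- array(superior, dim = shape)
  lab <- array(0L, dim = shape)
  lab[mask & anterior & superior]  <- .lobe_codes[["frontal"]]
  lab[mask & anterior & !superior] <- .lobe_codes[["temporal"]]
  lab[mask & !anterior & superior] <- .lobe_codes[["parietal"]]
  lab[mask & !anterior & !superior] <- .lobe_codes[["occipital"]]
  lobar_atlas(lab)
}

#' Simulate a FLAIR-like volume with planted lesions
#'
#' Draws in-mask background intensities from the configured Gaussian, sets
#' lesion voxels to exactly `background_mean + lesion_offset_sd *
#' background_sd`, and returns the volume together with an octant lobar
#' atlas and the ground-truth lesion mask. Lesions are non-overlapping
#' spheres placed uniformly inside the mask; if placement fails after
#' exhausting candidate positions, the function errors rather than
#' silently planting fewer lesions.
#'
#' @param config An `image_sim_config`.
#' @return List with `volume` (a [flair_volume()]), `atlas` (a
#'   [lobar_atlas()]) and `truth` (logical lesion mask).
#' @export
simulate_flair <- function(config) {
  set.seed(config$seed)
  shape <- config$shape
  mask <- .brain_mask(shape)
  data <- array(0, dim = shape)
  n_in <- sum(mask)
  data[mask] <- stats::rnorm(n_in, config$background_mean, config$background_sd)

  truth <- array(FALSE, dim = shape)
  if (config$n_lesions > 0) {
    r <- config$lesion_radius
    offs <- as.matrix(expand.grid(dx = -ceiling(r):ceiling(r),
                                  dy = -ceiling(r):ceiling(r),
                                  dz = -ceiling(r):ceiling(r)))
    offs <- offs[rowSums(offs^2) <= r^2, , drop = FALSE]
    candidates <- which(mask)
    placed <- 0
    attempts <- 0
    max_attempts <- 200L * config$n_lesions
    while (placed < config$n_lesions) {
      attempts <- attempts + 1
      if (attempts > max_attempts)
        stop("lesion placement impossible: ", config$n_lesions,
             " lesions of radius ", r, " do not fit in the mask")
      ctr <- arrayInd(sample(candidates, 1), shape)
      vox <- sweep(offs, 2, as.integer(ctr), "+")
      ok <- vox[, 1] >= 1 & vox[, 1] <= shape[1] &
            vox[, 2] >= 1 & vox[, 2] <= shape[2] &
            vox[, 3] >= 1 & vox[, 3] <= shape[3]
      if (!all(ok)) next
      lin <- vox[, 1] + (vox[, 2] - 1L) * shape[1] +
             (vox[, 3] - 1L) * shape[1] * shape[2]
      if (!all(mask[lin]) || any(truth[lin])) next
      truth[lin] <- TRUE
      placed <- placed + 1
    }
    data[truth] <- config$background_mean +
      config$lesion_offset_sd * config$background_sd
  }
  list(volume = flair_volume(data, mask, rep(config$voxdim, 3)),
       atlas = .octant_atlas(shape, mask),
       truth = truth)
}

#' Write a simulated image set to disk
#'
#' Writes the FLAIR volume, brain mask, lobar atlas and truth lesion mask
#' as NIfTI files into a directory.
#'
#' @param sim Output of [simulate_flair()].
#' @param dir Output directory (created if needed).
#' @param gzip Compress as `.nii.gz` (default TRUE).
#' @return Named character vector of the four file paths, invisibly.
#' @export
write_image_set <- function(sim, dir, gzip = TRUE) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ext <- if (gzip) ".nii.gz" else ".nii"
  vd <- sim$volume$voxdim
  paths <- c(flair = file.path(dir, paste0("flair", ext)),
             mask = file.path(dir, paste0("brain_mask", ext)),
             atlas = file.path(dir, paste0("lobar_atlas", ext)),
             truth = file.path(dir, paste0("truth_lesions", ext)))
  write_nifti(sim$volume$data, paths["flair"], vd, "float32")
  write_nifti(sim$volume$mask, paths["mask"], vd, "uint8")
  write_nifti(sim$atlas$labels, paths["atlas"], vd, "uint8")
  write_nifti(sim$truth, paths["truth"], vd, "uint8")
  invisible(paths)
}
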