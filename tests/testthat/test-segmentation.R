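test_that("moments fit and threshold reproduce the hand-worked toy volume", {
  vol <- toy_flair()
  fit <- fit_intensity_gaussian(vol, segmentation_params())
  expect_equal(fit$mu, 101)
  expect_equal(fit$sigma, sqrt(99))
  seg <- segment_wmh(vol, segmentation_params())       # min size 5, one 10-voxel line
  expect_equal(seg$threshold, 101 + 2.1 * sqrt(99))
  expect_equal(sort(which(seg$lesion_mask)), toy_bright_idx())
  expect_equal(seg$n_labeled, 10L)
  # z = 11 puts the threshold above 200: empty mask
  seg11 <- segment_wmh(vol, segmentation_params(z_threshold = 11))
  expect_equal(seg11$n_labeled, 0L)
})

test_that("degenerate intensity input is rejected", {
  flat <- flair_volume(array(5, c(4, 4, 4)), array(TRUE, c(4, 4, 4)))
  expect_error(fit_intensity_gaussian(flat), "zero intensity variance")
  expect_error(flair_volume(array(1, c(2, 2, 2)), array(FALSE, c(2, 2, 2))),
               "mask is empty")
  expect_error(flair_volume(array(1, c(2, 2, 2)), array(TRUE, c(2, 2, 3))),
               "different shapes")
})

test_that("trimmed and moments fits both recover pure-Gaussian parameters", {
  set.seed(11)
  n <- 2e5
  data <- array(rnorm(n + 16, 100, 10), c(60, 60, 60))[1:60, 1:60, 1:56]
  n <- length(data)
  vol <- flair_volume(data, array(TRUE, dim(data)))
  se_mu <- 10 / sqrt(n); se_sd <- 10 / sqrt(2 * n)
  for (p in list(segmentation_params(fit_method = "moments"),
                 segmentation_params(fit_method = "trimmed", trim_fraction = 0.05),
                 segmentation_params(fit_method = "trimmed", trim_fraction = 0.2))) {
    fit <- fit_intensity_gaussian(vol, p)
    expect_lt(abs(fit$mu - 100), 3 * se_mu)
    expect_lt(abs(fit$sigma - 10), 4 * se_sd)
  }
  # trimming resists a planted hyperintense tail that inflates the moments SD
  data2 <- data; data2[1:4000] <- 200
  vol2 <- flair_volume(data2, array(TRUE, dim(data2)))
  s_mom <- fit_intensity_gaussian(vol2, segmentation_params())$sigma
  s_trim <- fit_intensity_gaussian(vol2,
    segmentation_params(fit_method = "trimmed", trim_fraction = 0.05))$sigma
  # the asymmetric share of Gaussian vs contaminant inside the trim window
  # leaves a small residual bias, so the check is coarse by design
  expect_gt(s_mom, 13)
  expect_lt(abs(s_trim - 10), 0.5)
})

test_that("labeling is monotone in z and affine-equivariant in intensity", {
  set.seed(3)
  for (i in 1:5) {
    data <- array(rnorm(4096, 50, 5), c(16, 16, 16))
    mask <- array(runif(4096) < 0.9, c(16, 16, 16))
    mask[1] <- TRUE
    vol <- flair_volume(data, mask)
    p1 <- segmentation_params(z_threshold = 1.2, min_component_size = 1)
    p2 <- segmentation_params(z_threshold = 2.0, min_component_size = 1)
    m1 <- which(segment_wmh(vol, p1)$lesion_mask)
    m2 <- which(segment_wmh(vol, p2)$lesion_mask)
    expect_true(all(m2 %in% m1))
    vol_aff <- flair_volume(2.5 * data + 40, mask)
    expect_equal(which(segment_wmh(vol_aff, p1)$lesion_mask), m1)
  }
})

test_that("3-D component labeling matches a brute-force oracle", {
  set.seed(21)
  for (conn in c(6L, 18L, 26L)) {
    mask <- array(runif(512) < 0.25, c(8, 8, 8))
    lab <- label_components_3d(mask, conn)
    expect_equal(sort(which(lab > 0)), sort(which(mask)))
    got <- split(which(lab > 0), lab[lab > 0])
    got <- unname(lapply(got, sort))
    want <- bfs_components_3d(mask, conn)
    key <- function(l) sort(vapply(l, function(x) paste(x, collapse = ","), ""))
    expect_equal(key(got), key(want))
  }
})

test_that("the minimum-component-size filter drops small islands only", {
  data <- array(100, c(12, 12, 12))
  data[2:11, 2, 2] <- 200          # 10-voxel line
  data[2:4, 8, 8] <- 200           # 3-voxel line
  # enough background spread for a nonzero variance fit
  set.seed(1); data <- data + array(rnorm(12^3, 0, 1), c(12, 12, 12))
  vol <- flair_volume(data, array(TRUE, c(12, 12, 12)))
  seg <- segment_wmh(vol, segmentation_params(min_component_size = 5))
  lab <- which(seg$lesion_mask)
  line10 <- which(array(slice.index(data, 2) == 2 & slice.index(data, 3) == 2 &
                          slice.index(data, 1) %in% 2:11, dim(data)))
  expect_setequal(lab, line10)
  seg1 <- segment_wmh(vol, segmentation_params(min_component_size = 1))
  expect_equal(seg1$n_labeled, 13L)
})

test_that("regional volumes follow count x voxel volume, with additivity", {
  vol <- toy_flair()
  seg <- segment_wmh(vol, segmentation_params())
  atlas_par <- lobar_atlas(array(3L, c(10, 10, 10)))   # everything parietal
  res <- regional_volumes(seg, atlas_par, vol)
  expect_equal(res$total_volume_cm3, 0.01)
  expect_equal(unname(res$lobar_volumes_cm3["parietal"]), 0.01)
  expect_equal(unname(res$lobar_volumes_cm3[c("frontal", "temporal",
                                              "occipital", "unassigned")]),
               rep(0, 4))
  # 6 frontal / 4 occipital voxels at 2 mm isotropic (8 mm^3 per voxel)
  vol2 <- toy_flair(voxdim = 2)
  labels <- array(0L, c(10, 10, 10))
  labels[1:6, 1, 1] <- 1L; labels[7:10, 1, 1] <- 4L
  res2 <- regional_volumes(segment_wmh(vol2, segmentation_params()),
                           lobar_atlas(labels), vol2)
  expect_equal(unname(res2$lobar_volumes_cm3["frontal"]), 0.048)
  expect_equal(unname(res2$lobar_volumes_cm3["occipital"]), 0.032)
  expect_equal(res2$total_volume_cm3, 0.080)
  expect_equal(sum(res2$lobar_volumes_cm3), res2$total_volume_cm3)
  # empty mask -> all volumes zero
  seg11 <- segment_wmh(vol, segmentation_params(z_threshold = 11))
  res3 <- regional_volumes(seg11, atlas_par, vol)
  expect_equal(res3$total_volume_cm3, 0)
  expect_equal(sum(res3$lobar_volumes_cm3), 0)
  expect_error(regional_volumes(seg, lobar_atlas(array(0L, c(9, 9, 9))), vol),
               "different shapes")
})
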