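test_that("fixed-bin-number discretization follows its edge conventions", {
  const <- image_volume(array(40, c(3, 3, 3)))
  m <- segmentation_mask(array(TRUE, c(3, 3, 3)))
  roi <- discretize(const, m, n_bins = 32)
  expect_true(all(roi$bin_index == 1L))
  expect_equal(roi$n_levels, 32L)

  v <- image_volume(array(c(0, 1, 2, 3, rep(0, 23)), c(3, 3, 3)))
  m4 <- array(FALSE, c(3, 3, 3)); m4[1:4] <- TRUE
  roi2 <- discretize(v, segmentation_mask(m4), n_bins = 2)
  expect_equal(roi2$bin_index, c(1L, 1L, 2L, 2L))

  big <- generate_tumor_volume(quick_params(), seed = 2)
  roi3 <- discretize(big$volume, big$mask)
  expect_equal(nrow(roi3$voxel_coords), sum(big$mask$voxels))
  expect_true(all(roi3$bin_index >= 1 & roi3$bin_index <= 32))

  expect_error(discretize(const, segmentation_mask(
    array(FALSE, c(3, 3, 3)))), "empty")
  expect_error(discretize(const, m, n_bins = 1), "n_bins")
})

test_that("first-order features collapse correctly on degenerate distributions", {
  const <- image_volume(array(-12, c(3, 3, 3)))
  roi <- discretize(const, segmentation_mask(array(TRUE, c(3, 3, 3))))
  f <- first_order_features(roi)
  expect_equal(unname(f["Firstorder.histogram.Entropy"]), 0)
  expect_equal(unname(f["Firstorder.intensity.Std"]), 0)
  expect_equal(unname(f["Firstorder.intensity.Robust.mean.abs.deviation"]),
               0)
  expect_equal(unname(f["Firstorder.intensity.Root.mean.square"]), 12)
})

test_that("robust MAD matches direct enumeration on the worked values", {
  vals <- c(1, 2, 3, 4, 5, 100)
  vol <- image_volume(array(c(vals, rep(0, 21)), c(3, 3, 3)))
  m <- array(FALSE, c(3, 3, 3)); m[1:6] <- TRUE
  roi <- discretize(vol, segmentation_mask(m), n_bins = 4)
  f <- first_order_features(roi)
  q <- quantile(vals, c(.1, .9), names = FALSE)
  trimmed <- vals[vals >= q[1] & vals <= q[2]]
  expect_equal(unname(f["Firstorder.intensity.Robust.mean.abs.deviation"]),
               mean(abs(trimmed - mean(trimmed))))
})

test_that("two equally occupied gray levels carry exactly one bit of entropy", {
  vol <- image_volume(array(rep(c(0, 10), 16), c(4, 4, 2)))
  roi <- discretize(vol, segmentation_mask(array(TRUE, c(4, 4, 2))),
                    n_bins = 2)
  f <- first_order_features(roi)
  expect_equal(unname(f["Firstorder.histogram.Entropy"]), 1.0)
})

test_that("GLCM construction matches brute-force pair enumeration", {
  # 1D strip of alternating levels: mass only on (1,2)/(2,1), each 1/2
  vol <- image_volume(array(c(0, 9, 0, 9), c(4, 1, 1)))
  roi <- discretize(vol, segmentation_mask(array(TRUE, c(4, 1, 1))),
                    n_bins = 2)
  G <- build_glcm(roi)
  expect_equal(G$P, matrix(c(0, .5, .5, 0), 2, 2))

  # single-voxel ROI: degenerate, flagged, features all zero
  m1 <- array(FALSE, c(3, 3, 3)); m1[2, 2, 2] <- TRUE
  roi1 <- discretize(image_volume(array(rnorm(27), c(3, 3, 3))),
                     segmentation_mask(m1), n_bins = 4)
  G1 <- build_glcm(roi1)
  expect_true(G1$degenerate)
  expect_true(all(glcm_features(G1) == 0))

  # random ROIs: package GLCM equals the brute-force oracle, is
  # symmetric, and sums to 1 under both aggregation policies
  set.seed(404)
  for (rep in 1:10) {
    r <- random_small_roi()
    roi <- discretize(r$volume, r$mask, n_bins = 4)
    for (pol in c("average", "merge")) {
      G <- build_glcm(roi, policy = pol)
      ref <- oracle_build_glcm(roi$voxel_coords, roi$bin_index, 4,
                               policy = pol)
      expect_equal(G$P, ref, tolerance = 1e-12)
      expect_equal(G$P, t(G$P), tolerance = 1e-12)
      expect_equal(sum(G$P), 1, tolerance = 1e-12)
    }
  }
  expect_error(build_glcm(roi, distance = 0), "distance")
})

test_that("GLCM features evaluate their closed forms on point masses and diagonals", {
  # constant ROI: all mass at (1,1)
  const <- image_volume(array(5, c(3, 3, 3)))
  roi <- discretize(const, segmentation_mask(array(TRUE, c(3, 3, 3))))
  g <- glcm_features(build_glcm(roi))
  expect_equal(unname(g["Glcm.Joint.entropy"]), 0)
  expect_equal(unname(g["Glcm.Dissimilarity"]), 0)
  expect_equal(unname(g["Glcm.Difference.variance"]), 0)
  expect_equal(unname(g["Glcm.Joint.average"]), 1)

  # hand-built 2x2 diagonal GLCM
  G <- structure(list(P = diag(c(0.5, 0.5)), n_levels = 2L, distance = 1,
                      policy = "average", degenerate = FALSE),
                 class = "glcm_matrix")
  g2 <- glcm_features(G)
  expect_equal(unname(g2["Glcm.Joint.entropy"]), 1)
  expect_equal(unname(g2["Glcm.Dissimilarity"]), 0)
  expect_equal(unname(g2["Glcm.Sum.of.averages"]), 3)

  # non-normalized input is rejected
  bad <- G; bad$P <- diag(c(0.5, 0.6))
  expect_error(glcm_features(bad), "not normalized")
})

test_that("every GLCM feature equals the double-loop oracle on random matrices", {
  set.seed(77)
  for (rep in 1:20) {
    A <- matrix(runif(16), 4, 4)
    P <- (A + t(A)); P <- P / sum(P)
    G <- structure(list(P = P, n_levels = 4L, distance = 1,
                        policy = "average", degenerate = FALSE),
                   class = "glcm_matrix")
    expect_equal(glcm_features(G), oracle_glcm_features(P),
                 tolerance = 1e-12)
  }
})

test_that("ellipsoid-equivalent axes recover analytic ellipsoid dimensions", {
  p <- phantom_class_params("x", size_median_mm = 80, size_log_sd = 0,
                            axis_ratio_range = c(0.5, 0.5),
                            noise_sd_hu = 0)
  tv <- generate_tumor_volume(p, spacing_mm = c(1, 1, 1), seed = 1)
  ax <- shape_axes(tv$mask)
  expect_lt(abs(ax["long_axis_mm"] - 80) / 80, 0.05)
  expect_lt(abs(ax["short_axis_mm"] - 40) / 40, 0.05)

  sph <- phantom_class_params("s", size_median_mm = 30, size_log_sd = 0,
                              axis_ratio_range = c(1, 1), noise_sd_hu = 0)
  axs <- shape_axes(generate_tumor_volume(sph, spacing_mm = c(1, 1, 1),
                                          seed = 1)$mask)
  expect_lt(abs(axs["long_axis_mm"] - axs["short_axis_mm"]) /
              axs["long_axis_mm"], 0.02)

  # axis lengths are invariant under permutation of the grid axes
  ax2 <- shape_axes(segmentation_mask(aperm(tv$mask$voxels, c(3, 1, 2))))
  expect_equal(unname(ax), unname(ax2), tolerance = 1e-9)
})

test_that("the assembled panel has 59 deterministic, registered features", {
  cs <- quick_case(21, necrosis = 1)
  v <- extract_panel(cs)
  expect_length(v, 59)
  expect_identical(names(v), as.character(feature_panel()))
  expect_true(all(c("Tumor.short.axis", "Glcm.Joint.entropy",
                    "Firstorder.intensity.Robust.mean.abs.deviation")
                  %in% names(v)))
  expect_true(all(is.finite(v)))
  expect_identical(v, extract_panel(cs))
})

test_that("features ignore out-of-mask voxels and whole-voxel translations", {
  cs <- quick_case(33)
  v0 <- extract_panel(cs)

  scr <- cs$volume$voxels
  scr[!cs$mask_reader1$voxels] <- 999
  v1 <- extract_panel(volume = image_volume(scr),
                      mask = cs$mask_reader1)
  expect_equal(v0, v1, tolerance = 1e-12, ignore_attr = TRUE)

  # pad by 3 voxels along each axis: translation by whole voxels
  d <- dim(cs$volume$voxels)
  vox <- array(-50, d + 3)
  msk <- array(FALSE, d + 3)
  vox[3 + seq_len(d[1]), 3 + seq_len(d[2]), 3 + seq_len(d[3])] <-
    cs$volume$voxels
  msk[3 + seq_len(d[1]), 3 + seq_len(d[2]), 3 + seq_len(d[3])] <-
    cs$mask_reader1$voxels
  v2 <- extract_panel(volume = image_volume(vox),
                      mask = segmentation_mask(msk))
  expect_equal(v0, v2, tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("feature bounds hold across random phantoms", {
  for (s in 1:5) {
    v <- extract_panel(quick_case(s + 100, noise_sd = 20, corr = 1.5))
    expect_gte(v[["Firstorder.histogram.Entropy"]], 0)
    expect_lte(v[["Firstorder.histogram.Entropy"]], log2(32))
    expect_gte(v[["Glcm.Joint.entropy"]], 0)
    expect_lte(v[["Glcm.Joint.entropy"]], 2 * log2(32))
    expect_gte(v[["Glcm.Dissimilarity"]], 0)
    expect_gte(v[["Tumor.long.axis"]], v[["Tumor.short.axis"]])
  }
})
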