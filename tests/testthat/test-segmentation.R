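# One shared noisy blob phantom for the heavier checks in this file.
bp_noisy <- make_blob_phantom(n_blobs = 200, snr = 8, seed = 1)
bp_clean <- make_blob_phantom(n_blobs = 200, snr = Inf, seed = 1)
pre_shared <- preprocess_stack(bp_noisy$volume, seg_params())
fg_shared <- phansalkar_threshold(pre_shared, seg_params())

test_that("preprocessing removes flat and gradient backgrounds", {
  const <- vg(array(3, c(32, 32, 4)))
  expect_true(all(preprocess_stack(const, seg_params())$data == 0))
  # identical slices: histogram matching is the identity
  sl1 <- matrix(runif(32 * 32), 32, 32)
  rep_vol <- array(rep(sl1, 4), c(32, 32, 4))
  matched <- clarityatlas:::match_histograms_to_first(rep_vol)
  expect_equal(matched, rep_vol, tolerance = 1e-12)
  # blob phantom with linear background ramp: residual background (sampled
  # away from every blob) stays well below the signal peak
  peak <- max(pre_shared$data)
  dm <- dim(pre_shared$data)
  idx <- which(array(TRUE, dm), arr.ind = TRUE)
  ctrs <- bp_noisy$centers + 1  # world um -> index (unit spacing)
  d2min <- rep(Inf, nrow(idx))
  for (j in seq_len(nrow(ctrs))) {
    d2 <- (idx[, 1] - ctrs[j, 1])^2 + (idx[, 2] - ctrs[j, 2])^2 +
      (idx[, 3] - ctrs[j, 3])^2
    d2min <- pmin(d2min, d2)
  }
  bg_mean <- mean(pre_shared$data[d2min > 10^2])
  expect_lt(bg_mean, 0.25 * peak)
})

test_that("Phansalkar threshold follows its closed form and rejects bad input", {
  p <- seg_params()
  for (cval in c(0.1, 0.4, 0.8)) {
    img <- vg(array(cval, c(40, 40, 3)))
    got <- phansalkar_threshold(img, p)
    # constant image: local mean = c, sd = 0 -> threshold has closed form
    thr <- cval * (1 + p$phansalkar_p * exp(-p$phansalkar_q * cval) -
                     p$phansalkar_k)
    expect_true(all(got$data == (cval > thr)))
  }
  expect_true(all(!phansalkar_threshold(vg(array(0, c(20, 20, 2))),
                                        p)$data))
  expect_error(phansalkar_threshold(vg(array(2, c(8, 8, 2))), p),
               "normalized")
})

test_that("foreground mask overlaps the true blob support", {
  # ground truth: support of the noise-free blob signal at 10% of peak
  ramp <- 0.3 * (seq_len(192) - 1) / 191
  blob_only <- bp_clean$volume$data - array(ramp, dim(bp_clean$volume$data))
  truth <- blob_only > 0.1 * bp_clean$peak
  iou <- sum(truth & fg_shared$data) / sum(truth | fg_shared$data)
  expect_gte(iou, 0.7)
})

test_that("watershed separates objects and filters by size", {
  # two well-separated Gaussian blobs -> exactly two objects
  dm <- c(40, 20, 20)
  idx <- which(array(TRUE, dm), arr.ind = TRUE)
  two <- array(exp(-((idx[, 1] - 12)^2 + (idx[, 2] - 10)^2 +
                       (idx[, 3] - 10)^2) / 8) +
                 exp(-((idx[, 1] - 30)^2 + (idx[, 2] - 10)^2 +
                         (idx[, 3] - 10)^2) / 8), dm)
  img <- vg(two)
  fg <- vg_mask(img, as.vector(two > 0.2))
  seg <- segment_objects(img, fg, seg_params(minima_radius_px = 2))
  expect_equal(length(setdiff(unique(as.vector(seg$data)), 0L)), 2L)
  # touching blobs with distinct minima split near the symmetric ridge
  touch <- array(exp(-((idx[, 1] - 16)^2 + (idx[, 2] - 10)^2 +
                         (idx[, 3] - 10)^2) / 8) +
                   exp(-((idx[, 1] - 24)^2 + (idx[, 2] - 10)^2 +
                           (idx[, 3] - 10)^2) / 8), dm)
  img2 <- vg(touch)
  fg2 <- vg_mask(img2, as.vector(touch > 0.15))
  seg2 <- segment_objects(img2, fg2, seg_params())
  sizes <- table(seg2$data[seg2$data > 0])
  expect_equal(length(sizes), 2L)
  expect_lt(abs(sizes[[1]] - sizes[[2]]) / sum(sizes), 0.1)
  expect_identical(sort(unique(seg2$data[c(16, 24), 10, 10])),
                   sort(as.integer(names(sizes))))
  # objects exceeding max_object_volume_px are removed, others retained
  seg3 <- segment_objects(img, fg, seg_params(max_object_volume_px = 10))
  expect_equal(max(seg3$data), 0L)
  # every object voxel is foreground
  expect_true(all(fg2$data[seg2$data > 0]))
  # no markers -> empty segmentation with warning
  expect_warning(
    seg0 <- segment_objects(img, vg_mask(img, FALSE), seg_params()),
    "no watershed markers")
  expect_true(all(seg0$data == 0))
})

test_that("segmentation validation implements the matching formulas", {
  truth <- cbind(x = c(10, 20, 30), y = c(10, 10, 10), z = c(5, 5, 5))
  cents <- tibble::tibble(x = truth[, 1], y = truth[, 2], z = truth[, 3])
  v <- validate_segmentation(cents, truth, 2)
  expect_equal(v$specificity, 1)
  expect_equal(v$detection_rate, 1)
  extra <- rbind(cents, tibble::tibble(x = 50, y = 10, z = 5))
  v2 <- validate_segmentation(extra, truth, 2)
  expect_equal(v2$specificity, 3 / 4)
  expect_equal(v2$detection_rate, 1)
  # swapping detections and truth swaps FP and FN
  v3 <- validate_segmentation(cents, as.matrix(extra), 2)
  expect_equal(v3$fn, v2$fp)
  expect_equal(v3$fp, v2$fn)
  # empty segmentation
  v4 <- validate_segmentation(cents[0, ], truth, 2)
  expect_true(is.na(v4$specificity))
  expect_equal(v4$detection_rate, 0)
})

test_that("brain mask keeps the largest component only", {
  dm <- c(48, 32, 32)
  idx <- which(array(TRUE, dm), arr.ind = TRUE)
  ell <- ((idx[, 1] - 24)^2 / 18^2 + (idx[, 2] - 16)^2 / 10^2 +
            (idx[, 3] - 16)^2 / 10^2) <= 1
  set.seed(5)
  arr <- array(0.05 + 0.02 * rnorm(prod(dm)), dm)
  arr[ell] <- arr[ell] + 1
  speck <- runif(prod(dm)) < 0.002
  arr[speck] <- arr[speck] + 1  # isolated bright speckles
  m <- brain_mask(vg(arr))
  truth <- array(ell, dm)
  dice <- 2 * sum(m$data & truth) / (sum(m$data) + sum(truth))
  expect_gte(dice, 0.95)
  # two components, one 10x larger: only the larger survives
  a2 <- array(0, c(40, 16, 16))
  a2[2:21, 2:11, 2:11] <- 1     # 2000 voxels
  a2[30:34, 5:9, 5:9] <- 1      # 125 voxels
  m2 <- brain_mask(vg(a2), erode_radius = 1, dilate_radius = 1)
  expect_true(all(!m2$data[28:36, , ]))
  expect_true(any(m2$data[3:20, 3:10, 3:10]))
  expect_warning(mu <- brain_mask(vg(array(1, c(8, 8, 8)))), "uniform")
  expect_true(all(!mu$data))
})
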