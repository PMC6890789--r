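#' Segmentation parameters
#'
#' Defaults mirror the published protocol: per-slice rolling-background
#' removal with radius 50 px, 3D median filtering with radius 2 px,
#' Phansalkar local thresholding with radius 15 px, and 3D local minima
#' with radius 2 px for watershed markers. The Phansalkar constants
#' `k = 0.25, r = 0.5, p = 2, q = 10` are the standard published values.
#'
#' @param rolling_radius_px per-slice background window radius (pixels).
#' @param median_radius_px 3D median filter radius (pixels).
#' @param phansalkar_radius_px local-threshold neighbourhood radius (pixels).
#' @param minima_radius_px marker-detection local-minima radius (pixels).
#' @param max_object_volume_px objects above this voxel count are removed.
#' @param min_object_volume_px objects below this voxel count are removed
#'   (0 disables; set to roughly half the smallest expected cell volume to
#'   reject noise specks).
#' @param phansalkar_k,phansalkar_r,phansalkar_p,phansalkar_q Phansalkar
#'   constants.
#' @param saturate_frac fraction of voxels saturated by the contrast
#'   stretch (at each tail).
#' @return A `seg_params` list.
#' @export
seg_params <- function(rolling_radius_px = 50, median_radius_px = 2,
                       phansalkar_radius_px = 15, minima_radius_px = 2,
                       max_object_volume_px = Inf, min_object_volume_px = 0,
                       phansalkar_k = 0.25, phansalkar_r = 0.5,
                       phansalkar_p = 2, phansalkar_q = 10,
                       saturate_frac = 0.0035) {
  p <- list(rolling_radius_px = rolling_radius_px,
            median_radius_px = median_radius_px,
            phansalkar_radius_px = phansalkar_radius_px,
            minima_radius_px = minima_radius_px,
            max_object_volume_px = max_object_volume_px,
            min_object_volume_px = min_object_volume_px,
            phansalkar_k = phansalkar_k, phansalkar_r = phansalkar_r,
            phansalkar_p = phansalkar_p, phansalkar_q = phansalkar_q,
            saturate_frac = saturate_frac)
  radii <- c(p$rolling_radius_px, p$median_radius_px,
             p$phansalkar_radius_px, p$minima_radius_px)
  if (any(radii <= 0)) stop("all radii must be positive", call. = FALSE)
  structure(p, class = "seg_params")
}

#' Preprocess an image stack for segmentation
#'
#' The published chain: per-slice background removal (grayscale opening
#' with a separable square window approximating a rolling ball), histogram
#' matching of every slice to the first slice (counteracting intensity
#' fall-off across slices), percentile contrast stretching to `[0, 1]`,
#' and 3D median filtering (skipped for the dense PI nuclear stain).
#'
#' @param raw a [voxel_grid()].
#' @param params a [seg_params()].
#' @param stain `"yfp"` (sparse neurons; median filter applied) or `"pi"`
#'   (dense nuclei; median filter skipped).
#' @return A [voxel_grid()] with intensities in `[0, 1]`.
#' @export
preprocess_stack <- function(raw, params = seg_params(),
                             stain = c("yfp", "pi")) {
  stopifnot(is_voxel_grid(raw))
  stain <- match.arg(stain)
  arr <- raw$data * 1.0
  # estimate the background on a lightly pre-smoothed image (as rolling-ball
  # implementations do) so noise dips do not drag the envelope down
  sm <- conv_axis(conv_axis(arr, rep(1 / 3, 3), 1), rep(1 / 3, 3), 2)
  bg <- gray_opening(sm, params$rolling_radius_px, axes = 1:2)
  arr <- arr - bg
  arr[arr < 0] <- 0
  if (dim(arr)[3] > 1L) arr <- match_histograms_to_first(arr)
  arr <- stretch_contrast(arr, params$saturate_frac)
  if (stain == "yfp")
    arr <- cpp_median3d(as.numeric(arr), dim(arr),
                        as.integer(params$median_radius_px))
  vg_like(raw, array(arr, dim(raw$data)))
}

# Quantile-map each slice onto the empirical distribution of slice 1.
match_histograms_to_first <- function(arr) {
  ref <- sort(as.vector(arr[, , 1]))
  n <- length(ref)
  for (k in seq_len(dim(arr)[3])[-1]) {
    sl <- arr[, , k]
    r <- rank(sl, ties.method = "average")
    q <- (r - 0.5) / length(sl)
    arr[, , k] <- ref[pmin(pmax(ceiling(q * n), 1L), n)]
  }
  arr
}

# Percentile stretch to [0, 1]. The dark tail saturates `saturate_frac` of
# voxels; the bright tail only a hot-pixel guard fraction — a symmetric cut
# would land inside the signal when stained objects are sparse.
stretch_contrast <- function(arr, saturate_frac, upper_frac = 5e-5) {
  qs <- stats::quantile(arr, c(saturate_frac, 1 - upper_frac),
                        names = FALSE)
  if (qs[2] <= qs[1]) return(array(0, dim(arr)))
  arr <- (arr - qs[1]) / (qs[2] - qs[1])
  arr[arr < 0] <- 0
  arr[arr > 1] <- 1
  arr
}

#' Phansalkar local thresholding
#'
#' A voxel is foreground iff its value exceeds
#' `m * (1 + p * exp(-q * m) + k * (s / r - 1))`, where `m` and `s` are the
#' local mean and standard deviation in a disc of the configured radius
#' (computed per slice, as in the ImageJ implementation the protocol used).
#' Designed for low-contrast stained objects on dim backgrounds.
#'
#' @param img a [voxel_grid()] with intensities in `[0, 1]`.
#' @param params a [seg_params()].
#' @return A binary [voxel_grid()] (logical foreground mask).
#' @export
phansalkar_threshold <- function(img, params = seg_params()) {
  stopifnot(is_voxel_grid(img))
  if (max(img$data) > 1 + 1e-9 || min(img$data) < -1e-9)
    stop("Phansalkar thresholding expects intensities normalized to [0, 1]",
         call. = FALSE)
  dmxy <- dim(img$data)[1:2]
  rad <- min(params$phansalkar_radius_px, (min(dmxy) - 1) %/% 2)
  brush <- EBImage::makeBrush(2L * as.integer(rad) + 1L, shape = "disc")
  brush <- brush / sum(brush)
  dm <- dim(img$data)
  fg <- array(FALSE, dm)
  for (k in seq_len(dm[3])) {
    sl <- img$data[, , k]
    m <- ebi_filter2(sl, brush)
    m2 <- ebi_filter2(sl * sl, brush)
    s <- sqrt(pmax(m2 - m * m, 0))
    thr <- m * (1 + params$phansalkar_p * exp(-params$phansalkar_q * m) +
                  params$phansalkar_k * (s / params$phansalkar_r - 1))
    fg[, , k] <- sl > thr
  }
  vg_like(img, fg)
}

# filter2 with replicate boundary; isolates the EBImage call
ebi_filter2 <- function(x, brush) {
  as.matrix(EBImage::filter2(x, brush, boundary = "replicate"))
}

#' Marker-controlled 3D watershed segmentation
#'
#' Markers are 26-connected components of the 3D local minima (within the
#' configured radius) of the inverted image, restricted to the foreground
#' mask; the watershed floods the inverted image from these markers within
#' the mask, so each marker grows one object. Objects exceeding
#' `max_object_volume_px` are removed.
#'
#' @param img preprocessed [voxel_grid()] (the median-filtered image).
#' @param fg binary foreground [voxel_grid()] from
#'   [phansalkar_threshold()].
#' @param params a [seg_params()].
#' @return A `segmentation_volume`: an integer [voxel_grid()] where 0 is
#'   background and each object has a unique positive id.
#' @export
segment_objects <- function(img, fg, params = seg_params()) {
  stopifnot(is_voxel_grid(img))
  stopifnot_aligned(img, fg, "image and foreground")
  inv <- max(img$data) - img$data
  mn <- min_filter(inv, params$minima_radius_px)
  minima <- (inv <= mn + 1e-12) & (fg$data > 0)
  markers <- cpp_label3d(as.logical(minima), dim(inv))
  if (max(markers) == 0L) {
    warning("no watershed markers found; returning empty segmentation")
    out <- vg_like(img, array(0L, dim(img$data)))
    class(out) <- c("segmentation_volume", class(out))
    return(out)
  }
  lab <- cpp_watershed3d(as.numeric(inv), markers,
                         as.logical(fg$data > 0), dim(inv))
  lab <- filter_objects_by_size(lab, params$min_object_volume_px,
                                params$max_object_volume_px)
  out <- vg_like(img, lab)
  class(out) <- c("segmentation_volume", class(out))
  out
}

filter_objects_by_size <- function(lab, min_vol, max_vol) {
  if (min_vol <= 0 && !is.finite(max_vol)) return(lab)
  counts <- tabulate(lab[lab > 0])
  drop <- which(counts > max_vol | counts < min_vol)
  if (length(drop)) lab[lab %in% drop] <- 0L
  lab
}

#' Object centroids and volumes of a segmentation
#'
#' @param seg a segmentation volume from [segment_objects()].
#' @return Tibble with `object`, world-um centroid `x`, `y`, `z`, and
#'   `volume_px` / `volume_um3`.
#' @export
segmentation_centroids <- function(seg) {
  lab <- seg$data
  keep <- lab > 0
  if (!any(keep))
    return(tibble::tibble(object = integer(0), x = numeric(0),
                          y = numeric(0), z = numeric(0),
                          volume_px = integer(0), volume_um3 = numeric(0)))
  idx <- which(keep, arr.ind = TRUE)
  ids <- lab[keep]
  w <- index_to_world(seg, idx)
  agg <- rowsum(cbind(w, 1), group = ids)
  obj <- as.integer(rownames(agg))
  n <- agg[, 4]
  tibble::tibble(object = obj, x = agg[, 1] / n, y = agg[, 2] / n,
                 z = agg[, 3] / n, volume_px = as.integer(n),
                 volume_um3 = n * prod(seg$spacing_um))
}

#' Validate a segmentation against ground-truth centres
#'
#' Greedy one-to-one matching: candidate (centroid, truth) pairs within
#' `match_radius_um` are accepted nearest-first, each side used at most
#' once. Specificity = TP / (TP + FP) (fraction of detected objects that
#' are real); detection rate = TP / (TP + FN) (fraction of true cells
#' found).
#'
#' @param seg a segmentation volume, or a centroid table from
#'   [segmentation_centroids()].
#' @param truth_centers matrix or data frame of true centres (um, columns
#'   x, y, z).
#' @param match_radius_um maximum centre-to-centroid distance for a match.
#' @return List with `specificity`, `detection_rate`, `tp`, `fp`, `fn`.
#' @export
validate_segmentation <- function(seg, truth_centers, match_radius_um) {
  cents <- if (inherits(seg, "segmentation_volume"))
    segmentation_centroids(seg) else tibble::as_tibble(seg)
  truth <- as.matrix(as.data.frame(truth_centers)[, 1:3])
  if (nrow(truth) < 1) stop("need at least one truth centre", call. = FALSE)
  np <- nrow(cents)
  if (np == 0)
    return(list(specificity = NA_real_, detection_rate = 0,
                tp = 0L, fp = 0L, fn = nrow(truth)))
  P <- as.matrix(cents[, c("x", "y", "z")])
  d2 <- outer(rowSums(P^2), rowSums(truth^2), "+") - 2 * P %*% t(truth)
  d <- sqrt(pmax(d2, 0))
  cand <- which(d <= match_radius_um, arr.ind = TRUE)
  tp <- 0L
  if (nrow(cand)) {
    cand <- cand[order(d[cand]), , drop = FALSE]
    used_p <- logical(np)
    used_t <- logical(nrow(truth))
    for (r in seq_len(nrow(cand))) {
      i <- cand[r, 1]; j <- cand[r, 2]
      if (!used_p[i] && !used_t[j]) {
        used_p[i] <- TRUE
        used_t[j] <- TRUE
        tp <- tp + 1L
      }
    }
  }
  fp <- np - tp
  fn <- nrow(truth) - tp
  list(specificity = tp / (tp + fp), detection_rate = tp / (tp + fn),
       tp = tp, fp = fp, fn = fn)
}

#' Extract a brain mask from an intensity volume
#'
#' Otsu threshold, erosion, retention of the largest 26-connected
#' component, and dilation — removing speckle and imaging debris outside
#' the brain outline.
#'
#' @param volume a [voxel_grid()].
#' @param erode_radius,dilate_radius structuring radii in voxels.
#' @return A binary [voxel_grid()].
#' @export
brain_mask <- function(volume, erode_radius = 1, dilate_radius = 1) {
  stopifnot(is_voxel_grid(volume))
  arr <- volume$data
  rng <- range(arr)
  if (rng[2] <= rng[1]) {
    warning("uniform image; returning empty brain mask")
    return(vg_like(volume, array(FALSE, dim(arr))))
  }
  sc <- (arr - rng[1]) / (rng[2] - rng[1])
  # single global Otsu threshold over all voxels (one-frame image)
  thr <- EBImage::otsu(EBImage::Image(matrix(sc, ncol = 1)), range = c(0, 1))
  bin <- (sc > thr) * 1.0
  bin <- min_filter(bin, erode_radius) > 0.5
  if (!any(bin)) {
    warning("mask empty after erosion; returning empty brain mask")
    return(vg_like(volume, array(FALSE, dim(arr))))
  }
  lab <- cpp_label3d(as.logical(bin), dim(arr))
  counts <- tabulate(lab[lab > 0])
  keep <- (lab == which.max(counts)) * 1.0
  vg_like(volume, max_filter(keep, dilate_radius) > 0.5)
}
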