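#' Voxelize a full-resolution segmentation onto a coarser grid
#'
#' Centroid mode (the default) adds 1 to the coarse voxel containing each
#' object's centroid, conserving the total object count exactly. Kernel
#' mode counts, per coarse voxel, the distinct object ids intersecting a
#' sphere of `kernel_radius_um` centred on the voxel centre; objects
#' spanning several spheres are counted in each, so kernel mode is not
#' conserving (documented behaviour of the spherical-kernel convolution).
#'
#' @param seg a segmentation volume from [segment_objects()], or a
#'   centroid table (centroid mode only).
#' @param target a [voxel_grid()] defining the coarse (atlas) geometry.
#' @param mode `"centroid"` or `"kernel"`.
#' @param kernel_radius_um sphere radius for kernel mode (default 5).
#' @return An integer count [voxel_grid()] on the target geometry.
#' @export
voxelize_counts <- function(seg, target, mode = c("centroid", "kernel"),
                            kernel_radius_um = 5) {
  mode <- match.arg(mode)
  stopifnot(is_voxel_grid(target))
  dm <- dim(target$data)
  counts <- integer(prod(dm))
  if (mode == "centroid") {
    cents <- if (inherits(seg, "segmentation_volume"))
      segmentation_centroids(seg) else tibble::as_tibble(seg)
    if (nrow(cents)) {
      idx <- world_to_index(target, as.matrix(cents[, c("x", "y", "z")]))
      inb <- in_bounds(idx, dm)
      if (!all(inb)) warning("object centroid(s) outside target grid dropped")
      lin <- linear_index(idx[inb, , drop = FALSE], dm)
      tab <- tabulate(lin, prod(dm))
      counts <- tab
    }
  } else {
    if (!inherits(seg, "segmentation_volume"))
      stop("kernel mode needs the full segmentation volume", call. = FALSE)
    if (min(target$spacing_um) < min(seg$spacing_um))
      stop("target spacing must be >= segmentation spacing", call. = FALSE)
    keep <- seg$data > 0
    if (any(keep)) {
      idx <- which(keep, arr.ind = TRUE)
      w <- index_to_world(seg, idx)
      ids <- seg$data[keep]
      ctr_idx <- world_to_index(target, w)
      # candidate coarse voxels: all centres within radius of an object voxel
      reach <- ceiling(kernel_radius_um / target$spacing_um)
      offs <- as.matrix(expand.grid(-reach[1]:reach[1], -reach[2]:reach[2],
                                    -reach[3]:reach[3]))
      seen <- new.env(hash = TRUE)
      for (o in seq_len(nrow(offs))) {
        cand <- sweep(ctr_idx, 2, offs[o, ], "+")
        inb <- in_bounds(cand, dm)
        if (!any(inb)) next
        cw <- index_to_world(target, cand[inb, , drop = FALSE])
        d2 <- rowSums((cw - w[inb, , drop = FALSE])^2)
        hit <- d2 <= kernel_radius_um^2
        if (!any(hit)) next
        lin <- linear_index(cand[inb, , drop = FALSE][hit, , drop = FALSE],
                            dm)
        key <- paste(lin, ids[inb][hit])
        new <- !duplicated(key) &
          !vapply(key, exists, logical(1), envir = seen)
        for (kk in key[new]) assign(kk, TRUE, envir = seen)
        counts <- counts + tabulate(lin[new], prod(dm))
      }
    }
  }
  vg_like(target, array(as.integer(counts), dm))
}

#' Summarise voxelized counts per atlas region
#'
#' @param counts a count [voxel_grid()] from [voxelize_counts()].
#' @param labels a [label_volume()] on the same grid.
#' @param intensity optional intensity [voxel_grid()]; adds a per-region
#'   mean.
#' @param object_volumes optional numeric vector of object volumes (um^3)
#'   for a per-region mean-object-volume column (centroid bookkeeping).
#' @return Tibble with `id`, `object_count`, `region_volume_mm3`,
#'   `density` (count per mm^3) and optionally `mean_intensity`.
#' @export
region_features <- function(counts, labels, intensity = NULL,
                            object_volumes = NULL) {
  stopifnot_aligned(counts, labels, "counts and labels")
  lab <- as.vector(labels$data)
  present <- sort(unique(lab[lab != 0]))
  keep <- lab != 0
  f <- factor(lab[keep], levels = present)
  cnt <- tapply(as.vector(counts$data)[keep], f, sum)
  cnt[is.na(cnt)] <- 0
  nvox <- tabulate(f, length(present))
  vol_mm3 <- nvox * prod(labels$spacing_um) / 1e9
  zero <- vol_mm3 <= 0
  if (any(zero)) warning("region(s) with zero volume skipped")
  out <- tibble::tibble(
    id = unname(labels$id_map[as.character(present)]),
    object_count = as.numeric(cnt),
    region_volume_mm3 = vol_mm3,
    density = ifelse(vol_mm3 > 0, cnt / vol_mm3, NA_real_)
  )
  if (!is.null(intensity)) {
    stopifnot_aligned(intensity, labels, "intensity and labels")
    mi <- tapply(as.vector(intensity$data)[keep], f, mean)
    out$mean_intensity <- as.numeric(mi)
  }
  out[!zero, ]
}

#' Normalize case densities by controls and flag degeneration
#'
#' Each case region's density is divided by the mean control density for
#' that region; the degeneration score is the reciprocal of the normalized
#' density (low density = high degeneration). A region is flagged when its
#' normalized density falls below the mean over the evaluated regions
#' minus two standard deviations.
#'
#' @param case_tables list of [region_features()] tibbles (case subjects);
#'   a single tibble is also accepted.
#' @param control_tables list of [region_features()] tibbles (controls).
#' @return Tibble with `id`, `normalized_density`, `degeneration`,
#'   `flagged`.
#' @export
normalize_and_flag <- function(case_tables, control_tables) {
  as_list <- function(x) if (inherits(x, "data.frame")) list(x) else x
  case_tables <- as_list(case_tables)
  control_tables <- as_list(control_tables)
  if (length(control_tables) < 1) stop("need >= 1 control", call. = FALSE)
  dens <- function(tabs) {
    ids <- sort(unique(unlist(lapply(tabs, `[[`, "id"))))
    m <- sapply(tabs, function(t) t$density[match(ids, t$id)])
    m <- matrix(m, nrow = length(ids))
    list(ids = ids, mean = rowMeans(m, na.rm = TRUE))
  }
  ctl <- dens(control_tables)
  cse <- dens(case_tables)
  ids <- intersect(cse$ids, ctl$ids)
  ctl_mean <- ctl$mean[match(ids, ctl$ids)]
  cse_mean <- cse$mean[match(ids, cse$ids)]
  bad <- !is.finite(ctl_mean) | ctl_mean == 0
  if (any(bad))
    warning("region(s) with zero/undefined control density excluded: ",
            paste(ids[bad], collapse = ", "))
  ids <- ids[!bad]
  norm <- cse_mean[!bad] / ctl_mean[!bad]
  mu <- mean(norm)
  sdv <- stats::sd(norm)
  tibble::tibble(id = ids, normalized_density = norm,
                 degeneration = 1 / norm,
                 flagged = norm < mu - 2 * sdv)
}

#' Lesion incidence map across subjects
#'
#' Binarizes each subject's lesion mask and sums them voxelwise; the
#' thresholded mask keeps voxels delineated in more than
#' `threshold_fraction` of subjects (e.g. 0.5 for the >50% incidence
#' mask).
#'
#' @param masks list of binary [voxel_grid()]s sharing one geometry.
#' @param threshold_fraction fraction of subjects in `(0, 1)`.
#' @return List with `incidence` (integer [voxel_grid()]) and `mask`
#'   (binary [voxel_grid()]).
#' @export
incidence_map <- function(masks, threshold_fraction = 0.5) {
  stopifnot(is.list(masks), length(masks) >= 1)
  ref <- masks[[1]]
  acc <- array(0L, dim(ref$data))
  for (m in masks) {
    stopifnot_aligned(ref, m, "incidence masks")
    acc <- acc + (m$data > 0)
  }
  n <- length(masks)
  list(incidence = vg_like(ref, acc),
       mask = vg_like(ref, acc > threshold_fraction * n))
}
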