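#' Group heat-map: voxelwise sum of squares
#'
#' Computes the sum of squared values across all registered subject
#' volumes per voxel (the group "heat" of a modality). An optional
#' root-mean-square mode divides by the subject count and takes the square
#' root, for display comparability across cohort sizes.
#'
#' @param volumes list of aligned [voxel_grid()]s (one per subject).
#' @param mode `"sum_squares"` (as defined) or `"rms"`.
#' @return A [voxel_grid()] stat map.
#' @export
group_heatmap <- function(volumes, mode = c("sum_squares", "rms")) {
  mode <- match.arg(mode)
  stopifnot(is.list(volumes), length(volumes) >= 1)
  ref <- volumes[[1]]
  acc <- array(0, dim(ref$data))
  for (v in volumes) {
    stopifnot_aligned(ref, v, "heat-map volumes")
    acc <- acc + v$data^2
  }
  if (mode == "rms") acc <- sqrt(acc / length(volumes))
  vg_like(ref, acc)
}

#' Label-wise paired t-tests between hemispheres
#'
#' Two-sided paired Student's t-tests of an ipsilateral vs contralateral
#' per-region feature across subjects, one test per atlas label. When a
#' `labels` volume is given, a p-value map is painted (each label's voxels
#' take its p; labels above `alpha` are set to 1 so the map can be
#' displayed thresholded at the significance level).
#'
#' @param ipsi,contra lists of per-subject feature tibbles (columns `id`
#'   and `value_col`), paired by position.
#' @param value_col feature column name (default `"density"`).
#' @param labels optional [label_volume()] for the painted map.
#' @param alpha display threshold for the painted map.
#' @return List with `table` (tibble: `id`, `t`, `p`, `n`, `degenerate`)
#'   and `map` (a [voxel_grid()] or `NULL`).
#' @export
labelwise_paired_ttest <- function(ipsi, contra, value_col = "density",
                                   labels = NULL, alpha = 0.05) {
  stopifnot(length(ipsi) == length(contra), length(ipsi) >= 2)
  ids <- sort(unique(unlist(lapply(c(ipsi, contra), `[[`, "id"))))
  get <- function(tabs) sapply(tabs, function(t)
    t[[value_col]][match(ids, t$id)])
  mi <- matrix(get(ipsi), nrow = length(ids))
  mc <- matrix(get(contra), nrow = length(ids))
  res <- lapply(seq_along(ids), function(r) {
    d <- mi[r, ] - mc[r, ]
    d <- d[is.finite(d)]
    n <- length(d)
    if (n < 2)
      return(list(t = NA_real_, p = NA_real_, n = n, degenerate = TRUE))
    if (stats::sd(d) == 0) {
      # zero-variance differences: identical hemispheres give p = 1,
      # a constant nonzero shift is degenerate (t undefined)
      if (all(d == 0))
        return(list(t = 0, p = 1, n = n, degenerate = FALSE))
      return(list(t = NA_real_, p = NA_real_, n = n, degenerate = TRUE))
    }
    ht <- tryCatch(stats::t.test(mi[r, ], mc[r, ], paired = TRUE),
                   error = function(e) NULL)
    if (is.null(ht))
      return(list(t = NA_real_, p = NA_real_, n = n, degenerate = TRUE))
    list(t = unname(ht$statistic), p = ht$p.value, n = n,
         degenerate = FALSE)
  })
  tab <- tibble::tibble(id = ids,
                        t = vapply(res, `[[`, numeric(1), "t"),
                        p = vapply(res, `[[`, numeric(1), "p"),
                        n = vapply(res, `[[`, integer(1), "n"),
                        degenerate = vapply(res, `[[`, logical(1),
                                            "degenerate"))
  map <- NULL
  if (!is.null(labels)) {
    pvals <- tab$p
    pvals[!is.finite(pvals) | pvals > alpha] <- 1
    lut_ids <- unname(labels$id_map)
    arr <- array(1, dim(labels$data))
    for (k in seq_along(lut_ids)) {
      r <- match(lut_ids[k], tab$id)
      if (!is.na(r)) {
        val <- as.integer(names(labels$id_map)[k])
        arr[labels$data == val] <- pvals[r]
      }
    }
    map <- vg_like(labels, arr)
  }
  list(table = tab, map = map)
}

#' Voxelwise Spearman rank correlation between two maps
#'
#' Correlates two aligned volumes over the in-mask voxels, optionally
#' after dividing each hemisphere by its contralateral mean (controls
#' global intensity offsets), excluding a mask (e.g. ventricles), and
#' Gaussian pre-smoothing with a standard deviation of one voxel (absorbs
#' small registration errors).
#'
#' @param a,b aligned [voxel_grid()]s.
#' @param mask optional binary [voxel_grid()]; `NULL` = all voxels.
#' @param exclude_mask optional binary [voxel_grid()] of voxels to drop.
#' @param normalize_contralateral divide each x-half by the mean of the
#'   opposite half (per volume) before correlating.
#' @param presmooth_sigma_vox Gaussian pre-smoothing sigma in voxels
#'   (0 disables).
#' @return List with `rho`, `p`, `n`; `rho` is `NA` with a warning for
#'   constant input.
#' @export
voxelwise_spearman <- function(a, b, mask = NULL, exclude_mask = NULL,
                               normalize_contralateral = FALSE,
                               presmooth_sigma_vox = 0) {
  stopifnot_aligned(a, b, "correlation volumes")
  da <- a$data
  db <- b$data
  if (presmooth_sigma_vox > 0) {
    sp <- c(1, 1, 1)
    da <- gaussian_smooth(da, presmooth_sigma_vox, sp)
    db <- gaussian_smooth(db, presmooth_sigma_vox, sp)
  }
  if (normalize_contralateral) {
    da <- normalize_halves(da)
    db <- normalize_halves(db)
  }
  keep <- if (is.null(mask)) rep(TRUE, length(da)) else as.vector(mask$data > 0)
  if (!is.null(exclude_mask)) keep <- keep & !as.vector(exclude_mask$data > 0)
  x <- as.vector(da)[keep]
  y <- as.vector(db)[keep]
  if (length(x) < 3) stop("need >= 3 in-mask voxels", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("constant input; Spearman correlation undefined")
    return(list(rho = NA_real_, p = NA_real_, n = length(x)))
  }
  ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman"))
  list(rho = unname(ct$estimate), p = ct$p.value, n = length(x))
}

# divide the left x-half by the mean of the right half and vice versa
normalize_halves <- function(arr) {
  nx <- dim(arr)[1]
  half <- nx %/% 2
  left <- arr[seq_len(half), , , drop = FALSE]
  right <- arr[(nx - half + 1):nx, , , drop = FALSE]
  ml <- mean(left)
  mr <- mean(right)
  if (ml == 0 || mr == 0) return(arr)
  arr[seq_len(half), , ] <- left / mr
  arr[(nx - half + 1):nx, , ] <- right / ml
  arr
}

#' Landmark target registration error
#'
#' Euclidean distance per named landmark pair and the root-mean-square
#' error over pairs, in micrometres. Landmarks match by name; a name
#' present in only one set is an error.
#'
#' @param moved,reference data frames with columns `name`, `x`, `y`, `z`
#'   (um).
#' @return List with `distances` (tibble `name`, `distance_um`) and
#'   `rmse_um`.
#' @export
landmark_tre <- function(moved, reference) {
  moved <- tibble::as_tibble(moved)
  reference <- tibble::as_tibble(reference)
  if (!setequal(moved$name, reference$name) ||
      anyDuplicated(moved$name) || anyDuplicated(reference$name))
    stop("landmark names must match one-to-one between sets", call. = FALSE)
  i <- match(moved$name, reference$name)
  d <- sqrt((moved$x - reference$x[i])^2 + (moved$y - reference$y[i])^2 +
              (moved$z - reference$z[i])^2)
  list(distances = tibble::tibble(name = moved$name, distance_um = d),
       rmse_um = sqrt(mean(d^2)))
}

#' Read a landmark set from CSV
#'
#' @param path CSV with columns `name,x,y,z` in micrometres.
#' @return A tibble.
#' @export
read_landmarks <- function(path) {
  tab <- tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
  need <- c("name", "x", "y", "z")
  if (!all(need %in% names(tab)))
    stop("landmark CSV needs columns name,x,y,z", call. = FALSE)
  tab
}
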