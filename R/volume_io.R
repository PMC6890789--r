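#' Read a volumetric image
#'
#' Reads a NIfTI-1 volume (spacing and origin taken from the header; NIfTI
#' millimetres are converted to micrometres) or a multi-page TIFF stack
#' (pages become the third axis; spacing must be supplied since TIFF carries
#' no calibrated 3D geometry).
#'
#' @param path file path (`.nii`, `.nii.gz`, `.tif`, `.tiff`).
#' @param spacing_um voxel spacing in micrometres; required for TIFF,
#'   overrides the header when given for NIfTI.
#' @param axes axis codes to assume when the file carries none.
#' @return A [voxel_grid()].
#' @export
read_volume <- function(path, spacing_um = NULL, axes = "RAS") {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (grepl("\\.tiff?$", path, ignore.case = TRUE)) {
    pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
    if (!is.list(pages)) pages <- list(pages)
    if (is.null(spacing_um))
      stop("TIFF stacks carry no 3D spacing; supply `spacing_um`",
           call. = FALSE)
    data <- array(0, c(dim(pages[[1]]), length(pages)))
    for (k in seq_along(pages)) data[, , k] <- pages[[k]]
    return(voxel_grid(data, spacing_um = spacing_um, axes = axes))
  }
  img <- RNifti::readNifti(path)
  sp_mm <- RNifti::pixdim(img)[1:3]
  sp_um <- if (is.null(spacing_um)) sp_mm * 1000 else rep_len(spacing_um, 3L)
  if (any(!is.finite(sp_um)) || any(sp_um <= 0))
    stop("non-positive voxel spacing in ", path, call. = FALSE)
  xf <- RNifti::xform(img)
  origin_um <- as.numeric(xf[1:3, 4]) * 1000
  ax <- tryCatch(RNifti::orientation(img), error = function(e) axes)
  if (!nzchar(ax)) ax <- axes
  data <- array(as.vector(img), dim(img)[1:3])
  voxel_grid(data, spacing_um = sp_um, origin_um = origin_um, axes = ax)
}

#' Write a volumetric image
#'
#' NIfTI output preserves integer data bit-identically and stores spacing
#' and origin (converted to millimetres) in the header. TIFF output writes
#' one page per slice with intensities rescaled to 16-bit.
#'
#' @param grid a [voxel_grid()].
#' @param path destination (`.nii`, `.nii.gz`, `.tif`, `.tiff`).
#' @return `path`, invisibly.
#' @export
write_volume <- function(grid, path) {
  stopifnot(is_voxel_grid(grid))
  if (grepl("\\.tiff?$", path, ignore.case = TRUE)) {
    mx <- max(grid$data)
    sc <- if (mx > 0) mx else 1
    pages <- lapply(seq_len(dim(grid$data)[3]),
                    function(k) grid$data[, , k] / sc)
    tiff::writeTIFF(pages, path, bits.per.sample = 16L)
    return(invisible(path))
  }
  img <- RNifti::asNifti(grid$data)
  aff <- ras_affine(grid)
  xf <- rbind(cbind(aff$M, aff$t) / 1000, c(0, 0, 0, 1))
  RNifti::qform(img) <- structure(xf, code = 2L)
  RNifti::sform(img) <- structure(xf, code = 2L)
  RNifti::pixdim(img) <- grid$spacing_um / 1000
  RNifti::writeNifti(img, path)
  invisible(path)
}

# index -> RAS um affine of a grid: ras = M %*% (index - 1) + t
ras_affine <- function(grid) {
  ch <- validate_axis_codes(grid$axes)
  units <- list(R = c(1, 0, 0), L = c(-1, 0, 0), A = c(0, 1, 0),
                P = c(0, -1, 0), S = c(0, 0, 1), I = c(0, 0, -1))
  M <- sapply(seq_len(3), function(j) units[[ch[j]]] * grid$spacing_um[j])
  list(M = M, t = grid$origin_um)
}

#' Downsample a volume by block averaging
#'
#' Output shape is `ceiling(dim / factor)`; each output voxel is the exact
#' mean of its (possibly partial, at the far edges) `factor^3` block, and the
#' spacing is multiplied by the factor.
#'
#' @param grid a [voxel_grid()].
#' @param factor positive integer downsampling factor.
#' @return A [voxel_grid()].
#' @export
downsample <- function(grid, factor) {
  stopifnot(is_voxel_grid(grid))
  factor <- as.integer(factor)
  if (is.na(factor) || factor < 1L)
    stop("`factor` must be a positive integer", call. = FALSE)
  if (factor == 1L) return(grid)
  arr <- grid$data
  counts <- vector("list", 3)
  for (ax in 1:3) {
    dm <- dim(arr)
    n <- dm[ax]
    g <- ((seq_len(n) - 1L) %/% factor) + 1L
    ng <- max(g)
    counts[[ax]] <- tabulate(g, ng)
    A <- matrix(0, ng, n)
    A[cbind(g, seq_len(n))] <- 1
    perm <- switch(ax, `1` = c(1, 2, 3), `2` = c(2, 1, 3), `3` = c(3, 1, 2))
    a <- aperm(arr, perm)
    m <- A %*% matrix(a, nrow = dim(a)[1])
    dim(m) <- c(ng, dim(a)[2], dim(a)[3])
    arr <- aperm(m, order(perm))
  }
  denom <- outer(outer(counts[[1]], counts[[2]]), counts[[3]])
  dim(denom) <- dim(arr)
  voxel_grid(arr / denom, spacing_um = grid$spacing_um * factor,
             origin_um = grid$origin_um + (factor - 1) / 2 * grid$spacing_um,
             axes = grid$axes)
}

#' Reorient a volume to target axis codes
#'
#' Pure axis permutation and flips: voxel values are unchanged as a multiset
#' and the world (RAS) coordinate of every voxel's content is preserved.
#'
#' @param grid a [voxel_grid()].
#' @param target_codes 3-letter orientation code, e.g. `"RAS"`.
#' @return A [voxel_grid()] with `axes == target_codes`.
#' @export
orient_volume <- function(grid, target_codes) {
  stopifnot(is_voxel_grid(grid))
  src <- validate_axis_codes(grid$axes)
  tgt <- validate_axis_codes(target_codes)
  fam <- function(x) ifelse(x %in% c("R", "L"), "RL",
                            ifelse(x %in% c("A", "P"), "AP", "SI"))
  perm <- match(fam(tgt), fam(src))
  flip <- src[perm] != tgt
  data <- aperm(grid$data, perm)
  for (t in which(flip)) {
    idx <- rev(seq_len(dim(data)[t]))
    data <- switch(t, data[idx, , , drop = FALSE],
                   data[, idx, , drop = FALSE], data[, , idx, drop = FALSE])
  }
  # RAS position of the new first voxel = old voxel at (flipped ? n : 1)
  aff <- ras_affine(grid)
  flip_src <- flip[order(perm)]  # flip status per source axis
  idx0 <- ifelse(flip_src, dim(grid$data) - 1L, 0L)
  t_new <- as.numeric(aff$M %*% idx0 + aff$t)
  voxel_grid(data, spacing_um = grid$spacing_um[perm], origin_um = t_new,
             axes = toupper(target_codes))
}
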