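#' Create a voxel grid
#'
#' A `voxel_grid` is the common currency of all image stages: a 3D scalar
#' array together with its voxel spacing (micrometres), world origin
#' (micrometres, position of voxel `[1,1,1]`) and anatomical axis codes.
#' World coordinates are affine in the (1-based) voxel index:
#' `world = origin_um + (index - 1) * spacing_um` along each axis, with the
#' axis codes giving the anatomical direction of increasing index
#' (e.g. `"RAS"` = x towards Right, y towards Anterior, z towards Superior).
#'
#' @param data 3D numeric (or logical/integer) array.
#' @param spacing_um positive length-3 numeric, voxel size in micrometres.
#' @param origin_um length-3 numeric, world position of the first voxel (um).
#' @param axes 3-character orientation code, one of each letter pair
#'   R/L, A/P, S/I in any order (e.g. `"RAS"`, `"LPS"`, `"ASR"`).
#' @return An object of class `voxel_grid`.
#' @export
voxel_grid <- function(data, spacing_um = c(1, 1, 1), origin_um = c(0, 0, 0),
                       axes = "RAS") {
  if (length(dim(data)) == 2L) dim(data) <- c(dim(data), 1L)
  if (length(dim(data)) != 3L)
    stop("`data` must be a 3D array", call. = FALSE)
  spacing_um <- rep_len(as.numeric(spacing_um), 3L)
  if (any(!is.finite(spacing_um)) || any(spacing_um <= 0))
    stop("voxel spacing must be strictly positive", call. = FALSE)
  validate_axis_codes(axes)
  structure(
    list(data = data, spacing_um = spacing_um,
         origin_um = rep_len(as.numeric(origin_um), 3L), axes = axes),
    class = "voxel_grid"
  )
}

#' @export
dim.voxel_grid <- function(x) dim(x$data)

#' @export
print.voxel_grid <- function(x, ...) {
  cat(sprintf("<voxel_grid> %s voxels @ %s um [%s]\n",
              paste(dim(x$data), collapse = "x"),
              paste(signif(x$spacing_um, 4), collapse = "x"), x$axes))
  rng <- range(x$data)
  cat(sprintf("  values in [%.4g, %.4g], origin (%s) um\n", rng[1], rng[2],
              paste(signif(x$origin_um, 4), collapse = ", ")))
  invisible(x)
}

#' @export
as.array.voxel_grid <- function(x, ...) x$data

# New grid sharing x's geometry
vg_like <- function(x, data) {
  voxel_grid(data, spacing_um = x$spacing_um, origin_um = x$origin_um,
             axes = x$axes)
}

is_voxel_grid <- function(x) inherits(x, "voxel_grid")

stopifnot_aligned <- function(a, b, what = "grids") {
  if (!identical(dim(a$data), dim(b$data)) ||
      max(abs(a$spacing_um - b$spacing_um)) > 1e-6 ||
      max(abs(a$origin_um - b$origin_um)) > 1e-3)
    stop(sprintf("%s do not share grid geometry", what), call. = FALSE)
  invisible(TRUE)
}

#' World coordinates of voxel indices
#'
#' @param grid a [voxel_grid()].
#' @param index n x 3 matrix of 1-based voxel indices.
#' @return n x 3 matrix of world coordinates in micrometres.
#' @export
index_to_world <- function(grid, index) {
  index <- rbind(index)
  sweep(sweep(index - 1, 2, grid$spacing_um, "*"), 2, grid$origin_um, "+")
}

#' Voxel indices containing world points
#'
#' Points are assigned to the voxel whose centre is nearest (indices are
#' 1-based); points outside the array return indices outside `1..dim`.
#'
#' @param grid a [voxel_grid()].
#' @param world n x 3 matrix of world coordinates (um).
#' @return n x 3 integer matrix of voxel indices.
#' @export
world_to_index <- function(grid, world) {
  world <- rbind(world)
  idx <- sweep(sweep(world, 2, grid$origin_um, "-"), 2, grid$spacing_um, "/")
  matrix(as.integer(round(idx)) + 1L, ncol = 3L)
}

in_bounds <- function(idx, dm) {
  idx[, 1] >= 1L & idx[, 1] <= dm[1] &
    idx[, 2] >= 1L & idx[, 2] <= dm[2] &
    idx[, 3] >= 1L & idx[, 3] <= dm[3]
}

linear_index <- function(idx, dm) {
  (idx[, 1] - 1L) + dm[1] * ((idx[, 2] - 1L) + dm[2] * (idx[, 3] - 1L)) + 1L
}

#' Trilinear interpolation of a volume at world points
#'
#' Values outside the volume are clamped to the nearest edge voxel.
#'
#' @param grid a [voxel_grid()].
#' @param world n x 3 matrix of world coordinates (um).
#' @return numeric vector of interpolated values.
#' @export
interp_trilinear <- function(grid, world) {
  dm <- dim(grid$data)
  f <- sweep(sweep(rbind(world), 2, grid$origin_um, "-"), 2,
             grid$spacing_um, "/") + 1  # fractional 1-based index
  f[, 1] <- pmin(pmax(f[, 1], 1), dm[1])
  f[, 2] <- pmin(pmax(f[, 2], 1), dm[2])
  f[, 3] <- pmin(pmax(f[, 3], 1), dm[3])
  i0 <- pmin(floor(f), rep(dm - 1L, each = nrow(f)))
  i0 <- matrix(as.integer(i0), ncol = 3)
  t <- f - i0
  out <- numeric(nrow(f))
  for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
    w <- (if (dx) t[, 1] else 1 - t[, 1]) *
      (if (dy) t[, 2] else 1 - t[, 2]) *
      (if (dz) t[, 3] else 1 - t[, 3])
    corner <- cbind(i0[, 1] + dx, i0[, 2] + dy, i0[, 3] + dz)
    out <- out + w * grid$data[linear_index(corner, dm)]
  }
  out
}

valid_axis_letters <- c(R = "L", L = "R", A = "P", P = "A", S = "I", I = "S")

validate_axis_codes <- function(axes) {
  ch <- strsplit(toupper(axes), "")[[1]]
  if (length(ch) != 3L || !all(ch %in% names(valid_axis_letters)))
    stop("invalid axis codes: ", axes, call. = FALSE)
  fam <- function(x) ifelse(x %in% c("R", "L"), "RL",
                            ifelse(x %in% c("A", "P"), "AP", "SI"))
  if (anyDuplicated(fam(ch)))
    stop("axis codes must name three distinct anatomical axes: ", axes,
         call. = FALSE)
  invisible(ch)
}
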