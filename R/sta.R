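#' Structure-tensor analysis parameters
#'
#' @param sigma_dog_um standard deviation (um) of the first-order
#'   derivative-of-Gaussian filters that compute the intensity gradients.
#' @param sigma_g_um standard deviation (um) of the Gaussian weighting
#'   that smooths the gradient outer products into the structure tensor.
#' @param alpha_thresh_deg angular stopping threshold for streamline
#'   propagation; turns sharper than this terminate the streamline
#'   (default 35 degrees). Acts as the analog of an FA threshold: noisy
#'   orientations produce sharp turns and are cut off.
#' @param step_um streamline step length (um); `NULL` = half the smallest
#'   voxel size.
#' @param max_streamlines cap on the number of seeded streamlines
#'   (default 5000).
#' @param max_length_um maximum half-length of a streamline from its seed.
#' @param coherence_min validity cutoff: voxels whose tensor trace falls
#'   below `coherence_min * max(trace)` are marked invalid (0 disables).
#' @return An `sta_params` list.
#' @export
sta_params <- function(sigma_dog_um = 1, sigma_g_um = 2,
                       alpha_thresh_deg = 35, step_um = NULL,
                       max_streamlines = 5000, max_length_um = Inf,
                       coherence_min = 0) {
  stopifnot(sigma_dog_um > 0, sigma_g_um > 0,
            alpha_thresh_deg > 0, alpha_thresh_deg < 90)
  structure(list(sigma_dog_um = sigma_dog_um, sigma_g_um = sigma_g_um,
                 alpha_thresh_deg = alpha_thresh_deg, step_um = step_um,
                 max_streamlines = max_streamlines,
                 max_length_um = max_length_um,
                 coherence_min = coherence_min),
            class = "sta_params")
}

#' Compute a structure-tensor field
#'
#' Gradients `I_x, I_y, I_z` are computed by convolving the volume with 3D
#' first-order derivative-of-Gaussian filters of standard deviation
#' `sigma_dog_um`; the per-voxel second-moment matrix (the symmetric outer
#' product of the gradient) is then smoothed component-wise by a Gaussian
#' of standard deviation `sigma_g_um`. Both sigmas are expressed in
#' micrometres and converted to voxels per axis, so anisotropic spacing is
#' handled. The result is symmetric positive semidefinite at every voxel.
#'
#' @param img a [voxel_grid()].
#' @param params an [sta_params()].
#' @return A `tensor_field`: list of the six unique component arrays
#'   (`xx, yy, zz, xy, xz, yz`) plus geometry.
#' @export
structure_tensor_field <- function(img, params = sta_params()) {
  stopifnot(is_voxel_grid(img))
  if (length(dim(img$data)) != 3L) stop("3D input required", call. = FALSE)
  sp <- img$spacing_um
  arr <- img$data * 1.0
  gx <- gaussian_derivative(arr, params$sigma_dog_um, sp, axis = 1)
  gy <- gaussian_derivative(arr, params$sigma_dog_um, sp, axis = 2)
  gz <- gaussian_derivative(arr, params$sigma_dog_um, sp, axis = 3)
  sm <- function(a) gaussian_smooth(a, params$sigma_g_um, sp)
  structure(list(xx = sm(gx * gx), yy = sm(gy * gy), zz = sm(gz * gz),
                 xy = sm(gx * gy), xz = sm(gx * gz), yz = sm(gy * gz),
                 spacing_um = sp, origin_um = img$origin_um,
                 axes = img$axes, dim = dim(arr),
                 img_ms = mean(arr^2)),
            class = "tensor_field")
}

#' @export
print.tensor_field <- function(x, ...) {
  cat(sprintf("<tensor_field> %s voxels @ %s um\n",
              paste(x$dim, collapse = "x"),
              paste(signif(x$spacing_um, 4), collapse = "x")))
  invisible(x)
}

#' Extract the fiber orientation field from a tensor field
#'
#' The local fiber orientation at each voxel is the tertiary eigenvector
#' (smallest eigenvalue) of the structure tensor: intensity gradients mark
#' the walls of fiber tracts, so the direction of least intensity
#' variation runs along the fiber. Orientations are axial (sign-free) unit
#' vectors. Voxels whose tensor trace falls below
#' `coherence_min * max(trace)` (degenerate/background tensors) are
#' flagged invalid.
#'
#' @param tensor a `tensor_field` from [structure_tensor_field()].
#' @param coherence_min validity cutoff fraction in `[0, 1)`.
#' @return An `orientation_field`: arrays `vx, vy, vz` (unit axial vector
#'   components), `valid` mask, eigenvalue arrays, and geometry.
#' @export
orientation_field <- function(tensor, coherence_min = 0) {
  stopifnot(inherits(tensor, "tensor_field"))
  eo <- cpp_tensor_orientation(as.numeric(tensor$xx), as.numeric(tensor$yy),
                               as.numeric(tensor$zz), as.numeric(tensor$xy),
                               as.numeric(tensor$xz), as.numeric(tensor$yz))
  dm <- tensor$dim
  v <- eo$vectors
  nrm <- sqrt(rowSums(v^2))
  tr <- tensor$xx + tensor$yy + tensor$zz
  # numerical floor: a constant image yields traces of pure round-off
  # (~eps^2 relative to the image scale), far below any real gradient
  floor_tr <- 1e-20 * (tensor$img_ms %||% 1) / min(tensor$spacing_um)^2
  valid <- nrm > 0 & as.vector(tr) > floor_tr &
    as.vector(tr) >= coherence_min * max(tr)
  v <- v / pmax(nrm, 1e-300)
  structure(list(vx = array(v[, 1], dm), vy = array(v[, 2], dm),
                 vz = array(v[, 3], dm), valid = array(valid, dm),
                 eigenvalues = eo$values,
                 spacing_um = tensor$spacing_um,
                 origin_um = tensor$origin_um, axes = tensor$axes, dim = dm),
            class = "orientation_field")
}

#' @export
print.orientation_field <- function(x, ...) {
  cat(sprintf("<orientation_field> %s voxels, %.1f%% valid\n",
              paste(x$dim, collapse = "x"), 100 * mean(x$valid)))
  invisible(x)
}

#' Write an orientation field as a 4D NIfTI
#'
#' Stores the three vector components in the fourth dimension; invalid
#' voxels are written as zero vectors.
#'
#' @param field an [orientation_field()].
#' @param path output `.nii`/`.nii.gz` path.
#' @return `path`, invisibly.
#' @export
write_orientation_field <- function(field, path) {
  arr <- array(0, c(field$dim, 3L))
  arr[, , , 1] <- field$vx * field$valid
  arr[, , , 2] <- field$vy * field$valid
  arr[, , , 3] <- field$vz * field$valid
  img <- RNifti::asNifti(arr, pixdim = c(field$spacing_um / 1000, 1))
  RNifti::writeNifti(img, path)
  invisible(path)
}
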