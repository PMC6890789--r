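# Separable 3D filtering built on per-axis banded-matrix convolution with
# replicate boundary handling. Kernels are sampled Gaussians (sum-normalised)
# and first-order derivative-of-Gaussian kernels normalised so a unit linear
# ramp has derivative exactly 1 (making the analytic ramp test exact).

gaussian_kernel <- function(sigma) {
  r <- max(1L, ceiling(3 * sigma))
  x <- (-r):r
  k <- exp(-x^2 / (2 * sigma^2))
  k / sum(k)
}

dog_kernel <- function(sigma) {
  r <- max(1L, ceiling(3 * sigma))
  x <- (-r):r
  k <- -x * exp(-x^2 / (2 * sigma^2))
  # normalise so that convolving i -> i (a ramp) yields derivative 1
  k / sum(k * (-x))
}

# n x n convolution matrix with replicate boundary for a centred odd kernel
conv_matrix <- function(n, kernel) {
  r <- (length(kernel) - 1L) %/% 2L
  A <- matrix(0, n, n)
  i <- seq_len(n)
  for (o in -r:r) {
    j <- pmin(pmax(i + o, 1L), n)
    w <- kernel[o + r + 1L]
    A[cbind(i, j)] <- A[cbind(i, j)] + w
  }
  A
}

# Convolve a 3D array along one axis (1, 2 or 3) with a 1D kernel.
conv_axis <- function(arr, kernel, axis) {
  dm <- dim(arr)
  perm <- switch(axis, `1` = c(1, 2, 3), `2` = c(2, 1, 3), `3` = c(3, 1, 2))
  a <- aperm(arr, perm)
  da <- dim(a)
  A <- conv_matrix(da[1], kernel)
  m <- A %*% matrix(a, nrow = da[1])
  dim(m) <- da
  aperm(m, order(perm))
}

# Isotropic-in-um Gaussian smoothing: sigma_um converted to voxels per axis.
gaussian_smooth <- function(arr, sigma_um, spacing_um) {
  for (ax in 1:3) {
    s <- sigma_um / spacing_um[ax]
    if (s > 1e-8) arr <- conv_axis(arr, gaussian_kernel(s), ax)
  }
  arr
}

# Derivative of Gaussian along `axis` (per-um units), Gaussian along others.
gaussian_derivative <- function(arr, sigma_um, spacing_um, axis) {
  for (ax in 1:3) {
    s <- sigma_um / spacing_um[ax]
    k <- if (ax == axis) dog_kernel(s) / spacing_um[ax] else gaussian_kernel(s)
    arr <- conv_axis(arr, k, ax)
  }
  arr
}

# Grayscale erosion/dilation with a separable square/cube window (Rcpp).
min_filter <- function(arr, radius, axes = 1:3) {
  dm <- dim(arr)
  for (ax in axes)
    arr <- cpp_minmax_axis(as.numeric(arr), as.integer(dm),
                           as.integer(radius), as.integer(ax), FALSE)
  array(arr, dm)
}

max_filter <- function(arr, radius, axes = 1:3) {
  dm <- dim(arr)
  for (ax in axes)
    arr <- cpp_minmax_axis(as.numeric(arr), as.integer(dm),
                           as.integer(radius), as.integer(ax), TRUE)
  array(arr, dm)
}

# Grayscale opening (erosion then dilation); `axes = 1:2` gives the per-slice
# 2D behaviour used for background estimation.
gray_opening <- function(arr, radius, axes = 1:3) {
  max_filter(min_filter(arr, radius, axes), radius, axes)
}
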