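#' Trim leading and trailing volumes
#'
#' Discards dummy volumes acquired for scanner signal stabilisation at the
#' start and spare volumes at the end of a run. Geometry and TR are
#' unchanged.
#'
#' @param run a [bold_run].
#' @param n_start volumes to drop from the front.
#' @param n_end volumes to drop from the back.
#' @return a [bold_run] with `n_start + n_end` fewer volumes.
#' @export
trim_volumes <- function(run, n_start, n_end) {
  nt <- n_volumes(run)
  if (n_start < 0 || n_end < 0) stop_invalid("trim counts must be >= 0")
  if (nt <= n_start + n_end) {
    stop_invalid("run has ", nt, " volumes; cannot trim ", n_start, "+", n_end)
  }
  keep <- (n_start + 1):(nt - n_end)
  bold_run(run$data[, , , keep, drop = FALSE], tr = run$tr,
           voxel_size = run$voxel_size, affine = run$affine, mask = run$mask)
}

# Separable 1D Gaussian convolution matrix (zero-padded boundaries: rows near
# the edge sum to less than one rather than being renormalised).
gaussian_kernel_matrix <- function(n, sigma_vox) {
  if (sigma_vox <= 0) return(diag(n))
  half <- max(1L, ceiling(4 * sigma_vox))
  w <- stats::dnorm(-half:half, sd = sigma_vox)
  w <- w / sum(w)
  K <- matrix(0, n, n)
  for (j in seq_len(n)) {
    i <- (j - half):(j + half)
    ok <- i >= 1 & i <= n
    K[i[ok], j] <- w[ok]
  }
  t(K)
}

# Apply a matrix along one axis of a 4D (or 3D) array.
apply_axis <- function(arr, K, axis) {
  d <- dim(arr)
  perm <- c(axis, setdiff(seq_along(d), axis))
  m <- matrix(aperm(arr, perm), nrow = d[axis])
  out <- K %*% m
  aperm(array(out, dim = d[perm]), order(perm))
}

#' Spatial Gaussian smoothing
#'
#' Convolves every volume with an isotropic Gaussian of the given full width
#' at half maximum, applied separably per axis with
#' `sigma_mm = fwhm / (2 sqrt(2 ln 2))` converted to voxels. Boundaries are
#' zero-padded.
#'
#' @param run a [bold_run].
#' @param fwhm_mm kernel FWHM in mm; 0 is the identity.
#' @return smoothed [bold_run].
#' @export
smooth_gaussian <- function(run, fwhm_mm) {
  if (fwhm_mm < 0) stop_invalid("fwhm must be >= 0")
  if (fwhm_mm == 0) return(run)
  sigma_mm <- fwhm_mm / (2 * sqrt(2 * log(2)))
  d <- dim(run$data)
  out <- run$data
  for (ax in 1:3) {
    K <- gaussian_kernel_matrix(d[ax], sigma_mm / run$voxel_size[ax])
    out <- apply_axis(out, K, ax)
  }
  bold_run(out, tr = run$tr, voxel_size = run$voxel_size,
           affine = run$affine, mask = run$mask)
}

# Orthonormal DCT-II drift basis: columns k = 1..K, zero-mean by construction.
dct_basis <- function(n, tr, cutoff_s) {
  K <- floor(2 * n * tr / cutoff_s)
  if (K < 1) return(matrix(numeric(0), nrow = n, ncol = 0))
  t_idx <- seq_len(n) - 0.5
  B <- sapply(seq_len(K), function(k) cos(pi * k * t_idx / n))
  B <- matrix(B, nrow = n)
  sweep(B, 2, sqrt(colSums(B^2)), "/")
}

#' Temporal high-pass filter
#'
#' Removes fluctuations slower than the cut-off period by residualising each
#' voxel series against a discrete-cosine drift basis (all DCT components
#' with period above `cutoff_s`). The temporal mean is retained. The operator
#' is a projection, hence idempotent.
#'
#' @param run a [bold_run].
#' @param cutoff_s cut-off period in seconds; must exceed `2 * tr`.
#' @return filtered [bold_run].
#' @export
highpass_filter <- function(run, cutoff_s) {
  if (cutoff_s <= 2 * run$tr) stop_invalid("cutoff must exceed 2*TR")
  nt <- n_volumes(run)
  B <- dct_basis(nt, run$tr, cutoff_s)
  if (ncol(B) == 0) return(run)
  d <- dim(run$data)
  Y <- t(matrix(run$data, nrow = prod(d[1:3])))   # t x voxels
  Yf <- Y - B %*% crossprod(B, Y)
  bold_run(array(t(Yf), dim = d), tr = run$tr, voxel_size = run$voxel_size,
           affine = run$affine, mask = run$mask)
}

# Filter an arbitrary regressor with the same DCT operator used on the data.
highpass_vector <- function(x, tr, cutoff_s) {
  B <- dct_basis(length(x), tr, cutoff_s)
  if (ncol(B) == 0) return(x)
  drop(x - B %*% crossprod(B, x))
}

#' Intensity-threshold brain mask
#'
#' A voxel enters the mask when its temporal-mean intensity reaches
#' `threshold_fraction` of the robust maximum (the 98th percentile of the
#' mean image). Scaling the data globally does not change the mask.
#'
#' @param run a [bold_run].
#' @param threshold_fraction fraction of the robust maximum, in `[0, 1)`;
#'   0 admits every voxel with positive mean intensity.
#' @return 3D logical array.
#' @export
brain_mask <- function(run, threshold_fraction = 0.1) {
  mean_img <- rowMeans(matrix(run$data, nrow = prod(dim(run$data)[1:3])))
  if (all(mean_img == 0)) stop_invalid("all-zero run: cannot form a brain mask")
  rmax <- stats::quantile(mean_img, 0.98, names = FALSE)
  mask <- mean_img >= threshold_fraction * rmax & mean_img > 0
  if (!any(mask)) stop_invalid("empty brain mask")
  array(mask, dim = dim(run$data)[1:3])
}

#' Standard pre-processing chain
#'
#' Trim, smooth, high-pass filter and mask in one call, mirroring the fixed
#' single-subject pipeline: trim dummy/tail volumes, 4 mm FWHM smoothing,
#' 50 s high-pass, intensity-threshold masking.
#'
#' @param run a [bold_run].
#' @param config pipeline configuration, see [default_config()].
#' @return list with `run` (pre-processed) and `mask`.
#' @export
preprocess_run <- function(run, config = default_config()) {
  pp <- config$preprocess
  r <- trim_volumes(run, pp$n_discard_start, pp$n_discard_end)
  mask <- brain_mask(r, pp$mask_threshold_fraction)
  r <- smooth_gaussian(r, pp$fwhm_mm)
  r <- highpass_filter(r, pp$highpass_cutoff_s)
  r$mask <- mask
  list(run = r, mask = mask)
}
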