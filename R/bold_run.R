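#' 4D BOLD run container
#'
#' A light container for a 4D BOLD series: the intensity array `(x, y, z, t)`,
#' the repetition time, the voxel geometry and an optional brain mask. This is
#' the unit every pipeline stage consumes and returns.
#'
#' @param data 4D numeric array `(x, y, z, t)` of finite intensities.
#' @param tr repetition time in seconds.
#' @param voxel_size length-3 positive numeric, mm per axis.
#' @param affine optional 4x4 voxel-to-world transform; defaults to a scaled
#'   identity built from `voxel_size`.
#' @param mask optional 3D logical array matching the spatial grid.
#' @return an object of class `bold_run`.
#' @export
bold_run <- function(data, tr, voxel_size = c(2, 2, 2), affine = NULL,
                     mask = NULL) {
  d <- dim(data)
  if (length(d) != 4L) stop_invalid("data must be a 4D array (x, y, z, t)")
  if (tr <= 0) stop_invalid("tr must be positive")
  if (length(voxel_size) != 3L || any(voxel_size <= 0)) {
    stop_invalid("voxel_size must be 3 positive values (mm)")
  }
  if (!all(is.finite(data))) stop_invalid("all intensities must be finite")
  if (is.null(affine)) {
    affine <- diag(c(voxel_size, 1))
  }
  if (!is.null(mask)) {
    if (!identical(dim(mask), d[1:3])) stop_invalid("mask grid mismatch")
    mask <- array(as.logical(mask), dim = d[1:3])
  }
  structure(list(data = data, tr = tr, voxel_size = as.numeric(voxel_size),
                 affine = affine, mask = mask),
            class = "bold_run")
}

#' @export
print.bold_run <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<bold_run> %d x %d x %d grid, %d volumes, TR %.3g s, voxels %s mm\n",
              d[1], d[2], d[3], d[4], x$tr,
              paste(x$voxel_size, collapse = "x")))
  invisible(x)
}

n_volumes <- function(run) dim(run$data)[4]

# time x voxel matrix of the in-mask series
run_matrix <- function(run, mask) {
  d <- dim(run$data)
  m <- matrix(run$data, nrow = prod(d[1:3]), ncol = d[4])
  t(m[as.vector(mask), , drop = FALSE])
}

# place a per-voxel vector back into a 3D volume (0 outside mask)
vector_to_volume <- function(v, mask) {
  vol <- array(0, dim = dim(mask))
  vol[mask] <- v
  vol
}
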