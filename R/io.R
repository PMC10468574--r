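#' Read and write BOLD runs as NIfTI-1
#'
#' `write_bold_nifti()` stores the 4D array with the voxel sizes and TR in the
#' header pixdims; `read_bold_nifti()` reconstructs a [bold_run] from a file
#' written that way (or any 4D NIfTI with a sensible header).
#'
#' @param run a [bold_run].
#' @param path file path, conventionally ending in `.nii.gz`.
#' @return `write_bold_nifti()` returns `path` invisibly; `read_bold_nifti()`
#'   returns a [bold_run].
#' @export
write_bold_nifti <- function(run, path) {
  img <- RNifti::asNifti(run$data)
  RNifti::pixdim(img) <- c(run$voxel_size, run$tr)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_bold_nifti
#' @export
read_bold_nifti <- function(path) {
  img <- RNifti::readNifti(path)
  pd <- RNifti::pixdim(img)
  arr <- array(as.numeric(img), dim = dim(img))
  bold_run(arr, tr = pd[4], voxel_size = pd[1:3])
}

#' Write a 3D volume (mask or statistic map) as NIfTI-1
#' @param vol 3D array (logical masks are stored as 0/1).
#' @param voxel_size mm per axis.
#' @param path output path.
#' @export
write_volume_nifti <- function(vol, voxel_size, path) {
  img <- RNifti::asNifti(array(as.numeric(vol), dim = dim(vol)))
  RNifti::pixdim(img) <- voxel_size
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Events table I/O (BIDS-style TSV)
#'
#' Writes the paradigm as a BIDS-style events table with `onset`, `duration`
#' and `trial_type` columns. Onsets are in seconds relative to the first
#' stored volume, so the dummy-volume lead-in is included.
#'
#' @param p a paradigm from [make_block_paradigm()].
#' @param path output TSV path.
#' @export
write_events_tsv <- function(p, path) {
  df <- data.frame(
    onset = p$block_onsets + p$n_dummy * p$tr,
    duration = p$block_durations,
    trial_type = "task"
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_events_tsv
#' @export
read_events_tsv <- function(path) {
  utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
}

#' Motion parameter I/O (FSL .par dialect)
#'
#' Six whitespace-separated columns per volume: three rotations (radians)
#' followed by three translations (mm), matching FSL's `mcflirt` output.
#' Internally motion tables are kept as matrices with columns
#' `trans_x/y/z` (mm) then `rot_x/y/z` (rad).
#'
#' @param motion n x 6 matrix with columns trans_x, trans_y, trans_z,
#'   rot_x, rot_y, rot_z.
#' @param path output path.
#' @export
write_motion_par <- function(motion, path) {
  stopifnot(ncol(motion) == 6L)
  out <- cbind(motion[, 4:6, drop = FALSE], motion[, 1:3, drop = FALSE])
  utils::write.table(format(out, digits = 8), path, sep = "  ",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_motion_par
#' @export
read_motion_par <- function(path) {
  m <- as.matrix(utils::read.table(path))
  stopifnot(ncol(m) == 6L)
  out <- cbind(m[, 4:6, drop = FALSE], m[, 1:3, drop = FALSE])
  colnames(out) <- c("trans_x", "trans_y", "trans_z",
                     "rot_x", "rot_y", "rot_z")
  out
}

#' Serialize the ground-truth sidecar
#'
#' One NIfTI per planted mask plus a JSON parameter file, so the truth is
#' inspectable with standard viewers.
#'
#' @param truth a ground truth object from [make_ground_truth()].
#' @param dir output directory (created if missing).
#' @export
write_truth_sidecar <- function(truth, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (i in seq_along(truth$region_masks)) {
    write_volume_nifti(truth$region_masks[[i]], truth$voxel_size,
                       file.path(dir, sprintf("region_%02d.nii.gz", i)))
  }
  write_volume_nifti(truth$brain_mask, truth$voxel_size,
                     file.path(dir, "brain_mask.nii.gz"))
  if (!is.null(truth$lesion_mask)) {
    write_volume_nifti(truth$lesion_mask, truth$voxel_size,
                       file.path(dir, "lesion_mask.nii.gz"))
  }
  params <- list(
    region_amplitudes = truth$region_amplitudes,
    noise_ar = truth$noise_ar, noise_sd_pct = truth$noise_sd_pct,
    drift_periods_s = truth$drift_periods_s,
    drift_amplitudes_pct = truth$drift_amplitudes_pct,
    baseline = truth$baseline, seed = truth$seed,
    motion_artifact_gain = truth$motion_artifact_gain,
    lesion_attenuation = truth$lesion_attenuation
  )
  jsonlite::write_json(params, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
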