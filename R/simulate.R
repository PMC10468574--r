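#' Synthetic BOLD phantom ground truth
#'
#' Builds the ground-truth description a phantom scan is generated from:
#' a brain mask, planted activation regions with percent-signal-change
#' amplitudes, optional artifact sources confined to masks, a motion trace,
#' an optional lesion with signal dropout, and the noise/drift model.
#'
#' Defaults emulate a desk-scale language-mapping acquisition: a
#' 32 x 32 x 24 grid of 2 mm isotropic voxels holding an ellipsoidal "brain",
#' six planted "language-critical" regions spread over frontal, temporal,
#' parietal, occipital, median and deep locations, a baseline of 1000
#' intensity units, AR(1) temporal noise and slow cosine drift.
#'
#' @param n_volumes number of volumes the motion trace must cover.
#' @param grid_dim length-3 integer grid size.
#' @param voxel_size mm per axis.
#' @param region_amplitudes percent signal change per planted region
#'   (length 6 by default; recycled).
#' @param noise_ar AR(1) coefficient of the temporal noise.
#' @param noise_sd_pct marginal noise standard deviation, percent of baseline.
#' @param drift_periods_s periods of additive cosine drift (seconds).
#' @param drift_amplitudes_pct drift amplitudes, percent of baseline.
#' @param motion_trace n_volumes x 6 matrix (trans mm, rot rad); default a
#'   small seeded random walk.
#' @param motion_sd_mm random-walk step sd for the default motion trace.
#' @param motion_artifact_gain intensity units of rim artifact per unit of the
#'   coupled motion column (0 disables the artifact source).
#' @param motion_artifact_column which motion column drives the rim artifact.
#' @param lesion_mask optional 3D logical lesion; see [make_lesion_mask()].
#' @param lesion_attenuation fraction of planted signal removed inside the
#'   lesion (1 = complete dropout).
#' @param baseline baseline intensity inside the brain.
#' @param tr repetition time in seconds (used for drift and motion defaults).
#' @param seed integer seed; every stochastic element derives from it.
#' @return an object of class `fmridual_truth`.
#' @export
make_ground_truth <- function(n_volumes,
                              grid_dim = c(32L, 32L, 24L),
                              voxel_size = c(2, 2, 2),
                              region_amplitudes = rep(1.2, 6),
                              noise_ar = 0.3,
                              noise_sd_pct = 1.0,
                              drift_periods_s = c(128, 211),
                              drift_amplitudes_pct = c(0.3, 0.2),
                              motion_trace = NULL,
                              motion_sd_mm = 0.02,
                              motion_artifact_gain = 0,
                              motion_artifact_column = 1L,
                              lesion_mask = NULL,
                              lesion_attenuation = 1.0,
                              baseline = 1000,
                              tr = 1.7,
                              seed = 1L) {
  brain <- ellipsoid_mask(grid_dim)
  regions <- default_region_masks(grid_dim)
  region_amplitudes <- rep_len(region_amplitudes, length(regions))
  if (any(region_amplitudes < 0)) stop_invalid("amplitudes must be >= 0")
  if (is.null(motion_trace)) {
    motion_trace <- with_seed(derive_seed(seed, "motion"), {
      steps <- matrix(stats::rnorm(n_volumes * 6,
                                   sd = rep(c(rep(motion_sd_mm, 3),
                                              rep(motion_sd_mm / 50, 3)),
                                            each = n_volumes)),
                      ncol = 6)
      apply(steps, 2, cumsum)
    })
  }
  motion_trace <- as.matrix(motion_trace)
  if (nrow(motion_trace) != n_volumes) {
    stop_invalid("motion_trace length must equal emitted volume count")
  }
  colnames(motion_trace) <- c("trans_x", "trans_y", "trans_z",
                              "rot_x", "rot_y", "rot_z")
  # pairwise disjointness of planted regions is part of the contract
  overlap <- Reduce(`+`, lapply(regions, function(m) m * 1L))
  if (any(overlap > 1L)) stop_invalid("region masks must be pairwise disjoint")
  structure(list(
    grid_dim = as.integer(grid_dim), voxel_size = as.numeric(voxel_size),
    brain_mask = brain, region_masks = regions,
    region_amplitudes = region_amplitudes,
    artifact_masks = if (motion_artifact_gain != 0) list(rim_mask(brain)) else list(),
    noise_ar = noise_ar, noise_sd_pct = noise_sd_pct,
    drift_periods_s = drift_periods_s,
    drift_amplitudes_pct = drift_amplitudes_pct,
    motion_trace = motion_trace,
    motion_artifact_gain = motion_artifact_gain,
    motion_artifact_column = as.integer(motion_artifact_column),
    lesion_mask = lesion_mask, lesion_attenuation = lesion_attenuation,
    baseline = baseline, tr = tr, seed = as.integer(seed)
  ), class = "fmridual_truth")
}

# Ellipsoidal brain filling most of the grid.
ellipsoid_mask <- function(grid_dim, semi_frac = c(0.82, 0.82, 0.84)) {
  ctr <- (grid_dim + 1) / 2
  semi <- semi_frac * grid_dim / 2
  ix <- seq_len(grid_dim[1]); iy <- seq_len(grid_dim[2]); iz <- seq_len(grid_dim[3])
  dx2 <- ((ix - ctr[1]) / semi[1])^2
  dy2 <- ((iy - ctr[2]) / semi[2])^2
  dz2 <- ((iz - ctr[3]) / semi[3])^2
  outer(outer(dx2, dy2, `+`), dz2, `+`) <= 1
}

# Six spherical planted regions at fixed anatomically-flavoured offsets,
# scaled to the grid. Centres chosen inside the default ellipsoid and
# pairwise well separated.
default_region_masks <- function(grid_dim, radius_vox = 2.2) {
  rel <- rbind(
    frontal   = c(0.25, 0.75, 0.58),
    temporal  = c(0.22, 0.38, 0.38),
    parietal  = c(0.75, 0.69, 0.67),
    occipital = c(0.81, 0.31, 0.50),
    median    = c(0.50, 0.50, 0.75),
    deep      = c(0.50, 0.50, 0.38)
  )
  lapply(seq_len(nrow(rel)), function(i) {
    ctr <- rel[i, ] * grid_dim
    sphere_mask(grid_dim, ctr, radius_vox)
  })
}

sphere_mask <- function(grid_dim, centre, radius_vox) {
  ix <- seq_len(grid_dim[1]); iy <- seq_len(grid_dim[2]); iz <- seq_len(grid_dim[3])
  dx2 <- (ix - centre[1])^2
  dy2 <- (iy - centre[2])^2
  dz2 <- (iz - centre[3])^2
  outer(outer(dx2, dy2, `+`), dz2, `+`) <= radius_vox^2
}

# Brain-edge shell: voxels in the mask with a 6-neighbour outside it.
# Motion-coupled artifact sources live here, as rim intensity changes are
# where head motion expresses itself most strongly.
rim_mask <- function(brain) {
  d <- dim(brain)
  interior <- brain
  shift <- function(m, ax, by) {
    out <- array(FALSE, dim = d)
    idx_src <- lapply(d, seq_len)
    idx_dst <- idx_src
    if (by > 0) { idx_dst[[ax]] <- (1 + by):d[ax]; idx_src[[ax]] <- 1:(d[ax] - by) }
    else { idx_dst[[ax]] <- 1:(d[ax] + by); idx_src[[ax]] <- (1 - by):d[ax] }
    out[idx_dst[[1]], idx_dst[[2]], idx_dst[[3]]] <-
      m[idx_src[[1]], idx_src[[2]], idx_src[[3]]]
    out
  }
  for (ax in 1:3) for (by in c(-1, 1)) interior <- interior & shift(brain, ax, by)
  brain & !interior
}

#' Spherical lesion mask overlapping a planted region
#'
#' @param grid_dim grid size.
#' @param region_index which default region the lesion engulfs.
#' @param radius_vox lesion radius in voxels.
#' @return 3D logical array.
#' @export
make_lesion_mask <- function(grid_dim = c(32L, 32L, 24L), region_index = 2L,
                             radius_vox = 4) {
  rel <- rbind(c(0.25, 0.75, 0.58), c(0.22, 0.38, 0.38), c(0.75, 0.69, 0.67),
               c(0.81, 0.31, 0.50), c(0.50, 0.50, 0.75), c(0.50, 0.50, 0.38))
  sphere_mask(grid_dim, rel[region_index, ] * grid_dim, radius_vox)
}

#' Simulate a BOLD phantom scan
#'
#' Generates the 4D series
#' `baseline + planted activations + artifact sources + drift + AR(1) noise`
#' on the truth's grid. Planted activation time courses are the HRF-convolved
#' task boxcar scaled to the region's percent-signal-change amplitude;
#' artifact sources follow the configured motion column, confined to the
#' brain rim; lesion voxels have their planted signal attenuated. Identical
#' seeds give bit-identical output.
#'
#' @param p paradigm from [make_block_paradigm()].
#' @param truth ground truth from [make_ground_truth()].
#' @param hrf HRF kernel; default [gamma_hrf()] at the paradigm TR.
#' @return list with elements `run` (a [bold_run]) and `truth`.
#' @export
simulate_scan <- function(p, truth, hrf = gamma_hrf(tr = p$tr)) {
  stopifnot(inherits(p, "fmridual_paradigm"), inherits(truth, "fmridual_truth"))
  nv <- p$n_volumes
  if (nrow(truth$motion_trace) != nv) {
    stop_invalid("motion trace length (", nrow(truth$motion_trace),
                 ") does not match emitted volume count (", nv, ")")
  }
  d <- truth$grid_dim
  for (m in truth$region_masks) {
    if (!identical(dim(m), d)) stop_invalid("region mask grid mismatch")
  }
  # task boxcar over the full emitted run (paradigm starts after the dummies)
  mid <- (seq_len(nv) - 0.5) * p$tr
  boxcar <- numeric(nv)
  for (b in seq_len(p$n_blocks)) {
    on <- p$n_dummy * p$tr + p$block_onsets[b]
    boxcar[mid >= on & mid < on + p$block_durations[b]] <- 1
  }
  x_task <- convolve_hrf(boxcar, hrf)

  nvox <- prod(d)
  brain_idx <- which(truth$brain_mask)
  data <- matrix(0, nrow = nvox, ncol = nv)
  data[brain_idx, ] <- truth$baseline

  # planted activations (lesion voxels attenuated)
  for (i in seq_along(truth$region_masks)) {
    amp <- truth$region_amplitudes[i] / 100 * truth$baseline
    if (amp == 0) next
    idx <- which(truth$region_masks[[i]])
    gain <- rep(amp, length(idx))
    if (!is.null(truth$lesion_mask)) {
      inles <- truth$lesion_mask[idx]
      gain[inles] <- gain[inles] * (1 - truth$lesion_attenuation)
    }
    data[idx, ] <- data[idx, ] + gain %o% x_task
  }

  # motion-coupled rim artifact
  if (truth$motion_artifact_gain != 0 && length(truth$artifact_masks)) {
    tc <- truth$motion_trace[, truth$motion_artifact_column]
    for (am in truth$artifact_masks) {
      idx <- which(am)
      data[idx, ] <- data[idx, ] +
        rep(truth$motion_artifact_gain, length(idx)) %o% tc
    }
  }

  # drift + AR(1) noise inside the brain
  tsec <- (seq_len(nv) - 1) * p$tr
  if (length(truth$drift_periods_s) && any(truth$drift_amplitudes_pct > 0)) {
    ph <- with_seed(derive_seed(truth$seed, "drift"),
                    stats::runif(length(truth$drift_periods_s), 0, 2 * pi))
    drift <- rep(0, nv)
    for (k in seq_along(truth$drift_periods_s)) {
      drift <- drift + truth$drift_amplitudes_pct[k] / 100 * truth$baseline *
        cos(2 * pi * tsec / truth$drift_periods_s[k] + ph[k])
    }
    data[brain_idx, ] <- data[brain_idx, ] + rep(1, length(brain_idx)) %o% drift
  }
  sd_n <- truth$noise_sd_pct / 100 * truth$baseline
  if (sd_n > 0) {
    rho <- truth$noise_ar
    burn <- 25L
    eps <- with_seed(derive_seed(truth$seed, "noise"),
                     matrix(stats::rnorm((nv + burn) * length(brain_idx)),
                            nrow = nv + burn))
    if (rho != 0) {
      eps <- stats::filter(eps, rho, method = "recursive")
      eps <- eps * sqrt(1 - rho^2) # innovations scaled to unit marginal sd
    }
    noise <- t(eps[(burn + 1):(nv + burn), , drop = FALSE]) * sd_n
    data[brain_idx, ] <- data[brain_idx, ] + noise
  }

  run <- bold_run(array(data, dim = c(d, nv)), tr = p$tr,
                  voxel_size = truth$voxel_size, mask = truth$brain_mask)
  list(run = run, truth = truth)
}

#' Build a cohort manifest
#'
#' One row per simulated scan, mirroring the study structure: healthy
#' controls (several task runs each, clean archetype), a patient group with
#' chronic static lesions (optionally atypically lateralised activation,
#' moderate motion) and a patient group with progressive lesions (lesion
#' signal dropout, higher motion, more task-correlated-motion scans).
#' Archetype rates are free parameters of the generator, fixed here and
#' recorded per row along with a per-scan seed.
#'
#' @param n_controls number of control subjects.
#' @param tasks_per_control task runs per control subject.
#' @param group1_scans scans in the static-lesion group.
#' @param group2_scans scans in the progressive-lesion group.
#' @param seed master seed.
#' @param p_task_motion per-group probability of a task-correlated-motion scan
#'   (control, group1, group2).
#' @param p_noncompliant per-group probability the subject did not perform
#'   the task.
#' @return data.frame with one row per scan: `scan_id`, `group`, `archetype`
#'   flags (`atypical`, `lesion`, `task_motion`, `noncompliant`),
#'   `amplitude_scale`, `motion_sd_mm` and `seed`.
#' @export
make_cohort_manifest <- function(n_controls, tasks_per_control,
                                 group1_scans, group2_scans, seed = 1L,
                                 p_task_motion = c(0, 0.15, 0.30),
                                 p_noncompliant = c(0, 0.04, 0.06)) {
  if (any(c(n_controls, tasks_per_control, group1_scans, group2_scans) < 0)) {
    stop_invalid("counts must be >= 0")
  }
  groups <- c(rep("control", n_controls * tasks_per_control),
              rep("group1", group1_scans),
              rep("group2", group2_scans))
  n <- length(groups)
  if (n == 0) {
    return(data.frame(scan_id = character(), group = character(),
                      atypical = logical(), lesion = logical(),
                      task_motion = logical(), noncompliant = logical(),
                      amplitude_scale = numeric(), motion_sd_mm = numeric(),
                      seed = integer(), stringsAsFactors = FALSE))
  }
  gi <- match(groups, c("control", "group1", "group2"))
  with_seed(derive_seed(seed, "manifest"), {
    data.frame(
      scan_id = sprintf("scan_%03d", seq_len(n)),
      group = groups,
      atypical = gi == 2 & stats::runif(n) < 0.3,
      lesion = gi == 3,
      task_motion = stats::runif(n) < p_task_motion[gi],
      noncompliant = stats::runif(n) < p_noncompliant[gi],
      amplitude_scale = c(1, 0.85, 0.75)[gi] *
        stats::rnorm(n, 1, 0.08),
      motion_sd_mm = c(0.02, 0.05, 0.08)[gi],
      seed = sapply(seq_len(n), function(i)
        derive_seed(seed, paste0("scan", i))),
      stringsAsFactors = FALSE
    )
  })
}

#' Instantiate the ground truth for one manifest row
#'
#' Translates a cohort-manifest row's archetype flags into a concrete
#' [make_ground_truth()] call: non-compliant scans have zero planted
#' amplitude; atypical scans shuffle the region amplitude profile;
#' lesioned scans attenuate the signal under a lesion mask;
#' task-correlated-motion scans replace the first motion column with a
#' scaled task boxcar and couple a rim artifact source to it.
#'
#' @param row one row of [make_cohort_manifest()].
#' @param p paradigm the scan will follow.
#' @param config pipeline configuration, see [default_config()].
#' @return an `fmridual_truth` object.
#' @export
truth_from_manifest_row <- function(row, p, config = default_config()) {
  sim <- config$simulate
  amps <- rep(sim$amplitude_pct, 6) * row$amplitude_scale
  if (isTRUE(row$noncompliant)) amps[] <- 0
  if (isTRUE(row$atypical)) {
    amps <- amps * with_seed(derive_seed(row$seed, "atypical"),
                             sample(c(0.6, 0.8, 1, 1, 1.2, 1.4)))
  }
  motion <- NULL
  gain <- 0
  if (isTRUE(row$task_motion)) {
    # task-correlated motion: translation-x follows the raw task boxcar
    mid <- (seq_len(p$n_volumes) - 0.5) * p$tr
    box <- numeric(p$n_volumes)
    for (b in seq_len(p$n_blocks)) {
      on <- p$n_dummy * p$tr + p$block_onsets[b]
      box[mid >= on & mid < on + p$block_durations[b]] <- 1
    }
    motion <- with_seed(derive_seed(row$seed, "motion"), {
      steps <- matrix(stats::rnorm(p$n_volumes * 6,
                                   sd = rep(c(rep(row$motion_sd_mm, 3),
                                              rep(row$motion_sd_mm / 50, 3)),
                                            each = p$n_volumes)), ncol = 6)
      m <- apply(steps, 2, cumsum)
      # the head settles sluggishly, so the task-locked displacement is a
      # low-pass-filtered boxcar rather than a crisp square wave
      lagged <- as.numeric(stats::filter(box, 0.45, method = "recursive")) * 0.55
      m[, 1] <- m[, 1] + sim$task_motion_mm * lagged
      m
    })
    gain <- sim$motion_artifact_gain
  }
  make_ground_truth(
    n_volumes = p$n_volumes,
    grid_dim = sim$grid_dim, voxel_size = sim$voxel_size,
    region_amplitudes = amps,
    noise_ar = sim$noise_ar, noise_sd_pct = sim$noise_sd_pct,
    motion_trace = motion, motion_sd_mm = row$motion_sd_mm,
    motion_artifact_gain = gain,
    lesion_mask = if (isTRUE(row$lesion)) make_lesion_mask(sim$grid_dim) else NULL,
    lesion_attenuation = sim$lesion_attenuation,
    baseline = sim$baseline, tr = p$tr,
    seed = row$seed
  )
}
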