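#' Default pipeline configuration
#'
#' One nested list covering every stage, with the study acquisition settings
#' as defaults: TR 1.7 s, six 24 s task / 24 s control blocks, 3 dummy and 4
#' tail volumes (trimmed), 4 mm FWHM smoothing, 50 s high-pass, single-gamma
#' HRF (mean lag 6 s, std 3 s), voxel-wise z grid {2.3, 2.6, 2.9, 3.1} with
#' cluster-wise p < 0.05.
#'
#' @return nested configuration list.
#' @export
default_config <- function() {
  list(
    paradigm = list(n_blocks = 6L, task_s = 24, control_s = 24, tr = 1.7,
                    n_dummy = 3L, n_tail = 4L),
    hrf = list(mean_lag_s = 6, std_s = 3, length_s = 30),
    preprocess = list(n_discard_start = 3L, n_discard_end = 4L,
                      fwhm_mm = 4, highpass_cutoff_s = 50,
                      mask_threshold_fraction = 0.1),
    glm = list(ar_smooth_fwhm_mm = 8),
    pica = list(q = "auto", k_noise = 20, max_order = 40L, n_restarts = 3,
                max_iter = 200,
                w_spatial = 0.6, w_temporal = 0.4, split_fraction = 0.75,
                split_z = 2.3, split_dice_max = 0.2),
    threshold = list(z_grid = c(2.3, 2.6, 2.9, 3.1), cluster_p = 0.05,
                     n_sim = 200L, two_sided = FALSE),
    rubric = rubric_config(),
    simulate = list(grid_dim = c(32L, 32L, 24L), voxel_size = c(2, 2, 2),
                    baseline = 1000, amplitude_pct = 1.2,
                    noise_ar = 0.3, noise_sd_pct = 1.0,
                    lesion_attenuation = 1.0,
                    task_motion_mm = 1.2, motion_artifact_gain = 25)
  )
}

config_paradigm <- function(config) {
  pc <- config$paradigm
  make_block_paradigm(pc$n_blocks, pc$task_s, pc$control_s, pc$tr,
                      pc$n_dummy, pc$n_tail)
}

# Memoised cluster-extent nulls keyed by smoothness rounded to 0.5 mm, so a
# cohort reuses the Monte-Carlo null across scans of similar smoothness.
null_cache_env <- function() new.env(parent = emptyenv())

cached_cluster_null <- function(cache, fwhm_mm, mask, voxel_size, z_grid,
                                cluster_p, n_sim, seed) {
  fw <- pmin(pmax(round(fwhm_mm * 2) / 2, 1), 12)
  key <- paste0(paste(fw, collapse = "_"), "_", n_sim)
  if (!is.null(cache) && !is.null(cache[[key]])) return(cache[[key]])
  null <- cluster_null(fw, mask, voxel_size, z_grid, cluster_p, n_sim, seed)
  if (!is.null(cache)) cache[[key]] <- null
  null
}

#' Run the full dual pipeline on one scan
#'
#' Simulate (or accept) a scan, pre-process it, fit the GLM route and the
#' PICA route, threshold both statistic maps through the shared dual
#' thresholding scheme, and score both against the planted truth. Identical
#' seed and configuration give identical score rows.
#'
#' @param scan either a cohort-manifest row (data.frame row; the scan is
#'   simulated from its archetype) or a list `list(run = , truth = )`.
#' @param config pipeline configuration, see [default_config()].
#' @param seed integer seed for the stochastic stages (ICA initialisation,
#'   cluster null); simulation seeds come from the manifest row/truth.
#' @param null_cache optional environment from `null_cache_env()` to share
#'   Monte-Carlo cluster nulls across scans.
#' @return list with `rows` (2-row data.frame: one per method), `glm`,
#'   `ica`, `selection`, `mapsets`, `smoothness_fwhm_mm`, `mask`, `truth`.
#' @export
run_scan <- function(scan, config = default_config(), seed = 1L,
                     null_cache = NULL) {
  p <- config_paradigm(config)
  if (is.data.frame(scan)) {
    truth <- truth_from_manifest_row(scan, p, config)
    sim <- simulate_scan(p, truth, hrf = gamma_hrf(config$hrf$mean_lag_s,
                                                   config$hrf$std_s, p$tr,
                                                   config$hrf$length_s))
    scan_id <- scan$scan_id
    group <- scan$group
  } else {
    sim <- scan
    scan_id <- "scan"
    group <- "unspecified"
  }
  truth <- sim$truth
  pp <- preprocess_run(sim$run, config)
  mask <- pp$mask & truth$brain_mask # analysis stays inside the known brain
  hrf <- gamma_hrf(config$hrf$mean_lag_s, config$hrf$std_s, p$tr,
                   config$hrf$length_s)
  motion <- truth$motion_trace[(p$n_dummy + 1):(p$n_dummy + p$n_analysis), ,
                               drop = FALSE]
  design <- build_design_matrix(p, hrf, motion = motion,
                                cutoff_s = config$preprocess$highpass_cutoff_s)
  glm_res <- fit_glm(pp$run, mask, design,
                     ar_smooth_fwhm_mm = config$glm$ar_smooth_fwhm_mm)
  fw <- estimate_smoothness(glm_res$fit$residuals_white,
                            voxel_size = sim$run$voxel_size, mask = mask)
  n_eff <- sum(mask) / prod(pmax(fw / sim$run$voxel_size, 1))
  pc <- config$pica
  dec <- fit_pica(pp$run, mask, q = pc$q,
                  seed = derive_seed(seed, paste0("pica_", scan_id)),
                  k_noise = pc$k_noise, max_order = pc$max_order,
                  n_restarts = pc$n_restarts, max_iter = pc$max_iter,
                  n_effective = max(n_eff, dim(pp$run$data)[4] + 1),
                  on_nonconvergence = "warn")
  task_reg <- design$values[, design$task_column_index]
  sel <- select_task_component(dec, glm_res$zmap, task_reg,
                               w_spatial = pc$w_spatial,
                               w_temporal = pc$w_temporal,
                               split_fraction = pc$split_fraction,
                               split_z = pc$split_z,
                               split_dice_max = pc$split_dice_max)
  ica_zmaps <- zscore_components(dec)
  ica_zmap <- ica_zmaps[[sel$primary_index]]
  th <- config$threshold
  null <- cached_cluster_null(null_cache, fw, mask, sim$run$voxel_size,
                              th$z_grid, th$cluster_p, th$n_sim,
                              derive_seed(seed, "null"))
  sets <- list(
    glm = threshold_map(glm_res$zmap, mask, null, two_sided = th$two_sided),
    ica = threshold_map(ica_zmap, mask, null, two_sided = th$two_sided)
  )
  truth_union <- Reduce(`|`, truth$region_masks)
  rows <- do.call(rbind, lapply(names(sets), function(m) {
    best <- choose_best_map(sets[[m]], truth, config$rubric)
    data.frame(scan_id = scan_id, group = group, method = m,
               chosen_voxel_z = best$chosen_z, score = best$row$score,
               regions_visible = best$row$regions_visible,
               regions_satisfactory = best$row$regions_satisfactory,
               n_noise_clusters = best$row$n_noise_clusters,
               interference = best$row$interference,
               dice_truth = dice(best$chosen_map, truth_union),
               stringsAsFactors = FALSE)
  }))
  list(rows = rows, glm = glm_res, ica = dec, selection = sel,
       mapsets = sets, smoothness_fwhm_mm = fw, mask = mask, truth = truth,
       design = design, null = null)
}

#' Run a cohort of simulated scans
#'
#' Applies [run_scan()] to every manifest row (per-scan failures are
#' recorded and the cohort continues), then computes the per-group paired
#' t-tests between the two methods' scores, the score histograms and the
#' complementarity table.
#'
#' @param manifest a [make_cohort_manifest()] data.frame.
#' @param config pipeline configuration.
#' @param seed master seed for the analysis stages.
#' @param keep_details keep each scan's full [run_scan()] result (memory!).
#' @param quiet suppress per-scan progress messages.
#' @return list with `scores` (one row per scan x method), `ttests` (per
#'   group and overall patients), `complementarity`, `failures`.
#' @export
run_cohort <- function(manifest, config = default_config(), seed = 1L,
                       keep_details = FALSE, quiet = TRUE) {
  cache <- null_cache_env()
  rows <- list(); fails <- list(); details <- list()
  for (i in seq_len(nrow(manifest))) {
    row <- manifest[i, ]
    res <- tryCatch(
      run_scan(row, config, seed = derive_seed(seed, row$scan_id),
               null_cache = cache),
      error = function(e) e
    )
    if (inherits(res, "error")) {
      fails[[row$scan_id]] <- conditionMessage(res)
      next
    }
    rows[[row$scan_id]] <- res$rows
    if (keep_details) details[[row$scan_id]] <- res
    if (!quiet) {
      message(sprintf("%s [%s]: glm %d, ica %d", row$scan_id, row$group,
                      res$rows$score[res$rows$method == "glm"],
                      res$rows$score[res$rows$method == "ica"]))
    }
  }
  scores <- if (length(rows)) do.call(rbind, c(rows, make.row.names = FALSE)) else
    data.frame()
  ttests <- list()
  if (nrow(scores)) {
    by_group <- split(scores, scores$group)
    pair <- function(df) {
      g <- df[df$method == "glm", c("scan_id", "score")]
      i2 <- df[df$method == "ica", c("scan_id", "score")]
      m <- merge(g, i2, by = "scan_id", suffixes = c("_glm", "_ica"))
      if (nrow(m) < 2) return(NULL)
      c(paired_ttest(m$score_ica, m$score_glm),
        list(mean_ica = mean(m$score_ica), mean_glm = mean(m$score_glm),
             n = nrow(m)))
    }
    ttests <- lapply(by_group, pair)
    pat <- scores[scores$group != "control", ]
    if (nrow(pat)) ttests$patients <- pair(pat)
  }
  comp <- if (nrow(scores)) complementarity_table(scores) else NULL
  list(scores = scores, ttests = ttests, complementarity = comp,
       failures = fails, details = if (keep_details) details else NULL)
}
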