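#' Rubric configuration
#'
#' Parameters of the automated 0-5 map-reliability rubric: how much of a
#' planted region must be covered for it to count as visible or as covered
#' to a satisfactory extent, how little truth overlap makes a cluster a
#' noise cluster, and how close a noise cluster must come to the truth to
#' count as interfering.
#'
#' @param n_critical_regions planted regions a full map must cover.
#' @param visible_min_overlap fraction of a region's voxels that must be in
#'   the map for the region to be "visible".
#' @param satisfactory_extent_fraction fraction for "satisfactory extent".
#' @param noise_cluster_max_truth_overlap a cluster with at most this
#'   fraction of its voxels inside the truth is a noise cluster.
#' @param interference_radius_mm a noise cluster within this distance of a
#'   truth voxel interferes with reading the map.
#' @return list of class `fmridual_rubric`.
#' @export
rubric_config <- function(n_critical_regions = 6,
                          visible_min_overlap = 0.1,
                          satisfactory_extent_fraction = 0.5,
                          noise_cluster_max_truth_overlap = 0.1,
                          interference_radius_mm = 10) {
  fr <- c(visible_min_overlap, satisfactory_extent_fraction,
          noise_cluster_max_truth_overlap)
  if (any(fr < 0 | fr > 1)) stop_invalid("fractions must lie in [0, 1]")
  structure(list(n_critical_regions = n_critical_regions,
                 visible_min_overlap = visible_min_overlap,
                 satisfactory_extent_fraction = satisfactory_extent_fraction,
                 noise_cluster_max_truth_overlap = noise_cluster_max_truth_overlap,
                 interference_radius_mm = interference_radius_mm),
            class = "fmridual_rubric")
}

#' Dice overlap coefficient
#'
#' `2 |A n B| / (|A| + |B|)`; defined as 1 when both maps are empty.
#'
#' @param a,b logical arrays/vectors on the same grid.
#' @return value in `[0, 1]`.
#' @export
dice <- function(a, b) {
  if (length(a) != length(b)) stop_invalid("grid mismatch")
  sa <- sum(a); sb <- sum(b)
  if (sa + sb == 0) return(1)
  2 * sum(a & b) / (sa + sb)
}

#' Score a thresholded map against the planted truth (0-5 rubric)
#'
#' Automated surrogate of expert map reading. The decision tree:
#' * 0 - empty map, or no planted region visible.
#' * 5 - all regions visible at satisfactory extent, no noise clusters.
#' * 4 - all regions visible (some below satisfactory extent), no noise
#'   clusters.
#' * 3 - at least half the regions visible and no interfering noise
#'   cluster (distant noise clusters allowed).
#' * 2 - few regions visible and/or interfering noise present, but the
#'   visible activation is not dominated by it.
#' * 1 - interfering noise clusters outnumber the visible regions.
#'
#' @param map 3D logical thresholded map.
#' @param truth ground truth from [make_ground_truth()].
#' @param cfg a [rubric_config()].
#' @return list: `score`, `regions_visible`, `regions_satisfactory`,
#'   `n_noise_clusters`, `n_interfering`, `interference`.
#' @export
score_map <- function(map, truth, cfg = rubric_config()) {
  if (!identical(dim(map), truth$grid_dim)) stop_invalid("grid mismatch")
  regions <- truth$region_masks
  truth_union <- Reduce(`|`, regions)
  cover <- vapply(regions, function(r) sum(map & r) / sum(r), numeric(1))
  visible <- cover >= cfg$visible_min_overlap
  satisfactory <- cover >= cfg$satisfactory_extent_fraction
  lab <- label_clusters(map)
  n_noise <- 0L; n_interf <- 0L
  if (length(lab$sizes)) {
    truth_idx <- which(truth_union)
    truth_co <- arrayInd(truth_idx, truth$grid_dim)
    truth_mm <- sweep(truth_co, 2, truth$voxel_size, "*")
    for (cl in seq_along(lab$sizes)) {
      cl_idx <- which(lab$labels == cl)
      frac <- mean(truth_union[cl_idx])
      if (frac <= cfg$noise_cluster_max_truth_overlap) {
        n_noise <- n_noise + 1L
        co <- arrayInd(cl_idx, truth$grid_dim)
        co_mm <- sweep(co, 2, truth$voxel_size, "*")
        dmin <- min_cross_distance(co_mm, truth_mm)
        if (dmin <= cfg$interference_radius_mm) n_interf <- n_interf + 1L
      }
    }
  }
  nv <- sum(visible); ns <- sum(satisfactory)
  nreg <- cfg$n_critical_regions
  score <- if (length(lab$sizes) == 0 || nv == 0) {
    0L
  } else if (n_noise == 0 && nv == nreg) {
    if (ns == nreg) 5L else 4L
  } else if (nv >= ceiling(nreg / 2) && n_interf == 0) {
    3L
  } else if (n_interf > nv) {
    1L
  } else {
    2L
  }
  list(score = score, regions_visible = nv, regions_satisfactory = ns,
       n_noise_clusters = n_noise, n_interfering = n_interf,
       interference = n_interf > 0)
}

# minimum Euclidean distance between two coordinate sets (rows = points, mm)
min_cross_distance <- function(a, b) {
  if (nrow(a) == 0 || nrow(b) == 0) return(Inf)
  # chunk to bound memory on large clusters
  best <- Inf
  step <- 2000L
  for (s in seq(1, nrow(a), by = step)) {
    ai <- a[s:min(s + step - 1L, nrow(a)), , drop = FALSE]
    d2 <- outer(rowSums(ai^2), rowSums(b^2), `+`) - 2 * tcrossprod(ai, b)
    best <- min(best, sqrt(max(0, min(d2))))
  }
  best
}

#' Choose the best map from a thresholded set
#'
#' Scores every candidate map in the grid and returns the highest-scoring
#' one; ties break toward the higher voxel-wise threshold (the cleaner map),
#' mirroring how a reader prefers the strictest map that still shows the
#' full pattern.
#'
#' @param set a [threshold_map()] result.
#' @param truth ground truth.
#' @param cfg a [rubric_config()].
#' @return list: `chosen_z`, `row` (the winning [score_map()] result plus
#'   `chosen_voxel_z`), `all_scores`, `chosen_map`.
#' @export
choose_best_map <- function(set, truth, cfg = rubric_config()) {
  stopifnot(inherits(set, "fmridual_mapset"))
  rows <- lapply(set$maps, function(e) score_map(e$binary, truth, cfg))
  scores <- vapply(rows, `[[`, numeric(1), "score")
  zs <- vapply(set$maps, `[[`, numeric(1), "voxel_z")
  best <- which(scores == max(scores))
  pick <- best[which.max(zs[best])]
  row <- rows[[pick]]
  row$chosen_voxel_z <- zs[pick]
  list(chosen_z = zs[pick], row = row, all_scores = scores,
       chosen_map = set$maps[[pick]]$binary)
}

#' Paired t-test on rubric scores
#'
#' Classic paired t on the per-scan score differences, with explicit
#' conventions for degenerate inputs: all-zero differences give `t = 0,
#' p = 1`; zero-variance nonzero differences give `p = 0` (flagged).
#'
#' @param scores_a,scores_b equal-length numeric vectors.
#' @return list: `t`, `dof`, `p`, `mean_difference`, `degenerate`.
#' @export
paired_ttest <- function(scores_a, scores_b) {
  if (length(scores_a) != length(scores_b)) stop_invalid("length mismatch")
  n <- length(scores_a)
  if (n < 2) stop_invalid("need at least 2 pairs")
  d <- scores_a - scores_b
  md <- mean(d)
  sd_d <- stats::sd(d)
  if (sd_d == 0) {
    if (md == 0) {
      return(list(t = 0, dof = n - 1, p = 1, mean_difference = 0,
                  degenerate = TRUE))
    }
    return(list(t = sign(md) * Inf, dof = n - 1, p = 0, mean_difference = md,
                degenerate = TRUE))
  }
  tstat <- md / (sd_d / sqrt(n))
  list(t = tstat, dof = n - 1,
       p = 2 * stats::pt(abs(tstat), df = n - 1, lower.tail = FALSE),
       mean_difference = md, degenerate = FALSE)
}

#' Complementarity of the two methods
#'
#' Per-scan reliability bookkeeping with `reliable := score >= 3` (scores
#' 0-2 are the "unreliable" bucket): per-method reliable counts, scans where
#' exactly one method is reliable, the combined count (either method
#' reliable), and the conditional score histograms of each method on the
#' scans where the other was unreliable.
#'
#' @param table data.frame with columns `scan_id`, `method` (glm/ica) and
#'   `score`.
#' @return list of counts and histograms.
#' @export
complementarity_table <- function(table) {
  w <- stats::reshape(table[, c("scan_id", "method", "score")],
                      idvar = "scan_id", timevar = "method",
                      direction = "wide")
  names(w) <- sub("^score\\.", "", names(w))
  missing <- !stats::complete.cases(w[, c("glm", "ica")])
  if (any(missing)) {
    warning(sum(missing), " scan(s) missing a method; excluded", call. = FALSE)
    w <- w[!missing, ]
  }
  rel_g <- w$glm >= 3
  rel_i <- w$ica >= 3
  hist6 <- function(x) {
    h <- tabulate(x + 1L, nbins = 6L)
    names(h) <- 0:5
    h
  }
  list(
    n_scans = nrow(w),
    glm_reliable = sum(rel_g),
    ica_reliable = sum(rel_i),
    glm_only = sum(rel_g & !rel_i),
    ica_only = sum(rel_i & !rel_g),
    both_reliable = sum(rel_g & rel_i),
    neither_reliable = sum(!rel_g & !rel_i),
    combined_reliable = sum(rel_g | rel_i),
    glm_hist_when_ica_unreliable = hist6(w$glm[!rel_i]),
    ica_hist_when_glm_unreliable = hist6(w$ica[!rel_g]),
    score_hist_glm = hist6(w$glm),
    score_hist_ica = hist6(w$ica)
  )
}
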