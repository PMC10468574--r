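# a 20x20x16 truth with the six default regions and no nuisance sources
rubric_truth <- function() {
  p <- small_paradigm()
  make_ground_truth(p$n_volumes, grid_dim = c(20L, 20L, 16L), tr = p$tr,
                    seed = 1)
}

# build a map covering the given fraction of each listed region
cover_map <- function(truth, regions, fraction = 1) {
  m <- array(FALSE, dim = truth$grid_dim)
  for (r in regions) {
    idx <- which(truth$region_masks[[r]])
    take <- idx[seq_len(ceiling(length(idx) * fraction))]
    m[take] <- TRUE
  }
  m
}

# add a cubic cluster far from / near to the truth
add_cluster <- function(map, at, size = 2) {
  map[at[1]:(at[1] + size - 1), at[2]:(at[2] + size - 1),
      at[3]:(at[3] + size - 1)] <- TRUE
  map
}

test_that("dice matches its definition and conventions", {
  a <- c(rep(TRUE, 100), rep(FALSE, 100))
  expect_equal(dice(a, a), 1)
  expect_equal(dice(a, !a), 0)
  b <- c(rep(TRUE, 50), rep(FALSE, 50), rep(TRUE, 50), rep(FALSE, 50))
  expect_equal(dice(a, b), 0.5)
  expect_equal(dice(logical(5), logical(5)), 1)
  expect_error(dice(logical(4), logical(5)), "mismatch")
})

test_that("rubric scores the canonical map archetypes", {
  truth <- rubric_truth()
  cfg <- rubric_config()
  # empty map -> 0
  expect_equal(score_map(array(FALSE, truth$grid_dim), truth, cfg)$score, 0L)
  # all six regions fully covered, no noise -> 5
  full <- cover_map(truth, 1:6, 1)
  expect_equal(score_map(full, truth, cfg)$score, 5L)
  # all visible but one region below satisfactory extent -> 4
  partial <- cover_map(truth, 1:5, 1) | cover_map(truth, 6, 0.2)
  r4 <- score_map(partial, truth, cfg)
  expect_equal(r4$score, 4L)
  expect_equal(r4$regions_satisfactory, 5L)
  # 4 of 6 regions visible plus one distant noise cluster -> 3
  m3 <- add_cluster(cover_map(truth, 1:4, 1), c(18, 2, 15))
  r3 <- score_map(m3, truth, cfg)
  expect_equal(r3$score, 3L)
  expect_equal(r3$n_noise_clusters, 1L)
  expect_false(r3$interference)
  # few regions with interfering noise nearby -> 2
  near <- truth$region_masks[[5]] # median region centre ~ (10, 10, 12)
  m2 <- add_cluster(cover_map(truth, 1:2, 1), c(12, 12, 12))
  r2 <- score_map(m2, truth, cfg)
  expect_equal(r2$score, 2L)
  expect_true(r2$interference)
  # interfering noise clusters outnumber visible regions -> 1
  m1 <- cover_map(truth, 1, 1)
  m1 <- add_cluster(m1, c(7, 13, 12))
  m1 <- add_cluster(m1, c(12, 12, 12))
  m1 <- add_cluster(m1, c(7, 9, 7))
  r1 <- score_map(m1, truth, cfg)
  expect_equal(r1$score, 1L)
  expect_gt(r1$n_interfering, r1$regions_visible)
  expect_error(score_map(array(FALSE, c(4, 4, 4)), truth, cfg), "mismatch")
})

test_that("rubric is monotone in helpful and harmful additions", {
  truth <- rubric_truth()
  cfg <- rubric_config()
  base_maps <- list(
    cover_map(truth, 1:3, 0.6),
    cover_map(truth, 1:6, 0.3),
    cover_map(truth, 1:6, 1)
  )
  for (m in base_maps) {
    s0 <- score_map(m, truth, cfg)$score
    # adding correctly-placed voxels never lowers the score
    grown <- m | cover_map(truth, 1:6, 0.8)
    expect_gte(score_map(grown, truth, cfg)$score, s0)
    # adding a pure noise cluster never raises it
    noisy <- add_cluster(m, c(18, 2, 15))
    expect_lte(score_map(noisy, truth, cfg)$score, s0)
  }
  # score 5 exactly iff all satisfactory and zero noise clusters
  full <- cover_map(truth, 1:6, 1)
  expect_equal(score_map(full, truth, cfg)$score, 5L)
  expect_lt(score_map(add_cluster(full, c(18, 2, 15)), truth, cfg)$score, 5L)
})

test_that("best-map choice maximises the rubric with ties to stricter z", {
  truth <- rubric_truth()
  cfg <- rubric_config()
  mk_set <- function(maps) {
    structure(list(maps = lapply(seq_along(maps), function(i) {
      list(voxel_z = c(2.3, 2.6, 2.9, 3.1)[i], cluster_p = 0.05, k_star = 1,
           binary = maps[[i]], cluster_sizes = integer(0))
    }), z_grid = c(2.3, 2.6, 2.9, 3.1), smoothness_fwhm_mm = rep(4, 3)),
    class = "fmridual_mapset")
  }
  empty <- array(FALSE, truth$grid_dim)
  # all empty -> score 0 reported at the strictest threshold
  res0 <- choose_best_map(mk_set(list(empty, empty, empty, empty)), truth, cfg)
  expect_equal(res0$chosen_z, 3.1)
  expect_equal(res0$row$score, 0L)
  # signal survives at z <= 2.6 but noise contaminates the 2.3 map
  full <- cover_map(truth, 1:6, 1)
  noisy23 <- add_cluster(full, c(18, 2, 15))
  res <- choose_best_map(mk_set(list(noisy23, full, cover_map(truth, 1:4, 1),
                                     empty)), truth, cfg)
  expect_equal(res$chosen_z, 2.6)
  expect_equal(res$row$score, 5L)
  # identical maps across the grid -> strictest threshold chosen
  res_id <- choose_best_map(mk_set(list(full, full, full, full)), truth, cfg)
  expect_equal(res_id$chosen_z, 3.1)
})

test_that("paired t-test matches closed form and the reference implementation", {
  r <- paired_ttest(c(2, 1, 3, 1), c(1, 1, 2, 1)) # differences 1,0,1,0
  expect_equal(r$mean_difference, 0.5)
  expect_equal(r$t, 0.5 / (sd(c(1, 0, 1, 0)) / 2), tolerance = 1e-12)
  expect_equal(r$dof, 3)
  expect_equal(r$p, 0.1817, tolerance = 1e-3)
  # antisymmetry
  r2 <- paired_ttest(c(1, 1, 2, 1), c(2, 1, 3, 1))
  expect_equal(r2$t, -r$t)
  expect_equal(r2$p, r$p)
  expect_equal(r2$mean_difference, -0.5)
  # equal vectors
  expect_equal(paired_ttest(1:4, 1:4)$mean_difference, 0)
  expect_equal(paired_ttest(1:4, 1:4)$p, 1)
  # degenerate: constant nonzero differences
  rd <- paired_ttest(c(2, 2, 2), c(1, 1, 1))
  expect_true(rd$degenerate)
  expect_equal(rd$p, 0)
  # agreement with stats::t.test on random data
  set.seed(9)
  for (i in 1:5) {
    a <- rnorm(12); b <- rnorm(12)
    ref <- t.test(a, b, paired = TRUE)
    got <- paired_ttest(a, b)
    expect_equal(got$t, unname(ref$statistic), tolerance = 1e-10)
    expect_equal(got$p, ref$p.value, tolerance = 1e-10)
  }
  expect_error(paired_ttest(1:3, 1:4), "mismatch")
})

test_that("complementarity bookkeeping partitions the cohort", {
  tab <- data.frame(
    scan_id = rep(c("s1", "s2"), each = 2),
    method = rep(c("ica", "glm"), 2),
    score = c(5, 2, 2, 4)
  )
  comp <- complementarity_table(tab)
  expect_equal(comp$combined_reliable, 2)
  expect_equal(comp$ica_only, 1)
  expect_equal(comp$glm_only, 1)
  expect_equal(comp$both_reliable, 0)
  # partition identity
  expect_equal(comp$ica_only + comp$glm_only + comp$both_reliable +
                 comp$neither_reliable, comp$n_scans)
  # all-zero scores
  tab0 <- transform(tab, score = 0)
  expect_equal(complementarity_table(tab0)$combined_reliable, 0)
  # combined reliability dominates each method
  set.seed(3)
  tabr <- data.frame(scan_id = rep(sprintf("s%02d", 1:20), each = 2),
                     method = rep(c("glm", "ica"), 20),
                     score = sample(0:5, 40, replace = TRUE))
  cr <- complementarity_table(tabr)
  expect_gte(cr$combined_reliable, max(cr$glm_reliable, cr$ica_reliable))
  # a scan missing one method is excluded with a warning
  expect_warning(complementarity_table(tab[-1, ]), "excluded")
})
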