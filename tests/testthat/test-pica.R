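test_that("variance normalisation equalises noise scale and undoes exactly", {
  set.seed(1)
  # homoscedastic noise, std 2: recovered scale close to 2 everywhere
  X <- matrix(rnorm(170 * 800, sd = 2), 170, 800)
  vn <- variance_normalize(X, k_noise = 10)
  # scale close to the true noise std everywhere (slight downward bias from
  # the removed components is expected and small)
  expect_lt(abs(mean(vn$scale) - 2) / 2, 0.05)
  expect_lt(unname(quantile(abs(vn$scale / 2 - 1), 0.95)), 0.15)
  # two-voxel toy with stds 1 and 3 (no structured components to remove)
  Y <- cbind(rnorm(200, sd = 1), rnorm(200, sd = 3))
  vy <- variance_normalize(Y, k_noise = 0)
  expect_equal(unname(apply(vy$data, 2, sd)), c(1, 1), tolerance = 0.15)
  # exact undo
  back <- sweep(sweep(vn$data, 2, vn$scale, "*"), 2, vn$mean, "+")
  expect_equal(back, X, tolerance = 1e-10)
  # constant voxels flagged, not crashed
  Z <- cbind(matrix(rnorm(300), 100, 3), rep(2, 100))
  vz <- variance_normalize(Z, k_noise = 1)
  expect_identical(vz$excluded, c(rep(FALSE, 3), TRUE))
})

test_that("Laplace evidence selects the planted order", {
  ph <- source_phantom(5, snr = 10, seed = 1)
  ev <- eigen(tcrossprod(ph$X) / ncol(ph$X), symmetric = TRUE,
              only.values = TRUE)$values
  expect_equal(estimate_order_laplace(ev, ncol(ph$X)), 5L)
  # q is always below the number of eigenvalues
  expect_lt(estimate_order_laplace(ev, ncol(ph$X)), length(ev))
  # adding strong sources raises the selected order above noise-only
  set.seed(2)
  X0 <- matrix(rnorm(120 * 2000), 120)
  q0 <- estimate_order_laplace(eigen(tcrossprod(X0) / 2000, symmetric = TRUE,
                                     only.values = TRUE)$values, 2000)
  ph3 <- source_phantom(3, p = 120, V = 2000, snr = 10, seed = 3)
  q3 <- estimate_order_laplace(eigen(tcrossprod(ph3$X) / 2000, symmetric = TRUE,
                                     only.values = TRUE)$values, 2000)
  expect_gt(q3, q0)
  expect_error(estimate_order_laplace(c(2, 1), 100), "at least 3")
  expect_error(estimate_order_laplace(c(3, 2, 1), 3), "n_samples")
})

test_that("fixed-point unmixing recovers planted sources", {
  # two uniform sources through a tall mixing with leading block [[2,1],[1,1]]
  set.seed(9)
  S <- matrix(runif(2 * 4000, -sqrt(3), sqrt(3)), 2)
  A <- matrix(c(2, 1, 1, 1, 0, 1, 1, 0), 4, 2, byrow = TRUE)
  X <- A %*% S + 0.02 * matrix(rnorm(4 * 4000), 4)
  dec <- fit_pica(X, q = 2, seed = 4, normalize = FALSE)
  cc <- abs(cor(t(dec$sources), t(S)))
  expect_true(all(apply(cc, 2, max) > 0.99))
  # unmixing orthonormal in whitened space
  expect_lt(max(abs(tcrossprod(dec$unmixing) - diag(2))), 1e-8)
  # spatial maps keep positive skewness by convention
  ph <- source_phantom(3, p = 120, V = 3000, snr = 8, seed = 5)
  dec3 <- fit_pica(ph$X, q = 3, seed = 6)
  sk <- apply(dec3$sources, 1, function(s) mean((s - mean(s))^3))
  expect_true(all(sk >= 0))
  # purely Gaussian sources are unidentifiable -> flagged
  set.seed(7)
  Xg <- matrix(rnorm(60 * 3000), 60, 3000)
  expect_warning(fit_pica(Xg, q = 4, seed = 8, on_nonconvergence = "warn"),
                 "Gaussian|converge")
})

test_that("source recovery holds at moderate SNR with automatic order", {
  ph <- source_phantom(4, snr = 5, seed = 3)
  dec <- fit_pica(ph$X, q = "auto", seed = 2)
  expect_equal(dec$order, 4L)
  cc <- abs(cor(t(dec$sources[1:4, ]), t(ph$S)))
  expect_true(all(apply(cc, 2, max) > 0.95))
  # permutation of voxels permutes maps and preserves selection outcome
  perm <- sample(ncol(ph$X))
  dec_p <- fit_pica(ph$X[, perm], q = 4, seed = 2)
  cc_p <- abs(cor(t(dec_p$sources), t(dec$sources[, perm])))
  expect_true(all(apply(cc_p, 2, max) > 0.999))
})

test_that("component z-maps are noise-normalised", {
  ph <- source_phantom(3, p = 150, V = 4000, snr = 8, seed = 11)
  dec <- fit_pica(ph$X, q = 6, seed = 12)
  Z <- zscore_components(dec)
  # identity: z equals sources * scale / noise_std
  expect_equal(Z[2, ], dec$sources[2, ] * dec$scale / dec$noise_std,
               tolerance = 1e-12)
  # doubling the noise std halves the z-map
  dec2 <- dec
  dec2$noise_std <- dec$noise_std * 2
  expect_equal(zscore_components(dec2)[1, ], Z[1, ] / 2, tolerance = 1e-12)
  # noise-dominated components are approximately standard normal
  expect_lt(abs(mean(abs(Z[5:6, ])) - sqrt(2 / pi)), 0.05)
  # zero noise std voxels flagged and zeroed
  dec3 <- dec
  dec3$noise_std[1] <- 0
  z3 <- zscore_components(dec3)
  expect_equal(z3[, 1], rep(0, 6))
  expect_equal(attr(z3, "n_zero_noise"), 1L)
})

test_that("task-component selection finds the planted component and splits", {
  # one task-locked source among noise components
  set.seed(21)
  p <- 150; V <- 4000
  task <- rep(c(1, 0), each = 15, length.out = p)
  tc <- scale(fmridual:::convolve_hrf(task, gamma_hrf(tr = 1.7)))
  spatial <- (runif(V) < 0.05) * 3
  X <- tc %*% t(spatial) * 4 + matrix(rnorm(p * V), p, V)
  dec <- fit_pica(X, q = 5, seed = 22)
  glm_map <- spatial + rnorm(V, sd = 0.3) # a noisy stand-in GLM map
  sel <- select_task_component(dec, glm_map, drop(tc))
  truthcorr <- abs(cor(t(dec$sources), spatial))
  expect_equal(sel$primary_index, which.max(truthcorr))
  expect_gt(sel$timecourse_task_corr[sel$primary_index], 0.9)
  # split activation across two disjoint sources sharing the time course
  spl_a <- c(rep(3, 300), rep(0, V - 300)) * (runif(V) < 1)
  spl_b <- c(rep(0, V - 300), rep(3, 300))
  tc2 <- scale(fmridual:::convolve_hrf(rep(c(1, 0), each = 20,
                                           length.out = p),
                                       gamma_hrf(tr = 1.7)))
  X2 <- 5 * tc %*% t(spl_a) + 5 * tc2 %*% t(spl_b) + matrix(rnorm(p * V), p, V)
  dec2 <- suppressWarnings(fit_pica(X2, q = 4, seed = 23,
                                    on_nonconvergence = "warn"))
  sel2 <- select_task_component(dec2, spl_a + spl_b, drop(tc),
                                split_fraction = 0.5)
  expect_gte(length(sel2$split_indices), 2)
  expect_true(sel2$primary_index %in% sel2$split_indices)
  # single component: trivially primary and sole split member
  dec1 <- fit_pica(X, q = 1, seed = 24)
  sel1 <- select_task_component(dec1, glm_map, drop(tc))
  expect_equal(sel1$primary_index, 1L)
  expect_equal(sel1$split_indices, 1L)
})

test_that("PCA-space reconstruction respects retained variance", {
  ph <- source_phantom(3, p = 100, V = 2000, snr = 6, seed = 31)
  dec <- fit_pica(ph$X, q = 3, seed = 32)
  Xn <- sweep(sweep(ph$X, 2, dec$mean), 2, dec$scale, "/")
  recon <- dec$mixing %*% dec$sources
  frac_unexplained <- sum((Xn - recon)^2) / sum(Xn^2)
  retained <- sum(dec$eigenvalues[1:3]) / sum(dec$eigenvalues)
  expect_lte(frac_unexplained, 1 - retained + 1e-6)
})
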