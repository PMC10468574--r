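test_that("OLS reproduces hand-computed fits and projection identities", {
  # intercept-only on a constant
  f1 <- ols_fit(matrix(4, 10, 1), matrix(1, 10, 1))
  expect_equal(drop(f1$beta), 4)
  expect_equal(max(abs(f1$residuals)), 0)
  # 3-point regression: beta = (1, 2) exactly
  X <- cbind(1, 0:2)
  f2 <- ols_fit(matrix(c(1, 3, 5), 3, 1), X)
  expect_equal(drop(f2$beta), c(1, 2))
  expect_equal(max(abs(f2$residuals)), 0)
  # residuals orthogonal to the design on random instances
  set.seed(1)
  for (i in 1:5) {
    Xr <- cbind(1, matrix(rnorm(40 * 3), 40, 3))
    Yr <- matrix(rnorm(40 * 7), 40, 7)
    fr <- ols_fit(Yr, Xr)
    expect_lt(max(abs(crossprod(Xr, fr$residuals))) / max(abs(Yr)), 1e-9)
  }
  # cross-check against the reference linear-model fitter
  set.seed(2)
  Xr <- cbind(1, rnorm(30), rnorm(30))
  y <- rnorm(30)
  expect_equal(drop(ols_fit(matrix(y), Xr)$beta),
               unname(coef(lm(y ~ Xr[, 2] + Xr[, 3]))), tolerance = 1e-10)
  expect_error(ols_fit(matrix(rnorm(8), 4, 2), cbind(1, 1:4, 2 * (1:4) + 1)),
               "singular|rank")
})

test_that("design matrix has the specified columns and degenerates loudly", {
  p <- study_paradigm()
  motion <- matrix(rnorm(170 * 6, sd = 0.05), 170, 6)
  d <- build_design_matrix(p, gamma_hrf(tr = p$tr), motion, cutoff_s = 50)
  expect_equal(dim(d$values), c(170L, 9L))
  expect_equal(d$column_labels,
               c("task", "task_derivative", paste0("motion", 1:6), "intercept"))
  expect_equal(d$task_column_index, 1L)
  # all non-intercept columns demeaned
  expect_lt(max(abs(colMeans(d$values[, 1:8]))), 1e-10)
  d2 <- build_design_matrix(p, gamma_hrf(tr = p$tr), NULL, cutoff_s = 50)
  expect_equal(ncol(d2$values), 3L)
  # duplicated nuisance columns collapse the design rank
  bad <- motion
  bad[, 2] <- bad[, 1]
  expect_error(build_design_matrix(p, gamma_hrf(tr = p$tr), bad, 50), "rank")
})

test_that("residual AR(1) estimation is calibrated and degenerate-safe", {
  white <- ar1_null(170, 1000, 0, seed = 4)
  expect_lt(abs(mean(estimate_autocorr(white))), 0.05)
  ar <- ar1_null(170, 1000, 0.4, seed = 5)
  expect_lt(abs(median(estimate_autocorr(ar)) - 0.4), 0.08)
  # constant (degenerate) residuals: clipped at the bound, no crash
  expect_equal(estimate_autocorr(matrix(1, 170, 3)), rep(0.95, 3))
  expect_error(estimate_autocorr(matrix(rnorm(14), 7, 2)), "at least 8")
})

test_that("whitening at rho 0 equals OLS and leaves exact fits alone", {
  set.seed(6)
  X <- cbind(1, rnorm(50), rnorm(50))
  Y <- matrix(rnorm(50 * 20), 50, 20)
  ols <- ols_fit(Y, X)
  gls <- prewhiten_and_fit(Y, X, rep(0, 20))
  expect_equal(gls$beta, ols$beta, tolerance = 1e-10)
  expect_equal(gls$residuals, ols$residuals, tolerance = 1e-10)
  # exact-fit data: beta invariant to rho
  Yfit <- X %*% matrix(rnorm(3 * 4), 3, 4)
  for (rho in c(-0.5, 0, 0.3, 0.8)) {
    g <- prewhiten_and_fit(Yfit, X, rep(rho, 4))
    expect_equal(g$beta, qr.coef(qr(X), Yfit), tolerance = 1e-8)
  }
  expect_error(prewhiten_and_fit(Y, X, rep(1, 20)), "rho")
})

test_that("pre-whitening removes residual autocorrelation", {
  nt <- 170
  X <- cbind(scale(fmridual:::convolve_hrf(rep(c(1, 0), each = 12,
                                               length.out = nt),
                                           gamma_hrf(tr = 1.7)),
                   scale = FALSE), 1)
  Y <- ar1_null(nt, 800, 0.4, seed = 7)
  ols <- ols_fit(Y, X)
  rho <- estimate_autocorr(ols$residuals)
  fit <- prewhiten_and_fit(Y, X, rho)
  lag1 <- function(E) {
    abs(colSums(E[-1, ] * E[-nrow(E), ]) / colSums(E^2))
  }
  expect_lt(median(lag1(fit$residuals_white)), 0.1)
  expect_gt(median(lag1(ols$residuals)), 0.25)
})

test_that("null z-maps are calibrated after whitening", {
  nt <- 170; nv <- 5000
  X <- cbind(scale(fmridual:::convolve_hrf(rep(c(1, 0), each = 14,
                                               length.out = nt),
                                           gamma_hrf(tr = 1.7)),
                   scale = FALSE), 1)
  Y <- ar1_null(nt, nv, 0.5, seed = 8)
  ols <- ols_fit(Y, X)
  # voxels laid on a grid so the AR coefficient map can be smoothed,
  # as the pipeline does
  mask <- array(TRUE, dim = c(25L, 20L, 10L))
  rho <- estimate_autocorr(ols$residuals, mask = mask, smooth_fwhm_mm = 12,
                           voxel_size = c(2, 2, 2))
  fit <- prewhiten_and_fit(Y, X, rho)
  z <- contrast_zmap(fit, c(1, 0))
  expect_lt(abs(sd(z) - 1), 0.05)
  # without whitening the same data give inflated z spread
  fit0 <- prewhiten_and_fit(Y, X, rep(0, nv))
  z0 <- contrast_zmap(fit0, c(1, 0))
  expect_gt(sd(z0), sd(z) + 0.05)
  # tail calibration at the study thresholds
  for (u in c(2.3, 3.1)) {
    phat <- mean(z > u)
    p0 <- pnorm(u, lower.tail = FALSE)
    expect_lt(abs(phat - p0), 3 * sqrt(p0 * (1 - p0) / nv))
  }
  # zero contrast -> all-zero map
  expect_equal(max(abs(contrast_zmap(fit, c(0, 0)))), 0)
})

test_that("noiseless planted data return the planted amplitude", {
  s <- small_scan(seed = 11, noise_sd_pct = 0, amplitude = 2,
                  drift_amplitudes_pct = c(0, 0), motion_sd_mm = 0)
  p <- s$paradigm
  run <- trim_volumes(s$sim$run, p$n_dummy, p$n_tail)
  mask <- s$sim$truth$region_masks[[1]]
  d <- build_design_matrix(p, gamma_hrf(tr = p$tr), NULL, cutoff_s = Inf)
  Y <- fmridual:::run_matrix(run, mask)
  fit <- ols_fit(Y, d)
  expect_equal(unname(fit$beta[1, ]), rep(20, ncol(Y)), tolerance = 1e-8)
})

test_that("per-voxel results are equivariant to voxel order", {
  set.seed(12)
  X <- cbind(1, rnorm(40))
  Y <- matrix(rnorm(40 * 30), 40, 30)
  rho <- runif(30, -0.3, 0.6)
  perm <- sample(30)
  f1 <- prewhiten_and_fit(Y, X, rho)
  f2 <- prewhiten_and_fit(Y[, perm], X, rho[perm])
  expect_equal(f2$beta, f1$beta[, perm])
  expect_equal(f2$sigma2, f1$sigma2[perm])
  z1 <- contrast_zmap(f1, c(0, 1))
  z2 <- contrast_zmap(f2, c(0, 1))
  expect_equal(as.numeric(z2), as.numeric(z1)[perm])
})
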