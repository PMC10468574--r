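#' Build the task design matrix
#'
#' Column 1 is the HRF-convolved task boxcar, high-pass filtered with the
#' same discrete-cosine operator as the data; column 2 its first temporal
#' difference (a nuisance column absorbing small HRF lag shifts); then the
#' six motion parameters (no motion derivatives), all demeaned; an explicit
#' intercept column comes last so the task coefficient stays
#' amplitude-interpretable.
#'
#' @param p paradigm from [make_block_paradigm()].
#' @param hrf HRF kernel from [gamma_hrf()].
#' @param motion optional matrix with 6 columns and one row per analysis
#'   volume.
#' @param cutoff_s high-pass cut-off applied to the task regressor (and its
#'   derivative); `Inf` disables filtering.
#' @return object of class `fmridual_design`: a list with `values`
#'   (t x r matrix), `column_labels`, `task_column_index`.
#' @export
build_design_matrix <- function(p, hrf = gamma_hrf(tr = p$tr), motion = NULL,
                                cutoff_s = 50) {
  nt <- p$n_analysis
  box <- sample_boxcar(p)
  x1 <- convolve_hrf(box, hrf)
  if (is.finite(cutoff_s)) x1 <- highpass_vector(x1, p$tr, cutoff_s)
  dx1 <- c(0, diff(x1))
  cols <- list(task = x1 - mean(x1), task_derivative = dx1 - mean(dx1))
  if (!is.null(motion)) {
    motion <- as.matrix(motion)
    if (nrow(motion) != nt || ncol(motion) != 6L) {
      stop_invalid("motion table must be ", nt, " x 6")
    }
    for (j in 1:6) cols[[paste0("motion", j)]] <- motion[, j] - mean(motion[, j])
  }
  cols$intercept <- rep(1, nt)
  X <- do.call(cbind, cols)
  if (qr(X)$rank < ncol(X)) {
    stop_invalid("design matrix is rank deficient")
  }
  structure(list(values = X, column_labels = names(cols),
                 task_column_index = 1L),
            class = "fmridual_design")
}

design_values <- function(X) {
  if (inherits(X, "fmridual_design")) X$values else as.matrix(X)
}

#' Ordinary least squares fit
#'
#' Per-voxel OLS of `Y = X beta + e` solved by QR; residuals are the
#' projection of `Y` off the column space of `X`.
#'
#' @param Y t x V response matrix (one column per voxel).
#' @param X design matrix or [build_design_matrix()] result.
#' @return list with `beta` (r x V) and `residuals` (t x V).
#' @export
ols_fit <- function(Y, X) {
  Xm <- design_values(X)
  Y <- as.matrix(Y)
  if (nrow(Y) != nrow(Xm)) stop_invalid("Y and X row counts differ")
  if (nrow(Xm) <= ncol(Xm)) stop_invalid("need more time points than regressors")
  qrx <- qr(Xm)
  if (qrx$rank < ncol(Xm)) stop_invalid("design matrix is singular")
  beta <- qr.coef(qrx, Y)
  list(beta = beta, residuals = Y - Xm %*% beta)
}

#' Voxel-wise AR(1) coefficient of residuals
#'
#' Lag-1 autocorrelation per voxel with the standard small-sample bias
#' correction `(1 + 3 rho) / n`, clipped to (-0.95, 0.95). Degenerate
#' (zero-variance) voxels get 0. Optionally the coefficient volume is
#' spatially smoothed (before the correction) to stabilise the estimate, as
#' is standard before pre-whitening.
#'
#' @param residuals t x V residual matrix.
#' @param mask optional 3D logical array locating the V voxels, required for
#'   spatial smoothing.
#' @param smooth_fwhm_mm FWHM for smoothing the coefficient map (0 = none).
#' @param voxel_size mm per axis, used with `smooth_fwhm_mm`.
#' @return numeric vector of length V in (-0.95, 0.95).
#' @export
estimate_autocorr <- function(residuals, mask = NULL, smooth_fwhm_mm = 0,
                              voxel_size = c(2, 2, 2)) {
  E <- as.matrix(residuals)
  nt <- nrow(E)
  if (nt < 8) stop_invalid("need at least 8 time points")
  num <- colSums(E[-1, , drop = FALSE] * E[-nt, , drop = FALSE])
  den <- colSums(E^2)
  rho <- ifelse(den > 0, num / den, 0)
  rho[!is.finite(rho)] <- 0
  if (smooth_fwhm_mm > 0 && !is.null(mask)) {
    vol <- vector_to_volume(rho, mask)
    arr <- array(vol, dim = c(dim(mask), 1L))
    sm <- smooth_gaussian(bold_run(arr, tr = 1, voxel_size = voxel_size),
                          smooth_fwhm_mm)
    wts <- smooth_gaussian(bold_run(array(as.numeric(mask),
                                          dim = c(dim(mask), 1L)),
                                    tr = 1, voxel_size = voxel_size),
                           smooth_fwhm_mm)
    sv <- sm$data[, , , 1][mask]
    wv <- wts$data[, , , 1][mask]
    rho <- ifelse(wv > 0, sv / wv, rho)
  }
  rho <- rho + (1 + 3 * rho) / nt
  pmin(pmax(rho, -0.95), 0.95)
}

# AR(1) whitening transform applied to a matrix of series (first row scaled
# by sqrt(1 - rho^2), then x_i - rho x_{i-1}).
ar1_whiten <- function(M, rho) {
  M <- as.matrix(M)
  nt <- nrow(M)
  rbind(sqrt(1 - rho^2) * M[1, , drop = FALSE],
        M[-1, , drop = FALSE] - rho * M[-nt, , drop = FALSE])
}

#' Pre-whitened (generalised least squares) fit
#'
#' Whitens data and design per voxel with the AR(1) transform implied by the
#' voxel's autocorrelation coefficient, then refits by least squares on the
#' whitened pair; the error variance is estimated per voxel ("different
#' sigma^2 for each voxel"). Voxels are grouped by their coefficient rounded
#' to 0.01 so each group's whitened design and Gram inverse are computed
#' once; at `rho = 0` the transform is the identity and the result equals
#' OLS exactly.
#'
#' @param Y t x V data matrix.
#' @param X design matrix or [build_design_matrix()] result.
#' @param ar_coeff length-V AR(1) coefficients in (-1, 1).
#' @return object of class `fmridual_glmfit`: `beta` (r x V), `sigma2`,
#'   `ar_coeff`, `dof` (= t - r, uncorrected for AR estimation),
#'   `residuals` (unwhitened), `residuals_white`, and the per-group Gram
#'   inverses needed for contrast variance.
#' @export
prewhiten_and_fit <- function(Y, X, ar_coeff) {
  Xm <- design_values(X)
  Y <- as.matrix(Y)
  nt <- nrow(Y); nr <- ncol(Xm); nv <- ncol(Y)
  if (length(ar_coeff) == 1L) ar_coeff <- rep(ar_coeff, nv)
  if (any(abs(ar_coeff) >= 1)) stop_invalid("|rho| must be < 1")
  rho_bin <- round(ar_coeff, 2)
  bins <- sort(unique(rho_bin))
  beta <- matrix(NA_real_, nr, nv)
  sigma2 <- numeric(nv)
  resid_w <- matrix(NA_real_, nt, nv)
  gram_inv <- vector("list", length(bins))
  voxel_bin <- match(rho_bin, bins)
  for (b in seq_along(bins)) {
    rho <- bins[b]
    idx <- which(voxel_bin == b)
    Xw <- ar1_whiten(Xm, rho)
    G <- solve(crossprod(Xw))
    gram_inv[[b]] <- G
    Yw <- ar1_whiten(Y[, idx, drop = FALSE], rho)
    bet <- G %*% crossprod(Xw, Yw)
    rw <- Yw - Xw %*% bet
    beta[, idx] <- bet
    sigma2[idx] <- colSums(rw^2) / (nt - nr)
    resid_w[, idx] <- rw
  }
  structure(list(beta = beta, sigma2 = sigma2, ar_coeff = ar_coeff,
                 rho_bins = bins, voxel_bin = voxel_bin,
                 gram_inv = gram_inv, dof = nt - nr,
                 residuals = Y - Xm %*% beta, residuals_white = resid_w,
                 design = Xm),
            class = "fmridual_glmfit")
}

#' Contrast z-statistic map
#'
#' Per voxel `t = c' beta / sqrt(sigma2 * c' (Xw' Xw)^-1 c)` with the
#' whitened design, converted to a z-score by matching the upper-tail
#' probability of the t distribution at the fit's degrees of freedom.
#' Zero-variance voxels get z = 0 and are counted in the
#' `n_zero_variance` attribute.
#'
#' @param fit a [prewhiten_and_fit()] result.
#' @param contrast numeric contrast vector, length = number of regressors.
#' @param mask optional 3D logical array; when supplied the result is a 3D
#'   volume (0 outside the mask), otherwise a per-voxel vector.
#' @return z values as vector or 3D volume.
#' @export
contrast_zmap <- function(fit, contrast, mask = NULL) {
  nr <- nrow(fit$beta)
  if (length(contrast) != nr) stop_invalid("contrast length must be ", nr)
  eff <- drop(crossprod(contrast, fit$beta))
  cvc <- vapply(fit$gram_inv, function(G) drop(crossprod(contrast, G %*% contrast)),
                numeric(1))
  se2 <- fit$sigma2 * cvc[fit$voxel_bin]
  tstat <- numeric(length(eff))
  ok <- se2 > 0
  tstat[ok] <- eff[ok] / sqrt(se2[ok])
  z <- t_to_z(tstat, fit$dof)
  z[!ok] <- 0
  attr(z, "n_zero_variance") <- sum(!ok)
  if (!is.null(mask)) {
    zv <- vector_to_volume(z, mask)
    attr(zv, "n_zero_variance") <- sum(!ok)
    return(zv)
  }
  z
}

# t -> z by upper-tail probability matching, computed on the log scale so
# extreme statistics do not saturate.
t_to_z <- function(tstat, dof) {
  s <- sign(tstat)
  lp <- stats::pt(abs(tstat), df = dof, lower.tail = FALSE, log.p = TRUE)
  s * stats::qnorm(lp, lower.tail = FALSE, log.p = TRUE)
}

#' Full GLM stage on a pre-processed run
#'
#' OLS, residual AR(1) estimation (optionally spatially smoothed), a single
#' pre-whitened refit, and the task-contrast z-map.
#'
#' @param run pre-processed [bold_run].
#' @param mask 3D logical analysis mask.
#' @param design design from [build_design_matrix()].
#' @param ar_smooth_fwhm_mm FWHM for smoothing the AR coefficient map.
#' @return list with `fit` (the `fmridual_glmfit`), `zmap` (3D volume) and
#'   `contrast`.
#' @export
fit_glm <- function(run, mask, design, ar_smooth_fwhm_mm = 8) {
  Y <- run_matrix(run, mask)
  ols <- ols_fit(Y, design)
  rho <- estimate_autocorr(ols$residuals, mask = mask,
                           smooth_fwhm_mm = ar_smooth_fwhm_mm,
                           voxel_size = run$voxel_size)
  fit <- prewhiten_and_fit(Y, design, rho)
  contrast <- numeric(ncol(design$values))
  contrast[design$task_column_index] <- 1
  zmap <- contrast_zmap(fit, contrast, mask = mask)
  list(fit = fit, zmap = zmap, contrast = contrast)
}
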