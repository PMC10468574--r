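# Expected value of log cosh(u) for u ~ N(0,1); reference point of the
# negentropy contrast (computed once by numerical integration).
LOGCOSH_GAUSS <- 0.3745672

#' Voxel-wise variance normalisation
#'
#' Removes each voxel's temporal mean and divides the series by an estimate
#' of its noise standard deviation: the residual std after projecting out the
#' top `k_noise` principal components (which carry the structured signal).
#' The recorded mean and scale allow an exact undo. Constant voxels are
#' flagged and given unit scale.
#'
#' @param data t x V matrix (time by voxel).
#' @param k_noise principal components regarded as signal when estimating
#'   the noise std.
#' @return list with `data` (normalised), `scale`, `mean`, `excluded`
#'   (logical, constant voxels).
#' @export
variance_normalize <- function(data, k_noise = 20) {
  X <- as.matrix(data)
  p <- nrow(X)
  mu <- colMeans(X)
  Xc <- sweep(X, 2, mu)
  excluded <- colSums(Xc^2) == 0
  k <- min(k_noise, p - 1L)
  if (k > 0) {
    C <- tcrossprod(Xc) / ncol(Xc)
    eg <- eigen(C, symmetric = TRUE)
    U <- eg$vectors[, seq_len(k), drop = FALSE]
    R <- Xc - U %*% crossprod(U, Xc)
  } else {
    R <- Xc
  }
  scl <- sqrt(colSums(R^2) / (p - k))
  scl[excluded | scl == 0] <- 1
  list(data = sweep(Xc, 2, scl, "/"), scale = scl, mean = mu,
       excluded = excluded)
}

#' Model order by Laplace-approximated Bayesian evidence
#'
#' Selects the number of retained components `q` for a probabilistic-PCA
#' model of the data covariance by maximising the Laplace approximation to
#' the model evidence over candidate orders (Minka's approximation), keeping
#' `q` strictly below the number of time points.
#'
#' Eigenvalues that are numerically zero relative to the largest (the null
#' space created by temporal filtering and demeaning) are excluded before
#' model comparison, and `n_samples` should be the number of spatially
#' independent samples: for smoothed data pass the voxel count divided by
#' the volume of the smoothness kernel in voxels, not the raw voxel count.
#'
#' @param eigenvalues descending positive eigenvalues of the time-by-time
#'   data covariance.
#' @param n_samples number of (effectively independent) samples the
#'   covariance was estimated from (here: voxels).
#' @param max_order optional cap on the candidate orders.
#' @param rank_tol relative tolerance below which trailing eigenvalues are
#'   treated as exact zeros.
#' @return the selected order `q`.
#' @export
estimate_order_laplace <- function(eigenvalues, n_samples, max_order = NULL,
                                   rank_tol = 1e-9) {
  l <- as.numeric(eigenvalues)
  if (length(l) < 3) stop_invalid("need at least 3 eigenvalues")
  if (is.unsorted(rev(l))) stop_invalid("eigenvalues must be descending")
  l <- l[l > max(l) * rank_tol]
  p <- length(l)
  if (p < 3) stop_invalid("fewer than 3 nonzero eigenvalues")
  if (n_samples <= p) stop_invalid("n_samples must exceed the eigenvalue count")
  n <- n_samples
  kmax <- p - 1L
  if (!is.null(max_order)) kmax <- min(kmax, max_order)
  ev <- rep(-Inf, kmax)
  # terms reused across k
  lg <- cumsum(lgamma((p - seq_len(kmax) + 1) / 2) -
                 (p - seq_len(kmax) + 1) / 2 * log(pi))
  cum_log_l <- cumsum(log(l))
  cum_l <- cumsum(l)
  tot_l <- sum(l)
  for (k in seq_len(kmax)) {
    v <- (tot_l - cum_l[k]) / (p - k)
    if (v <= 0) break
    m <- p * k - k * (k + 1) / 2
    lp_u <- -k * log(2) + lg[k]
    ll <- -n / 2 * cum_log_l[k] - n * (p - k) / 2 * log(v)
    # log |A_Z|: curvature of the evidence around the MAP basis
    lh <- c(l[seq_len(k)], rep(v, p - k))
    log_az <- 0
    for (i in seq_len(k)) {
      j <- (i + 1):p
      terms <- (1 / lh[j] - 1 / lh[i]) * (l[i] - l[j]) * n
      terms[terms <= 0] <- .Machine$double.eps
      log_az <- log_az + sum(log(terms))
    }
    ev[k] <- lp_u + ll + (m + k) / 2 * log(2 * pi) - log_az / 2 - k / 2 * log(n)
  }
  which.max(ev)
}

# Symmetric fixed-point ICA on whitened data Z (q x V): maximises the
# log-cosh negentropy proxy of the rows of W Z under W orthonormal.
fastica_symmetric <- function(Z, max_iter = 200, tol = 1e-6, seed = 1L,
                              n_restarts = 3) {
  q <- nrow(Z); nv <- ncol(Z)
  best <- NULL
  for (r in seq_len(n_restarts)) {
    W <- with_seed(derive_seed(seed, paste0("ica_init", r)), {
      M <- matrix(stats::rnorm(q * q), q, q)
      qr.Q(qr(M))
    })
    converged <- FALSE
    iters <- 0L
    for (it in seq_len(max_iter)) {
      iters <- it
      S <- W %*% Z
      G <- tanh(S)
      gprime <- rowMeans(1 - G^2)
      W_new <- G %*% t(Z) / nv - gprime * W
      # symmetric decorrelation: W <- (W W')^{-1/2} W
      sw <- W_new %*% t(W_new)
      e <- eigen(sw, symmetric = TRUE)
      W_new <- e$vectors %*% diag(1 / sqrt(pmax(e$values, 1e-12)), q) %*%
        t(e$vectors) %*% W_new
      delta <- max(abs(abs(diag(W_new %*% t(W))) - 1))
      W <- W_new
      if (delta < tol) { converged <- TRUE; break }
    }
    S <- W %*% Z
    contrast <- sum((rowMeans(log(cosh(S))) - LOGCOSH_GAUSS)^2)
    cand <- list(W = W, converged = converged, iterations = iters,
                 contrast = contrast)
    if (is.null(best) || contrast > best$contrast) best <- cand
  }
  best
}

#' Probabilistic spatial ICA decomposition
#'
#' Variance-normalises the data, reduces to `q` principal components
#' (automatic `q` by [estimate_order_laplace()]), and unmixes by a
#' symmetric fixed-point iteration maximising the log-cosh negentropy proxy
#' of the spatial maps, with random restarts keeping the run with the best
#' contrast value. The noise term is the part of the data outside the
#' retained subspace; its voxel-wise std normalises the component maps into
#' z-scores. Components are sorted by explained variance and sign-flipped to
#' positive skewness.
#'
#' @param run pre-processed [bold_run] or a t x V matrix.
#' @param mask 3D logical analysis mask (ignored when `run` is a matrix).
#' @param q number of components, or `"auto"`.
#' @param seed integer seed for initialisation.
#' @param k_noise see [variance_normalize()].
#' @param max_order cap on the automatic order.
#' @param n_effective effectively independent spatial samples used by the
#'   automatic order selection; defaults to the voxel count (appropriate for
#'   spatially white noise). For smoothed data pass
#'   `V / prod(fwhm_vox)`.
#' @param normalize apply [variance_normalize()] first (default). Disable
#'   for data that are already on a common noise scale.
#' @param n_restarts random restarts of the unmixing.
#' @param max_iter fixed-point iteration cap.
#' @param on_nonconvergence `"error"` or `"warn"`.
#' @return object of class `fmridual_pica`: `mixing` (p x q time courses),
#'   `sources` (q x V unit-variance spatial maps), `order`, `noise_std`
#'   (original units), `noise_std_norm`, `scale`, `explained_variance`,
#'   `converged`, `iterations`, `eigenvalues`, `mask`.
#' @export
fit_pica <- function(run, mask = NULL, q = "auto", seed = 1L, k_noise = 20,
                     max_order = NULL, n_restarts = 3, max_iter = 200,
                     n_effective = NULL, normalize = TRUE,
                     on_nonconvergence = c("error", "warn")) {
  on_nonconvergence <- match.arg(on_nonconvergence)
  X <- if (inherits(run, "bold_run")) run_matrix(run, mask) else as.matrix(run)
  p <- nrow(X); nv <- ncol(X)
  vn <- if (normalize) {
    variance_normalize(X, k_noise = k_noise)
  } else {
    mu <- colMeans(X)
    list(data = sweep(X, 2, mu), scale = rep(1, nv), mean = mu,
         excluded = logical(nv))
  }
  Xn <- vn$data
  C <- tcrossprod(Xn) / nv
  eg <- eigen(C, symmetric = TRUE)
  evals <- pmax(eg$values, .Machine$double.eps)
  if (identical(q, "auto")) {
    q <- estimate_order_laplace(evals, n_effective %||% nv,
                                max_order = max_order)
  }
  q <- as.integer(q)
  if (q >= p) stop_invalid("q must be smaller than the number of time points")
  if (nv <= q) stop_invalid("need more voxels than components")
  if (p < 2 * q) stop_invalid("need at least 2*q time points")
  E <- eg$vectors[, seq_len(q), drop = FALSE]
  D <- evals[seq_len(q)]
  Z <- (t(E) %*% Xn) / sqrt(D)      # q x V, rows approx unit variance
  ica <- fastica_symmetric(Z, max_iter = max_iter, seed = seed,
                           n_restarts = n_restarts)
  if (!ica$converged) {
    msg <- sprintf("ICA fixed point did not converge in %d iterations (contrast %.3g)",
                   ica$iterations, ica$contrast)
    if (on_nonconvergence == "error") {
      cond <- structure(class = c("fmridual_nonconvergence", "error", "condition"),
                        list(message = msg, call = sys.call(),
                             iterations = ica$iterations,
                             contrast = ica$contrast))
      stop(cond)
    }
    warning(msg, call. = FALSE)
  }
  S <- ica$W %*% Z                   # q x V spatial maps
  # all-Gaussian sources are unidentifiable: flag when no component departs
  # measurably from the Gaussian log-cosh reference
  dev <- abs(rowMeans(log(cosh(S))) - LOGCOSH_GAUSS)
  if (max(dev) < 1.5 / sqrt(nv)) {
    warning("components are indistinguishable from Gaussian noise; ",
            "the decomposition is not identifiable", call. = FALSE)
  }
  A <- E %*% (sqrt(D) * t(ica$W))    # p x q time courses; Xn ~ A S
  eta <- Xn - E %*% crossprod(E, Xn) # residual outside the retained subspace
  noise_std_norm <- sqrt(colSums(eta^2) / (p - q))
  noise_std <- noise_std_norm * vn$scale
  expvar <- colSums(A^2) * rowSums(S^2)
  expvar <- expvar / sum(Xn^2)
  ord <- order(expvar, decreasing = TRUE)
  S <- S[ord, , drop = FALSE]
  A <- A[, ord, drop = FALSE]
  W_unmix <- ica$W[ord, , drop = FALSE]
  expvar <- expvar[ord]
  # sign convention: positive skewness of each spatial map
  sk <- rowMeans(sweep(S, 1, rowMeans(S))^3)
  flip <- ifelse(sk < 0, -1, 1)
  S <- S * flip
  A <- sweep(A, 2, flip, "*")
  W_unmix <- W_unmix * flip
  structure(list(mixing = A, sources = S, order = q, unmixing = W_unmix,
                 noise_std = noise_std, noise_std_norm = noise_std_norm,
                 scale = vn$scale, mean = vn$mean,
                 explained_variance = expvar,
                 converged = ica$converged, iterations = ica$iterations,
                 contrast = ica$contrast,
                 eigenvalues = evals, mask = mask),
            class = "fmridual_pica")
}

#' Noise-normalised component z-maps
#'
#' Each raw component map, restored to original intensity units, is divided
#' by the voxel-wise standard deviation of the estimated noise term.
#' Voxels with zero noise std get z = 0 and are counted in the
#' `n_zero_noise` attribute.
#'
#' @param dec a [fit_pica()] decomposition.
#' @return q x V matrix of z values (attribute `n_zero_noise`), or, when the
#'   decomposition carries a mask, a list of 3D volumes.
#' @export
zscore_components <- function(dec) {
  ok <- dec$noise_std > 0
  Z <- sweep(sweep(dec$sources, 2, dec$scale, "*"), 2,
             ifelse(ok, dec$noise_std, 1), "/")
  Z[, !ok] <- 0
  attr(Z, "n_zero_noise") <- sum(!ok)
  if (!is.null(dec$mask)) {
    vols <- lapply(seq_len(nrow(Z)), function(c) vector_to_volume(Z[c, ], dec$mask))
    attr(vols, "n_zero_noise") <- sum(!ok)
    return(vols)
  }
  Z
}

#' Select the task (language) component
#'
#' Scores every component by a weighted combination of the spatial
#' similarity of its absolute z-map to the GLM map and the absolute
#' correlation of its time course with the task regressor; the highest score
#' wins (ties to the lower index). Components scoring at least
#' `split_fraction` of the maximum whose suprathreshold maps are pairwise
#' spatially disjoint (Dice < `split_dice_max`) are returned as a split set,
#' covering runs where the activation is divided across components.
#'
#' @param dec a [fit_pica()] decomposition.
#' @param glm_zmap GLM z values over the same voxels (vector or 3D volume).
#' @param task_regressor task time course, length = time points.
#' @param w_spatial,w_temporal score weights.
#' @param split_fraction score fraction for split candidates.
#' @param split_z voxel z used for the disjointness check.
#' @param split_dice_max Dice upper bound for "disjoint".
#' @return list with `primary_index`, `split_indices`, `similarity_scores`,
#'   `timecourse_task_corr`, `spatial_corr`.
#' @export
select_task_component <- function(dec, glm_zmap, task_regressor,
                                  w_spatial = 0.6, w_temporal = 0.4,
                                  split_fraction = 0.75, split_z = 2.3,
                                  split_dice_max = 0.2) {
  Z <- zscore_components(dec)
  if (is.list(Z)) Z <- do.call(rbind, lapply(Z, function(v) v[dec$mask]))
  g <- if (is.array(glm_zmap) && length(dim(glm_zmap)) == 3) {
    glm_zmap[dec$mask]
  } else as.numeric(glm_zmap)
  q <- nrow(Z)
  safe_cor <- function(a, b) {
    if (stats::sd(a) == 0 || stats::sd(b) == 0) return(NA_real_)
    stats::cor(a, b)
  }
  sp <- vapply(seq_len(q), function(c) safe_cor(abs(Z[c, ]), abs(g)), numeric(1))
  tc <- vapply(seq_len(q), function(c)
    abs(safe_cor(dec$mixing[, c], task_regressor)), numeric(1))
  score <- w_spatial * sp + w_temporal * tc
  if (all(!is.finite(score))) stop_invalid("component selection failed: no finite scores")
  score_rank <- ifelse(is.finite(score), score, -Inf)
  primary <- which.max(score_rank)   # which.max breaks ties toward lower index
  cand <- which(score_rank >= split_fraction * score_rank[primary])
  cand <- cand[order(-score_rank[cand], cand)]
  supra <- lapply(seq_len(q), function(c) Z[c, ] >= split_z)
  split <- primary
  for (c in setdiff(cand, primary)) {
    disjoint <- all(vapply(split, function(s)
      dice(supra[[c]], supra[[s]]) < split_dice_max, logical(1)))
    if (disjoint) split <- c(split, c)
  }
  list(primary_index = primary, split_indices = sort(split),
       similarity_scores = score, timecourse_task_corr = tc,
       spatial_corr = sp)
}
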