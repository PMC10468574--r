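#' Label connected suprathreshold clusters
#'
#' Connected-component labelling of a 3D logical array under 26-connectivity
#' (faces, edges and corners), the common neuroimaging default.
#'
#' @param supra 3D logical array.
#' @return list with `labels` (integer 3D array, 0 = background) and `sizes`
#'   (voxel count per cluster, descending label order preserved).
#' @export
label_clusters <- function(supra) {
  d <- dim(supra)
  idx <- which(supra)
  labels <- array(0L, dim = d)
  if (length(idx) == 0) return(list(labels = labels, sizes = integer(0)))
  co <- arrayInd(idx, d)
  pos <- integer(prod(d))
  pos[idx] <- seq_along(idx)
  offsets <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  offsets <- offsets[rowSums(abs(offsets)) > 0, ]
  # keep only the 13 lexicographically-positive offsets; each pair appears once
  offsets <- offsets[offsets$dz > 0 |
                       (offsets$dz == 0 & offsets$dy > 0) |
                       (offsets$dz == 0 & offsets$dy == 0 & offsets$dx > 0), ]
  edges <- list()
  for (k in seq_len(nrow(offsets))) {
    nx <- co[, 1] + offsets$dx[k]
    ny <- co[, 2] + offsets$dy[k]
    nz <- co[, 3] + offsets$dz[k]
    ok <- nx >= 1 & nx <= d[1] & ny >= 1 & ny <= d[2] & nz >= 1 & nz <= d[3]
    if (!any(ok)) next
    nbr <- pos[(nz[ok] - 1L) * d[1] * d[2] + (ny[ok] - 1L) * d[1] + nx[ok]]
    hit <- nbr > 0L
    if (any(hit)) {
      edges[[length(edges) + 1L]] <- cbind(which(ok)[hit], nbr[hit])
    }
  }
  g <- igraph::make_empty_graph(n = length(idx), directed = FALSE)
  if (length(edges)) {
    g <- igraph::add_edges(g, t(do.call(rbind, edges)))
  }
  memb <- igraph::components(g)$membership
  labels[idx] <- memb
  list(labels = labels, sizes = as.integer(tabulate(memb)))
}

#' Spatial smoothness (FWHM) of a statistic field
#'
#' Estimates the per-axis FWHM of the effective spatial correlation kernel
#' from the variance of spatial finite differences of the standardised
#' field: for a unit-variance Gaussian-autocorrelated field,
#' `FWHM = sqrt(4 ln 2 / var(d))` voxels, with `d` the neighbour
#' difference. With a t x V residual matrix each voxel series is
#' standardised by its temporal std and the difference variance pooled over
#' volumes; with a single 3D volume the field is standardised globally
#' within the mask.
#'
#' @param x t x V residual matrix (with `mask` locating the voxels) or a 3D
#'   statistic volume.
#' @param voxel_size mm per axis.
#' @param mask 3D logical array.
#' @return per-axis FWHM in mm (length 3).
#' @export
estimate_smoothness <- function(x, voxel_size = c(2, 2, 2), mask) {
  d <- dim(mask)
  if (is.matrix(x)) {
    sds <- sqrt(colMeans(sweep(x, 2, colMeans(x))^2))
    sds[sds == 0] <- Inf
    Xs <- sweep(x, 2, sds, "/")
    nvol <- nrow(Xs)
    get_vol <- function(i) vector_to_volume(Xs[i, ], mask)
  } else {
    v <- x[mask]
    s <- stats::sd(v)
    if (s == 0) stop_invalid("flat field: smoothness undefined")
    nvol <- 1L
    get_vol <- function(i) vector_to_volume((x[mask] - mean(v)) / s, mask)
  }
  num <- den <- numeric(3)
  for (i in seq_len(nvol)) {
    vol <- get_vol(i)
    for (ax in 1:3) {
      m1 <- slice_shift(mask, ax)
      both <- m1$a & m1$b
      if (!any(both)) next
      dv <- (slice_shift(vol, ax)$a - slice_shift(vol, ax)$b)[both]
      num[ax] <- num[ax] + sum(dv^2)
      den[ax] <- den[ax] + length(dv)
    }
  }
  var_d <- num / pmax(den, 1)
  if (any(var_d == 0)) stop_invalid("flat field: smoothness undefined")
  fwhm_vox <- sqrt(4 * log(2) / var_d)
  fwhm_vox * voxel_size
}

# pair of arrays offset by one voxel along an axis (a: tail, b: head)
slice_shift <- function(arr, ax) {
  d <- dim(arr)
  ia <- ib <- lapply(d, seq_len)
  ia[[ax]] <- 2:d[ax]
  ib[[ax]] <- 1:(d[ax] - 1)
  list(a = arr[ia[[1]], ia[[2]], ia[[3]], drop = FALSE],
       b = arr[ib[[1]], ib[[2]], ib[[3]], drop = FALSE])
}

# one smoothness-matched standardized Gaussian null field on the grid
simulate_null_field <- function(dims, fwhm_mm, voxel_size, mask) {
  arr <- array(stats::rnorm(prod(dims)), dim = dims)
  sigma_mm <- fwhm_mm / (2 * sqrt(2 * log(2)))
  for (ax in 1:3) {
    K <- gaussian_kernel_matrix(dims[ax], sigma_mm[min(ax, length(sigma_mm))] /
                                  voxel_size[ax])
    arr <- apply_axis_3d(arr, K, ax)
  }
  v <- arr[mask]
  arr[mask] <- (v - mean(v)) / stats::sd(v)
  arr
}

apply_axis_3d <- function(arr, K, axis) {
  d <- dim(arr)
  perm <- c(axis, setdiff(1:3, axis))
  m <- matrix(aperm(arr, perm), nrow = d[axis])
  aperm(array(K %*% m, dim = d[perm]), order(perm))
}

#' Monte-Carlo cluster extent threshold
#'
#' Simulates Gaussian null fields matched to the estimated smoothness on the
#' analysis mask, thresholds each at the voxel-wise z values of the grid and
#' records the maximum surviving cluster extent. The extent threshold
#' `k*` for cluster-wise `p < cluster_p` is the `1 - cluster_p` quantile of
#' that maximum-extent null plus one voxel.
#'
#' @param fwhm_mm per-axis smoothness in mm (scalar recycled).
#' @param mask 3D logical analysis mask.
#' @param voxel_size mm per axis.
#' @param z_grid voxel-wise z thresholds.
#' @param cluster_p cluster-wise significance level.
#' @param n_sim number of simulated fields (>= 100).
#' @param seed integer seed; results are deterministic given it.
#' @return list with `k_star` (named by z), `max_extents` (n_sim x length(z)
#'   matrix), `fwhm_mm`, `n_sim`, `seed`.
#' @export
cluster_null <- function(fwhm_mm, mask, voxel_size = c(2, 2, 2),
                         z_grid = c(2.3, 2.6, 2.9, 3.1), cluster_p = 0.05,
                         n_sim = 200, seed = 1L) {
  if (n_sim < 100) stop_invalid("n_sim must be >= 100")
  dims <- dim(mask)
  fwhm_mm <- rep_len(fwhm_mm, 3)
  maxext <- with_seed(derive_seed(seed, "cluster_null"), {
    m <- vapply(seq_len(n_sim), function(i) {
      fld <- simulate_null_field(dims, fwhm_mm, voxel_size, mask)
      vapply(z_grid, function(z) {
        lab <- label_clusters(fld >= z & mask)
        if (length(lab$sizes)) max(lab$sizes) else 0L
      }, integer(1))
    }, integer(length(z_grid)))
    t(matrix(m, nrow = length(z_grid)))
  })
  k_star <- apply(maxext, 2, function(m)
    as.integer(stats::quantile(m, 1 - cluster_p, type = 1)) + 1L)
  names(k_star) <- as.character(z_grid)
  list(k_star = k_star, max_extents = maxext, fwhm_mm = fwhm_mm,
       n_sim = n_sim, seed = seed, z_grid = z_grid, cluster_p = cluster_p)
}

#' Dual voxel/cluster thresholding
#'
#' For each voxel-wise z in the grid, binarises the (positive-tail) map and
#' removes clusters smaller than the Monte-Carlo extent threshold, yielding
#' one candidate map per grid value (four under the default grid).
#'
#' @param zmap 3D z-statistic volume.
#' @param mask 3D logical analysis mask.
#' @param null a [cluster_null()] result (provides `k_star` per z).
#' @param z_grid voxel-wise thresholds; defaults to the null's grid.
#' @param two_sided threshold `|z|` instead of the positive tail.
#' @return object of class `fmridual_mapset`: list of entries with
#'   `voxel_z`, `cluster_p`, `k_star`, `binary` (3D logical),
#'   `cluster_sizes` (surviving).
#' @export
threshold_map <- function(zmap, mask, null, z_grid = NULL, two_sided = FALSE) {
  if (!any(mask)) stop_invalid("empty mask")
  z_grid <- z_grid %||% null$z_grid
  if (!length(z_grid)) stop_invalid("z grid is empty")
  entries <- lapply(z_grid, function(z) {
    ks <- null$k_star[[as.character(z)]]
    if (is.null(ks)) stop_invalid("no extent threshold for z = ", z)
    supra <- if (two_sided) abs(zmap) >= z & mask else zmap >= z & mask
    lab <- label_clusters(supra)
    keep <- which(lab$sizes >= ks)
    binary <- array(lab$labels %in% keep, dim = dim(mask))
    list(voxel_z = z, cluster_p = null$cluster_p, k_star = ks,
         binary = binary,
         cluster_sizes = sort(lab$sizes[keep], decreasing = TRUE))
  })
  structure(list(maps = entries, z_grid = z_grid,
                 smoothness_fwhm_mm = null$fwhm_mm),
            class = "fmridual_mapset")
}
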