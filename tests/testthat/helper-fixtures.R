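# Shared fixtures: small, fast phantoms built in code.

# the study-shaped paradigm (6 x 24 s / 24 s, TR 1.7, 3 dummy + 4 tail)
study_paradigm <- function() make_block_paradigm(6, 24, 24, 1.7, 3, 4)

# a reduced paradigm for cheap end-to-end tests
small_paradigm <- function() make_block_paradigm(3, 20, 20, 2, 2, 2)

# clean phantom scan on a reduced grid
small_scan <- function(seed = 1, grid = c(20L, 20L, 16L), amplitude = 1.5,
                       noise_sd_pct = 1, noise_ar = 0.3, ...) {
  p <- small_paradigm()
  truth <- make_ground_truth(p$n_volumes, grid_dim = grid,
                             region_amplitudes = rep(amplitude, 6),
                             noise_sd_pct = noise_sd_pct, noise_ar = noise_ar,
                             tr = p$tr, seed = seed, ...)
  list(paradigm = p, sim = simulate_scan(p, truth))
}

# planted-source matrix phantom for ICA tests: X = snr * A S + noise,
# snr the amplitude (std) ratio of each source to the unit noise
source_phantom <- function(k, p = 170, V = 5000, snr = 5, seed = 1) {
  set.seed(seed)
  A <- qr.Q(qr(matrix(stats::rnorm(p * k), p, k)))
  S <- matrix(stats::rexp(k * V) - 1, k, V)
  list(X = snr * A %*% S + matrix(stats::rnorm(p * V), p, V), A = A, S = S)
}

# AR(1) null data matrix (t x V), unit marginal sd
ar1_null <- function(nt, nv, rho, seed = 1) {
  set.seed(seed)
  e <- matrix(stats::rnorm((nt + 25) * nv), nt + 25, nv)
  if (rho != 0) {
    e <- stats::filter(e, rho, method = "recursive") * sqrt(1 - rho^2)
  }
  matrix(e[(25 + 1):(25 + nt), ], nt, nv)
}
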