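#' Block-design paradigm
#'
#' Describes an alternating task/control block paradigm sampled at a fixed
#' repetition time (TR), together with the number of dummy volumes acquired
#' before the paradigm starts (discarded for T1 stabilisation) and tail
#' volumes appended after it ends.
#'
#' Block onsets are expressed in seconds relative to the first analysis
#' volume (i.e. after the dummy volumes). Task blocks come first in each
#' task/control cycle.
#'
#' @param n_blocks number of task/control repetitions.
#' @param task_s task block duration in seconds.
#' @param control_s control block duration in seconds.
#' @param tr repetition time in seconds.
#' @param n_dummy dummy volumes prepended before the paradigm.
#' @param n_tail spare volumes appended after the paradigm.
#'
#' @return An object of class `fmridual_paradigm` with fields `block_onsets`,
#'   `block_durations`, `n_blocks`, `tr`, `n_dummy`, `n_tail`, `n_analysis`
#'   (volumes covering the paradigm) and `n_volumes` (total emitted volumes).
#'
#' @examples
#' p <- make_block_paradigm(6, 24, 24, tr = 1.7, n_dummy = 3, n_tail = 4)
#' p$n_volumes # 177
#' @export
make_block_paradigm <- function(n_blocks, task_s, control_s, tr,
                                n_dummy = 0L, n_tail = 0L) {
  if (n_blocks < 1 || task_s <= 0 || control_s <= 0 || tr <= 0) {
    stop_invalid("n_blocks, task_s, control_s and tr must be positive")
  }
  if (n_dummy < 0 || n_tail < 0) stop_invalid("n_dummy and n_tail must be >= 0")
  cycle <- task_s + control_s
  onsets <- (seq_len(n_blocks) - 1) * cycle
  span <- n_blocks * cycle
  n_analysis <- as.integer(ceiling(span / tr - 1e-9))
  structure(list(
    block_onsets = onsets,
    block_durations = rep(task_s, n_blocks),
    n_blocks = as.integer(n_blocks),
    tr = tr,
    n_dummy = as.integer(n_dummy),
    n_tail = as.integer(n_tail),
    n_analysis = n_analysis,
    n_volumes = n_analysis + as.integer(n_dummy) + as.integer(n_tail)
  ), class = "fmridual_paradigm")
}

#' Sample the task boxcar at volume midpoints
#'
#' Returns the binary task indicator per analysis volume (dummy and tail
#' volumes excluded). A volume is labelled 1 when its acquisition midpoint
#' falls inside a task block; the midpoint convention is symmetric and does
#' not depend on how block edges align with the TR grid.
#'
#' @param p a paradigm from [make_block_paradigm()].
#' @return integer vector of 0/1, length `p$n_analysis`.
#' @export
sample_boxcar <- function(p) {
  stopifnot(inherits(p, "fmridual_paradigm"))
  mid <- (seq_len(p$n_analysis) - 0.5) * p$tr
  out <- integer(p$n_analysis)
  for (b in seq_len(p$n_blocks)) {
    on <- p$block_onsets[b]
    out[mid >= on & mid < on + p$block_durations[b]] <- 1L
  }
  out
}

#' Gamma hemodynamic response kernel
#'
#' Single-gamma HRF parameterised by its distribution mean lag and standard
#' deviation (defaults 6 s and 3 s). Moment matching gives shape
#' `(mean/sd)^2` and scale `sd^2/mean`. The kernel is sampled on the TR grid
#' and normalised to unit sum, so convolving a sustained unit input reaches a
#' plateau of 1 and planted percent-signal-change amplitudes stay
#' unit-interpretable.
#'
#' @param mean_lag_s mean lag of the response in seconds.
#' @param std_s standard deviation of the response in seconds.
#' @param tr sampling interval in seconds.
#' @param length_s kernel support in seconds.
#' @return numeric kernel vector sampled at `0, tr, 2 tr, ...` up to
#'   `length_s`, summing to 1.
#' @export
gamma_hrf <- function(mean_lag_s = 6, std_s = 3, tr = 1.7, length_s = 30) {
  if (mean_lag_s <= 0 || std_s <= 0) stop_invalid("mean lag and std must be > 0")
  shape <- (mean_lag_s / std_s)^2
  scale <- std_s^2 / mean_lag_s
  t <- seq(0, length_s, by = tr)
  k <- stats::dgamma(t, shape = shape, scale = scale)
  k / sum(k)
}

# Convolve a per-volume regressor with an HRF kernel, truncated to length(x).
convolve_hrf <- function(x, kernel) {
  n <- length(x)
  full <- stats::convolve(c(x, numeric(length(kernel))), rev(kernel), type = "open")
  full[seq_len(n)]
}
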