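#' @keywords internal
"_PACKAGE"

# Run an expression under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(seed)
  }
  expr
}

# Derive a reproducible child seed from a master seed and a label, independent
# of execution order. Kept below 2^31 so it is a valid R integer.
derive_seed <- function(seed, label) {
  h <- sum(utf8ToInt(paste0(label, ":", seed)) * seq_along(utf8ToInt(paste0(label, ":", seed))))
  as.integer((as.double(seed) * 48271 + h) %% 2147483587) + 1L
}

stop_invalid <- function(...) stop(..., call. = FALSE)

`%||%` <- function(a, b) if (is.null(a)) b else a
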