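# Internal helpers shared across modules.

# Evaluate `code` with the RNG seeded at `seed`, restoring the caller's RNG
# state afterwards so library functions never clobber user randomness.
# seed = NULL leaves the RNG untouched.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    seed <- as.integer(seed %% .Machine$integer.max)
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv(), inherits = FALSE)
    }
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(seed)
  }
  force(code)
}

# Deterministic stream of child seeds (< 2^31) from one master seed.
derive_seed <- function(seed, k) {
  if (is.null(seed)) return(NULL)
  as.integer((as.double(seed) + 104729 * as.double(k)) %% 2147483629)
}

# Indices of time-axis samples falling in the closed window [w1, w2] (ms).
window_index <- function(time, window) {
  stopifnot(length(window) == 2L, window[1] <= window[2])
  idx <- which(time >= window[1] - 1e-9 & time <= window[2] + 1e-9)
  if (length(idx) == 0L) {
    stop("window [", window[1], ", ", window[2], "] ms contains no samples")
  }
  idx
}

`%||%` <- function(a, b) if (is.null(a)) b else a
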