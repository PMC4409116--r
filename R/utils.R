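# Internal helpers shared across modules.

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
local_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

# Deterministic substream derivation: fold integer keys into [0, 2^31 - 2].
# Order matters, so (seed, channel, condition) and (seed, condition, channel)
# give different streams.
derive_seed <- function(seed, ...) {
  keys <- c(...)
  h <- as.double(seed) %% 2147483647
  for (k in keys) {
    h <- (h * 48271 + as.double(k) * 104729 + 12345) %% 2147483647
  }
  as.integer(h)
}

# Round halves away from zero (base round() is round-half-even); used for the
# ms -> sample mapping so window sample counts are bit-stable.
round_half_up <- function(x) floor(x + 0.5)

# Indices of the central `frac` of a series, used to exclude boundary
# artifacts from summary statistics.
central_indices <- function(n, frac = 0.8) {
  drop <- floor(n * (1 - frac) / 2)
  seq.int(drop + 1L, n - drop)
}

# Phase unwrapping: remove 2*pi jumps from a wrapped angle series.
unwrap_phase <- function(p) {
  if (length(p) < 2L) return(p)
  d <- diff(p)
  d <- d - 2 * pi * round(d / (2 * pi))
  c(p[1L], p[1L] + cumsum(d))
}

stopf <- function(class, fmt, ...) {
  stop(structure(
    class = c(class, "ermtools_error", "error", "condition"),
    list(message = sprintf(fmt, ...), call = sys.call(-1))
  ))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
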