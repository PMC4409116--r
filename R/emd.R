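#' Empirical mode decomposition with spline envelopes
#'
#' Core decomposition machinery: extrema detection, cubic-spline envelope
#' means, fixed-iteration sifting, plain EMD and its noise-assisted ensemble
#' variant (EEMD). Signals are decomposed into a fixed number of intrinsic
#' mode functions (IMFs) plus a non-oscillating residual trend; following the
#' convention of event-related-mode analysis the residual is stored as the
#' last mode, so a decomposition into 7 IMFs is returned as 8 modes.
#'
#' @name emd_core
NULL

#' Locate strict local extrema
#'
#' Scans a numeric series for strict local maxima and minima by neighbour
#' comparison. Plateaus are collapsed: when several equal samples form a
#' local extremum, the first sample of the plateau is reported. Endpoints
#' are never extrema. Monotone or constant input yields empty index vectors.
#'
#' @param x numeric vector.
#' @return list with integer vectors `maxima` and `minima` (1-based indices).
#' @export
#' @examples
#' find_extrema(sin(2 * pi * seq(0, 1, length.out = 100)))
find_extrema <- function(x) {
  if (!is.numeric(x)) stopf("erm_bad_input", "input must be numeric")
  if (anyNA(x) || any(!is.finite(x))) {
    stopf("erm_bad_input", "input contains non-finite values")
  }
  n <- length(x)
  empty <- list(maxima = integer(0), minima = integer(0))
  if (n < 3L) return(empty)
  r <- rle(as.numeric(x))
  k <- length(r$values)
  if (k < 3L) return(empty)
  starts <- cumsum(c(1L, r$lengths[-k]))
  v <- r$values
  i <- 2:(k - 1L)
  is_max <- v[i] > v[i - 1L] & v[i] > v[i + 1L]
  is_min <- v[i] < v[i - 1L] & v[i] < v[i + 1L]
  list(maxima = starts[i][is_max], minima = starts[i][is_min])
}

# A series is treated as (part of) the residual trend when it lacks the two
# maxima and two minima needed to anchor both spline envelopes.
is_trend <- function(x) {
  e <- find_extrema(x)
  length(e$maxima) < 2L || length(e$minima) < 2L
}

# Spline envelope through one family of extrema, mirror-extended by two
# extrema on each side (reflection about the first/last sample) to suppress
# end swings on short epochs.
spline_envelope <- function(x, idx) {
  n <- length(x)
  m <- length(idx)
  left <- 2L - idx[c(2L, 1L)]
  right <- 2L * n - idx[c(m, m - 1L)]
  knots_x <- c(left, idx, right)
  knots_y <- x[c(idx[c(2L, 1L)], idx, idx[c(m, m - 1L)])]
  keep <- !duplicated(knots_x)
  stats::splinefun(knots_x[keep], knots_y[keep], method = "natural")(seq_len(n))
}

#' Mean of the upper and lower spline envelopes
#'
#' Fits a natural cubic spline through the local maxima (upper envelope) and
#' another through the local minima (lower envelope), after mirror-extending
#' two extrema beyond each end of the series, and returns their pointwise
#' mean. This is the quantity subtracted at each sifting step.
#'
#' @param x numeric vector with at least two maxima and two minima.
#' @return numeric vector of the same length as `x`.
#' @export
envelope_mean <- function(x) {
  e <- find_extrema(x)
  if (length(e$maxima) < 2L || length(e$minima) < 2L) {
    stopf("erm_trend", "signal has too few extrema for envelopes (is a trend)")
  }
  (spline_envelope(x, e$maxima) + spline_envelope(x, e$minima)) / 2
}

# envelope_mean without re-checking extrema (caller already did).
envelope_mean_at <- function(x, e) {
  (spline_envelope(x, e$maxima) + spline_envelope(x, e$minima)) / 2
}

#' Extract one mode candidate by fixed-iteration sifting
#'
#' Iterates `h <- h - envelope_mean(h)` exactly `iterations` times, stopping
#' early only if the running series loses the extrema needed for envelopes.
#' No formal IMF stopping criterion is evaluated; the fixed iteration count
#' keeps mode extraction deterministic and comparable across trials.
#'
#' @param x numeric vector; must not already be a trend.
#' @param iterations number of sifting iterations (>= 1).
#' @return numeric vector: the mode candidate.
#' @export
sift <- function(x, iterations = 10L) {
  if (iterations < 1L) stopf("erm_bad_input", "iterations must be >= 1")
  e <- find_extrema(x)
  if (length(e$maxima) < 2L || length(e$minima) < 2L) {
    stopf("erm_trend", "signal has too few extrema to sift (is a trend)")
  }
  h <- x
  for (k in seq_len(iterations)) {
    h <- h - envelope_mean_at(h, e)
    if (k < iterations) {
      e <- find_extrema(h)
      if (length(e$maxima) < 2L || length(e$minima) < 2L) break
    }
  }
  h
}

#' Construct a mode-set container
#'
#' @param modes numeric matrix, one row per mode (last row = residual trend).
#' @param sample_rate sampling rate in samples/s.
#' @param meta optional list of provenance metadata (config echo, seeds).
#' @return object of class `mode_set`.
#' @export
mode_set <- function(modes, sample_rate = 500, meta = list()) {
  stopifnot(is.matrix(modes))
  structure(
    list(modes = modes, sample_rate = sample_rate, meta = meta),
    class = "mode_set"
  )
}

#' @export
print.mode_set <- function(x, ...) {
  cat(sprintf(
    "<mode_set> %d modes x %d samples @ %g samples/s (last mode = trend)\n",
    nrow(x$modes), ncol(x$modes), x$sample_rate
  ))
  invisible(x)
}

#' Plain empirical mode decomposition
#'
#' Decomposes a signal into `n_imfs` intrinsic mode functions plus the
#' residual trend, which is appended as mode `n_imfs + 1`. Each IMF is
#' obtained by sifting the running remainder a fixed number of iterations and
#' subtracting the result. The decomposition telescopes, so the modes sum to
#' the input exactly (to floating-point round-off). If the remainder runs out
#' of extrema before all IMFs are extracted, the remaining IMF slots are zero
#' and the trend occupies the last slot.
#'
#' @param x numeric vector (length >= 8).
#' @param n_imfs number of oscillatory modes to extract (default 7).
#' @param sift_iterations sifting iterations per mode (default 10).
#' @param sample_rate samples/s, carried into the result (default 500).
#' @return a [mode_set()] with `n_imfs + 1` rows.
#' @export
#' @examples
#' t <- seq(0, 2, length.out = 1000)
#' ms <- emd(cos(2 * pi * 25 * t) + cos(2 * pi * 3 * t))
#' max(abs(colSums(ms$modes) - (cos(2 * pi * 25 * t) + cos(2 * pi * 3 * t))))
emd <- function(x, n_imfs = 7L, sift_iterations = 10L, sample_rate = 500) {
  if (length(x) < 8L) stopf("erm_bad_input", "signal too short (< 8 samples)")
  if (any(!is.finite(x))) stopf("erm_bad_input", "signal has non-finite values")
  n <- length(x)
  modes <- matrix(0, nrow = n_imfs + 1L, ncol = n)
  r <- as.numeric(x)
  for (j in seq_len(n_imfs)) {
    if (is_trend(r)) break
    h <- sift(r, sift_iterations)
    modes[j, ] <- h
    r <- r - h
  }
  modes[n_imfs + 1L, ] <- r
  mode_set(modes, sample_rate,
           meta = list(method = "emd", n_imfs = n_imfs,
                       sift_iterations = sift_iterations))
}

#' EEMD configuration
#'
#' Bundles the parameters of the ensemble decomposition: ensemble size E,
#' the ratio of added white-noise standard deviation to the signal's standard
#' deviation, the number of oscillatory modes, sifting iterations per mode,
#' and the seed that fixes every noise realization.
#'
#' @param ensemble_size ensemble size E (default 20).
#' @param noise_ratio sigma_noise / sigma_signal (default 0.2).
#' @param n_imfs oscillatory modes per decomposition (default 7; the residual
#'   trend is appended as mode `n_imfs + 1`).
#' @param sift_iterations sifting iterations per mode (default 10).
#' @param seed integer seed for the ensemble noise.
#' @return object of class `eemd_config`.
#' @export
eemd_config <- function(ensemble_size = 20L, noise_ratio = 0.2, n_imfs = 7L,
                        sift_iterations = 10L, seed = 1L) {
  if (ensemble_size < 1L) stopf("erm_bad_input", "ensemble_size must be >= 1")
  if (noise_ratio < 0) stopf("erm_bad_input", "noise_ratio must be >= 0")
  if (n_imfs < 1L) stopf("erm_bad_input", "n_imfs must be >= 1")
  structure(
    list(ensemble_size = as.integer(ensemble_size), noise_ratio = noise_ratio,
         n_imfs = as.integer(n_imfs),
         sift_iterations = as.integer(sift_iterations),
         seed = as.integer(seed)),
    class = "eemd_config"
  )
}

#' Ensemble empirical mode decomposition
#'
#' Runs plain EMD on `ensemble_size` noise-perturbed copies of the signal
#' (white Gaussian noise with standard deviation `noise_ratio` times the
#' signal's standard deviation) and averages corresponding modes across the
#' ensemble. Noise for ensemble member n is drawn from an independent
#' substream derived from `(seed, n)`, so members are order-independent and
#' the result is bit-reproducible given the config. With `noise_ratio = 0`
#' the result is identical to plain EMD.
#'
#' @param x numeric vector.
#' @param cfg an [eemd_config()].
#' @param sample_rate samples/s (default 500).
#' @return a [mode_set()] with `cfg$n_imfs + 1` rows.
#' @export
eemd <- function(x, cfg = eemd_config(), sample_rate = 500) {
  stopifnot(inherits(cfg, "eemd_config"))
  sigma <- stats::sd(x)
  if (cfg$noise_ratio == 0 || sigma == 0 || cfg$ensemble_size == 1L && cfg$noise_ratio == 0) {
    ms <- emd(x, cfg$n_imfs, cfg$sift_iterations, sample_rate)
    ms$meta <- c(ms$meta, list(method = "eemd", config = unclass(cfg)))
    return(ms)
  }
  n <- length(x)
  acc <- matrix(0, nrow = cfg$n_imfs + 1L, ncol = n)
  noise_sd <- cfg$noise_ratio * sigma
  for (member in seq_len(cfg$ensemble_size)) {
    eps <- local_seed(derive_seed(cfg$seed, member),
                      stats::rnorm(n, 0, noise_sd))
    acc <- acc + emd(x + eps, cfg$n_imfs, cfg$sift_iterations, sample_rate)$modes
  }
  mode_set(acc / cfg$ensemble_size, sample_rate,
           meta = list(method = "eemd", config = unclass(cfg)))
}
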