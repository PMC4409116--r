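#' Hilbert spectral analysis of intrinsic modes
#'
#' Instantaneous amplitude, phase and frequency of each oscillatory mode via
#' the analytic signal, plus a mode-wise Hilbert-Huang spectrum container
#' with band-labelling helpers. Summary statistics exclude the outer 10% of
#' samples at each end, where the discrete Hilbert transform is unreliable.
#'
#' @name hht
NULL

# Analytic extension via the one-sided FFT spectrum.
analytic_signal <- function(x) {
  n <- length(x)
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1L] <- 1
    h[2:(n / 2)] <- 2
    h[n / 2 + 1L] <- 1
  } else {
    h[1L] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(X * h, inverse = TRUE) / n
}

#' Instantaneous amplitude and unwrapped phase of a mode
#'
#' Computes the analytic extension of an oscillatory (roughly zero-mean) mode
#' and returns its modulus and unwrapped argument. Intended for IMFs; the
#' residual trend has no meaningful phase and should be excluded.
#'
#' @param x numeric vector.
#' @return list with numeric vectors `amplitude` (>= 0) and `phase` (rad,
#'   unwrapped).
#' @export
#' @examples
#' t <- seq(0, 2, length.out = 1000)
#' ap <- analytic_amplitude_phase(2 * cos(2 * pi * 10 * t))
#' range(ap$amplitude[100:900])
analytic_amplitude_phase <- function(x) {
  if (all(x == 0)) {
    return(list(amplitude = numeric(length(x)), phase = numeric(length(x))))
  }
  z <- analytic_signal(x)
  list(amplitude = Mod(z), phase = unwrap_phase(Arg(z)))
}

#' Instantaneous frequency from an unwrapped phase series
#'
#' Differentiates the phase by centred finite differences (one-sided at the
#' endpoints) and converts rad/sample to Hz. Transiently negative frequencies
#' are reported as-is, not clamped; summaries should use the central portion
#' of the series.
#'
#' @param phase numeric vector of unwrapped phase (rad).
#' @param sample_rate samples/s.
#' @return numeric vector of instantaneous frequency (Hz).
#' @export
instantaneous_frequency <- function(phase, sample_rate) {
  n <- length(phase)
  if (n < 2L) return(numeric(n))
  d <- numeric(n)
  d[1L] <- phase[2L] - phase[1L]
  d[n] <- phase[n] - phase[n - 1L]
  if (n > 2L) d[2:(n - 1L)] <- (phase[3:n] - phase[1:(n - 2L)]) / 2
  d * sample_rate / (2 * pi)
}

#' Hilbert-Huang spectrum of a mode set
#'
#' Applies [analytic_amplitude_phase()] and [instantaneous_frequency()] to
#' every oscillatory mode of a decomposition. The residual trend (last mode)
#' carries amplitude only (its absolute value); its phase and frequency are
#' `NA`.
#'
#' @param ms a [mode_set()].
#' @return object of class `hht_spectrum`: lists `amplitude`, `phase`,
#'   `frequency` (one numeric vector per mode) plus `sample_rate`.
#' @export
hh_spectrogram <- function(ms) {
  stopifnot(inherits(ms, "mode_set"))
  n_modes <- nrow(ms$modes)
  n <- ncol(ms$modes)
  amp <- phase <- freq <- vector("list", n_modes)
  for (j in seq_len(n_modes - 1L)) {
    ap <- analytic_amplitude_phase(ms$modes[j, ])
    amp[[j]] <- ap$amplitude
    phase[[j]] <- ap$phase
    freq[[j]] <- if (all(ms$modes[j, ] == 0)) numeric(n) else
      instantaneous_frequency(ap$phase, ms$sample_rate)
  }
  amp[[n_modes]] <- abs(ms$modes[n_modes, ])
  phase[[n_modes]] <- rep(NA_real_, n)
  freq[[n_modes]] <- rep(NA_real_, n)
  structure(
    list(amplitude = amp, phase = phase, frequency = freq,
         sample_rate = ms$sample_rate, n_samples = n),
    class = "hht_spectrum"
  )
}

#' @export
print.hht_spectrum <- function(x, ...) {
  cat(sprintf("<hht_spectrum> %d modes x %d samples @ %g samples/s\n",
              length(x$amplitude), x$n_samples, x$sample_rate))
  invisible(x)
}

#' Central-window mean instantaneous frequency per mode
#'
#' Mean (and median) instantaneous frequency of each oscillatory mode over
#' the central fraction of samples, skipping boundary artifacts.
#'
#' @param spec an `hht_spectrum`.
#' @param frac central fraction of samples to keep (default 0.8).
#' @return data.frame with columns `mode`, `mean_hz`, `median_hz`.
#' @export
mode_mean_frequency <- function(spec, frac = 0.8) {
  stopifnot(inherits(spec, "hht_spectrum"))
  idx <- central_indices(spec$n_samples, frac)
  n_modes <- length(spec$frequency)
  res <- data.frame(mode = seq_len(n_modes), mean_hz = NA_real_,
                    median_hz = NA_real_)
  for (j in seq_len(n_modes - 1L)) {
    f <- spec$frequency[[j]][idx]
    res$mean_hz[j] <- mean(f)
    res$median_hz[j] <- stats::median(f)
  }
  res
}

#' Label a frequency with its conventional EEG band
#'
#' delta < 4 Hz, theta 4-8 Hz, alpha 8-13 Hz, beta 13-30 Hz, gamma > 30 Hz.
#'
#' @param freq_hz numeric vector of frequencies (Hz).
#' @return character vector of band labels.
#' @export
eeg_band <- function(freq_hz) {
  as.character(cut(freq_hz, breaks = c(-Inf, 4, 8, 13, 30, Inf),
                   labels = c("delta", "theta", "alpha", "beta", "gamma"),
                   right = FALSE))
}

#' Export a Hilbert-Huang spectrum as a long-format table
#'
#' One row per (mode, sample) with time relative to the first sample,
#' instantaneous amplitude and frequency; suitable for plotting.
#'
#' @param spec an `hht_spectrum`.
#' @param onset_index number of samples preceding time zero (default 0).
#' @return data.frame with columns `mode`, `sample`, `time_ms`, `amplitude`,
#'   `frequency_hz`.
#' @export
hht_long <- function(spec, onset_index = 0L) {
  stopifnot(inherits(spec, "hht_spectrum"))
  n_modes <- length(spec$amplitude)
  n <- spec$n_samples
  t_ms <- (seq_len(n) - 1L - onset_index) * 1000 / spec$sample_rate
  do.call(rbind, lapply(seq_len(n_modes), function(j) {
    data.frame(mode = j, sample = seq_len(n), time_ms = t_ms,
               amplitude = spec$amplitude[[j]],
               frequency_hz = spec$frequency[[j]])
  }))
}
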