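#' Synthetic multi-subject event-related EEG
#'
#' Generates epoched multi-channel EEG with known ground truth so every
#' downstream stage (decomposition, windowed statistics, topography) can be
#' validated. Each trial is the sum of Gaussian-windowed evoked components
#' (P100, N200, P300, N400) whose latencies depend on the channel's scalp
#' region, band-limited oscillations with trial-random phase near 25/10/5/2
#' Hz, and 1/f background noise. Condition differences are planted only at
#' the channels and time windows named in the effect map.
#'
#' @name synthetic_eeg
NULL

#' Default evoked-component table
#'
#' Amplitudes are in units of the single-trial noise standard deviation;
#' widths are Gaussian standard deviations in ms. Posterior channels receive
#' the early latency, frontal channels the late latency, central channels
#' both (at half amplitude) when the two differ.
#'
#' @return data.frame with columns `name`, `amplitude`, `width_ms`,
#'   `early_latency_ms`, `late_latency_ms`.
#' @export
default_erp_components <- function() {
  data.frame(
    name = c("P100", "N200", "P300", "N400"),
    amplitude = c(1.0, -1.2, 0.8, -0.6),
    width_ms = c(15, 20, 35, 40),
    early_latency_ms = c(100, 180, 300, 400),
    late_latency_ms = c(170, 240, 300, 400)
  )
}

# Scalp region of each channel, from its layout cluster.
channel_region <- function(channels, layout) {
  cl <- layout$cluster[match(channels, layout$label)]
  if (anyNA(cl)) {
    stopf("erm_bad_input", "channels missing from layout: %s",
          paste(channels[is.na(cl)], collapse = ", "))
  }
  ifelse(cl %in% c("OC", "P", "PT"), "posterior",
         ifelse(cl == "CE", "central", "frontal"))
}

#' Simulation configuration for synthetic EEG
#'
#' @param n_subjects number of subjects (default 18).
#' @param channels channel labels; defaults to all labels of `layout`.
#' @param layout an electrode layout (see [default_layout()]); provides the
#'   scalp region of each channel.
#' @param n_trials_per_condition trials per condition per subject
#'   (default 115, about 230 per subject in total).
#' @param sample_rate samples/s (default 500).
#' @param pre_samples,post_samples samples before / from stimulus onset
#'   (defaults 75 and 425; the epoch is their sum, 500 samples spanning
#'   -150 to +850 ms).
#' @param components evoked-component table, see [default_erp_components()].
#' @param band_oscillations data.frame with `freq_hz` and `amplitude`;
#'   each trial receives every oscillation with an independent uniform phase,
#'   so they average out of the evoked response (induced activity).
#' @param noise_exponent 1/f spectral slope of the background noise
#'   (default 1; 0 gives white noise).
#' @param noise_sd single-trial noise standard deviation (a.u., default 1).
#' @param subject_amp_sd between-subject s.d. of the multiplicative component
#'   amplitude factor (default 0.1).
#' @param latency_jitter_sd_ms between-subject s.d. of component latency (ms,
#'   default 5).
#' @param effect_map list of planted condition effects; each entry is a list
#'   with `channels`, `window_ms = c(lo, hi)` relative to onset, and `delta`:
#'   a Gaussian bump spanning the window (s.d. one sixth of its width) is
#'   added to CT trials, scaled so that its mean over the window equals
#'   `delta` — the planted value is exactly the window-mean amplitude
#'   difference that the analysis measures.
#' @param seed integer seed; fixes all randomness of the dataset.
#' @return object of class `eeg_sim_config`.
#' @export
eeg_sim_config <- function(n_subjects = 18L, channels = NULL,
                           layout = default_layout(),
                           n_trials_per_condition = 115L,
                           sample_rate = 500, pre_samples = 75L,
                           post_samples = 425L,
                           components = default_erp_components(),
                           band_oscillations = data.frame(
                             freq_hz = c(25, 10, 5, 2),
                             amplitude = c(0.15, 0.25, 0.3, 0.3)),
                           noise_exponent = 1, noise_sd = 1,
                           subject_amp_sd = 0.1, latency_jitter_sd_ms = 5,
                           effect_map = list(), seed = 1L) {
  channels <- channels %||% layout$label
  epoch_ms <- c(-pre_samples, post_samples) * 1000 / sample_rate
  lat <- c(components$early_latency_ms, components$late_latency_ms)
  if (any(lat <= epoch_ms[1L] | lat >= epoch_ms[2L])) {
    stopf("erm_bad_input", "component latencies outside the epoch")
  }
  for (ef in effect_map) {
    if (ef$window_ms[1L] < epoch_ms[1L] || ef$window_ms[2L] > epoch_ms[2L]) {
      stopf("erm_bad_input", "effect window outside the epoch")
    }
    if (!all(ef$channels %in% channels)) {
      stopf("erm_bad_input", "effect channels not in the simulated montage")
    }
  }
  structure(
    list(n_subjects = as.integer(n_subjects), channels = channels,
         region = channel_region(channels, layout),
         n_trials_per_condition = as.integer(n_trials_per_condition),
         sample_rate = sample_rate, pre_samples = as.integer(pre_samples),
         post_samples = as.integer(post_samples), components = components,
         band_oscillations = band_oscillations,
         noise_exponent = noise_exponent, noise_sd = noise_sd,
         subject_amp_sd = subject_amp_sd,
         latency_jitter_sd_ms = latency_jitter_sd_ms,
         effect_map = effect_map, seed = as.integer(seed)),
    class = "eeg_sim_config"
  )
}

# 1/f^exponent noise, demeaned and rescaled to an exact sample s.d.
noise_1f <- function(n, exponent, sd_target) {
  if (sd_target == 0) return(numeric(n))
  w <- stats::rnorm(n)
  if (exponent != 0) {
    W <- stats::fft(w)
    k <- 0:(n - 1L)
    f <- pmin(k, n - k)
    scale <- c(0, f[-1L]^(-exponent / 2))
    w <- Re(stats::fft(W * scale, inverse = TRUE) / n)
  }
  s <- stats::sd(w)
  if (s == 0) return(numeric(n))
  (w - mean(w)) / s * sd_target
}

# Deterministic evoked waveform for one channel region and one subject's
# amplitude factors / latency jitters.
evoked_waveform <- function(t_ms, region, comps, amp_fac, lat_jit) {
  y <- numeric(length(t_ms))
  for (i in seq_len(nrow(comps))) {
    a <- comps$amplitude[i] * amp_fac[i]
    w <- comps$width_ms[i]
    early <- comps$early_latency_ms[i] + lat_jit[i]
    late <- comps$late_latency_ms[i] + lat_jit[i]
    bump <- function(mu, amp) amp * exp(-(t_ms - mu)^2 / (2 * w^2))
    y <- y + switch(region,
      posterior = bump(early, a),
      frontal   = bump(late, a),
      central   = if (early == late) bump(early, a) else
        bump(early, a / 2) + bump(late, a / 2)
    )
  }
  y
}

#' Construct a trial tensor
#'
#' @param subject_id subject identifier.
#' @param channels character vector of channel labels.
#' @param data numeric array channels x samples x trials.
#' @param conditions per-trial condition labels, each `"CT"` or `"NCT"`.
#' @param sample_rate samples/s (default 500).
#' @param onset_index number of pre-stimulus samples (default 75; the onset
#'   sample is the 76th of the epoch).
#' @param ground_truth optional list describing planted structure.
#' @return object of class `trial_tensor`.
#' @export
trial_tensor <- function(subject_id, channels, data, conditions,
                         sample_rate = 500, onset_index = 75L,
                         ground_truth = NULL) {
  stopifnot(is.array(data), length(dim(data)) == 3L)
  if (dim(data)[1L] != length(channels)) {
    stopf("erm_dim_mismatch", "data has %d rows but %d channel labels",
          dim(data)[1L], length(channels))
  }
  if (dim(data)[3L] != length(conditions)) {
    stopf("erm_dim_mismatch", "data has %d trials but %d condition labels",
          dim(data)[3L], length(conditions))
  }
  if (!all(conditions %in% c("CT", "NCT"))) {
    stopf("erm_bad_label", "unknown condition label(s): %s",
          paste(unique(setdiff(conditions, c("CT", "NCT"))), collapse = ", "))
  }
  if (any(!is.finite(data))) {
    stopf("erm_bad_input", "trial data contains non-finite values")
  }
  structure(
    list(subject_id = subject_id, channels = channels, data = data,
         conditions = conditions, sample_rate = sample_rate,
         onset_index = as.integer(onset_index),
         ground_truth = ground_truth),
    class = "trial_tensor"
  )
}

#' @export
print.trial_tensor <- function(x, ...) {
  cat(sprintf(
    "<trial_tensor> subject %s: %d channels x %d samples x %d trials (%d CT / %d NCT)\n",
    as.character(x$subject_id), dim(x$data)[1L], dim(x$data)[2L],
    dim(x$data)[3L], sum(x$conditions == "CT"), sum(x$conditions == "NCT")
  ))
  invisible(x)
}

#' Generate a synthetic multi-subject EEG dataset
#'
#' One [trial_tensor()] per subject, fully determined by `config$seed`.
#' Evoked components are deterministic per subject (with between-subject
#' amplitude and latency variability); oscillations and 1/f noise are
#' redrawn per trial; planted effects are added to CT trials only, as
#' Gaussian bumps spanning the configured windows at the configured channels.
#'
#' @param config an [eeg_sim_config()].
#' @return list of `trial_tensor`, length `config$n_subjects`.
#' @export
synth_eeg_dataset <- function(config) {
  stopifnot(inherits(config, "eeg_sim_config"))
  lapply(seq_len(config$n_subjects), function(s) {
    local_seed(derive_seed(config$seed, 101L, s), synth_subject(config, s))
  })
}

synth_subject <- function(cfg, subject) {
  n_ch <- length(cfg$channels)
  n_s <- cfg$pre_samples + cfg$post_samples
  n_tr <- 2L * cfg$n_trials_per_condition
  t_ms <- (seq_len(n_s) - 1L - cfg$pre_samples) * 1000 / cfg$sample_rate
  t_s <- t_ms / 1000
  conditions <- rep(c("CT", "NCT"), times = cfg$n_trials_per_condition)

  n_comp <- nrow(cfg$components)
  amp_fac <- 1 + stats::rnorm(n_comp, 0, cfg$subject_amp_sd)
  lat_jit <- stats::rnorm(n_comp, 0, cfg$latency_jitter_sd_ms)

  # deterministic per-channel evoked waveform, per condition
  evoked <- matrix(0, n_ch, n_s)
  for (c_i in seq_len(n_ch)) {
    evoked[c_i, ] <- evoked_waveform(t_ms, cfg$region[c_i], cfg$components,
                                     amp_fac, lat_jit)
  }
  effect <- matrix(0, n_ch, n_s)  # added to CT trials only
  for (ef in cfg$effect_map) {
    mid <- mean(ef$window_ms)
    sd_ms <- diff(ef$window_ms) / 6
    shape <- exp(-(t_ms - mid)^2 / (2 * sd_ms^2))
    # normalize so the window-mean of the planted bump equals delta exactly
    lo0 <- cfg$pre_samples + round_half_up(ef$window_ms[1L] * cfg$sample_rate / 1000)
    hi0 <- cfg$pre_samples + round_half_up(ef$window_ms[2L] * cfg$sample_rate / 1000)
    shape <- shape / mean(shape[(lo0 + 1L):hi0])
    rows <- match(ef$channels, cfg$channels)
    effect[rows, ] <- effect[rows, ] +
      matrix(ef$delta * shape, length(rows), n_s, byrow = TRUE)
  }

  osc <- cfg$band_oscillations
  data <- array(0, dim = c(n_ch, n_s, n_tr))
  for (tr in seq_len(n_tr)) {
    is_ct <- conditions[tr] == "CT"
    for (c_i in seq_len(n_ch)) {
      y <- evoked[c_i, ]
      if (is_ct) y <- y + effect[c_i, ]
      if (nrow(osc) > 0) {
        ph <- stats::runif(nrow(osc), 0, 2 * pi)
        for (b in seq_len(nrow(osc))) {
          y <- y + osc$amplitude[b] * cos(2 * pi * osc$freq_hz[b] * t_s + ph[b])
        }
      }
      y <- y + noise_1f(n_s, cfg$noise_exponent, cfg$noise_sd)
      data[c_i, , tr] <- y
    }
  }
  trial_tensor(
    subject_id = subject, channels = cfg$channels, data = data,
    conditions = conditions, sample_rate = cfg$sample_rate,
    onset_index = cfg$pre_samples,
    ground_truth = list(effect_map = cfg$effect_map,
                        components = cfg$components,
                        amp_factors = amp_fac, latency_jitter_ms = lat_jit)
  )
}
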