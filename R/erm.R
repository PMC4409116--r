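#' Event-related mode extraction
#'
#' The analysis pipeline proper: epoch segmentation, z-score
#' standardization, ERP averaging, and the two routes to event-related modes
#' (ERMs): approach A decomposes the per-condition ERP of each channel;
#' approach B decomposes every single trial and averages corresponding modes
#' over trials. Both yield, per channel and condition, 7 oscillatory modes
#' plus the residual trend stored as the 8th mode.
#'
#' @name erm_pipeline
NULL

#' Cut one epoch around a stimulus onset
#'
#' Extracts `pre + post` samples such that the first `pre` samples precede
#' the onset and the sample at position `pre + 1` is the onset sample itself.
#'
#' @param x numeric series.
#' @param onset 1-based index of the onset sample in `x`.
#' @param pre samples before onset (default 75).
#' @param post samples from onset onwards (default 425).
#' @return numeric vector of length `pre + post`.
#' @export
segment_epoch <- function(x, onset, pre = 75L, post = 425L) {
  if (onset - pre < 1L || onset + post - 1L > length(x)) {
    stopf("erm_out_of_range",
          "epoch [%d, %d] outside series of length %d",
          onset - pre, onset + post - 1L, length(x))
  }
  x[(onset - pre):(onset + post - 1L)]
}

#' z-score standardization
#'
#' Centres to zero mean and scales to unit standard deviation, preserving
#' relative shape. Constant input has no defined z-score and raises an error.
#'
#' @param x numeric vector.
#' @return standardized vector.
#' @export
standardize <- function(x) {
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0) {
    stopf("erm_degenerate", "cannot z-score a constant epoch")
  }
  (x - mean(x)) / s
}

#' Per-channel event-related potential
#'
#' Samplewise mean over all trials of one condition.
#'
#' @param tt a [trial_tensor()].
#' @param condition `"CT"` or `"NCT"`.
#' @return numeric matrix channels x samples.
#' @export
erp_average <- function(tt, condition) {
  stopifnot(inherits(tt, "trial_tensor"))
  sel <- tt$conditions == condition
  if (!any(sel)) {
    stopf("erm_empty_condition", "no trials with condition %s", condition)
  }
  erp <- apply(tt$data[, , sel, drop = FALSE], c(1L, 2L), mean)
  rownames(erp) <- tt$channels
  erp
}

#' Amplitude analysis window
#'
#' A component/phase pair with its interval in ms relative to stimulus
#' onset. Defaults follow the early/late occipital-to-frontal windows:
#' P100 early (60, 120), P100 late (120, 180), N200 early (150, 210),
#' N200 late (200, 260); P300 (270, 370) and N400 (370, 450) have a single
#' window.
#'
#' @param component one of `"P100"`, `"N200"`, `"P300"`, `"N400"`.
#' @param phase `"early"` or `"late"`.
#' @param interval_ms optional `c(lo, hi)` override (ms relative to onset,
#'   within \[-150, 850\]).
#' @return object of class `window_def`.
#' @export
window_def <- function(component = c("P100", "N200", "P300", "N400"),
                       phase = c("early", "late"), interval_ms = NULL) {
  component <- match.arg(component)
  phase <- match.arg(phase)
  defaults <- list(
    P100 = list(early = c(60, 120), late = c(120, 180)),
    N200 = list(early = c(150, 210), late = c(200, 260)),
    P300 = list(early = c(270, 370), late = c(270, 370)),
    N400 = list(early = c(370, 450), late = c(370, 450))
  )
  interval_ms <- interval_ms %||% defaults[[component]][[phase]]
  if (interval_ms[1L] < -150 || interval_ms[2L] > 850 ||
      interval_ms[1L] >= interval_ms[2L]) {
    stopf("erm_bad_input", "window must be an increasing pair within [-150, 850] ms")
  }
  structure(list(component = component, phase = phase,
                 interval_ms = interval_ms),
            class = "window_def")
}

# Half-open sample range [lo, hi) of a window: 1-based indices into the
# epoch. ms -> sample uses onset_index + round-half-up(ms * rate / 1000) in
# 0-based samples.
window_sample_range <- function(window, sample_rate, onset_index,
                                n_samples) {
  ms <- window$interval_ms
  lo0 <- onset_index + round_half_up(ms[1L] * sample_rate / 1000)
  hi0 <- onset_index + round_half_up(ms[2L] * sample_rate / 1000)
  if (hi0 <= lo0) stopf("erm_bad_input", "empty analysis window")
  if (lo0 < 0L || hi0 > n_samples) {
    stopf("erm_out_of_range", "window outside the epoch")
  }
  seq.int(lo0 + 1L, hi0)  # 1-based, half-open upper end
}

#' Mean amplitude within an analysis window
#'
#' Arithmetic mean of the samples whose time relative to onset lies in
#' `[lo, hi)` ms.
#'
#' @param x numeric epoch.
#' @param window a [window_def()].
#' @param sample_rate samples/s (default 500).
#' @param onset_index pre-stimulus samples (default 75).
#' @return mean amplitude (a.u.).
#' @export
window_mean_amplitude <- function(x, window, sample_rate = 500,
                                  onset_index = 75L) {
  idx <- window_sample_range(window, sample_rate, onset_index, length(x))
  mean(x[idx])
}

#' Event-related mode set container
#'
#' @param modes numeric 4-d array: channels x conditions x modes x samples.
#' @param channels channel labels.
#' @param conditions condition labels (`c("CT", "NCT")`).
#' @param approach `"A"` or `"B"`.
#' @param config the [eemd_config()] used.
#' @param sample_rate samples/s.
#' @param onset_index pre-stimulus samples.
#' @return object of class `erm_set`.
#' @export
erm_set <- function(modes, channels, conditions, approach, config,
                    sample_rate = 500, onset_index = 75L) {
  stopifnot(length(dim(modes)) == 4L)
  structure(
    list(modes = modes, channels = channels, conditions = conditions,
         approach = approach, config = config, sample_rate = sample_rate,
         onset_index = as.integer(onset_index)),
    class = "erm_set"
  )
}

#' @export
print.erm_set <- function(x, ...) {
  d <- dim(x$modes)
  cat(sprintf(
    "<erm_set> approach %s: %d channels x %d conditions x %d modes x %d samples\n",
    x$approach, d[1L], d[2L], d[3L], d[4L]))
  invisible(x)
}

# EEMD seed for one (channel, condition) cell; shared across trials so that
# approach B on identical trials reproduces approach A exactly.
cell_config <- function(cfg, c_i, cond_i) {
  out <- cfg
  out$seed <- derive_seed(cfg$seed, 211L, c_i, cond_i)
  out
}

#' Event-related modes, approach A (decompose the average)
#'
#' For every channel and condition: average the trials to an ERP, z-score
#' it, and decompose it with EEMD. The resulting modes are phase-locked to
#' the stimulus by construction.
#'
#' @param tt a [trial_tensor()].
#' @param cfg an [eemd_config()].
#' @return an [erm_set()] with approach tag `"A"`.
#' @export
erms_approach_A <- function(tt, cfg = eemd_config()) {
  stopifnot(inherits(tt, "trial_tensor"))
  conditions <- c("CT", "NCT")
  n_ch <- length(tt$channels)
  n_s <- dim(tt$data)[2L]
  modes <- array(0, dim = c(n_ch, 2L, cfg$n_imfs + 1L, n_s))
  for (cond_i in 1:2) {
    erp <- erp_average(tt, conditions[cond_i])
    for (c_i in seq_len(n_ch)) {
      ms <- eemd(standardize(erp[c_i, ]), cell_config(cfg, c_i, cond_i),
                 tt$sample_rate)
      modes[c_i, cond_i, , ] <- ms$modes
    }
  }
  erm_set(modes, tt$channels, conditions, "A", cfg, tt$sample_rate,
          tt$onset_index)
}

#' Event-related modes, approach B (decompose, then average)
#'
#' For every channel: z-score and decompose each single trial with EEMD,
#' then average corresponding modes over the trials of each condition. The
#' resulting modes retain non-phase-locked activity.
#'
#' @param tt a [trial_tensor()].
#' @param cfg an [eemd_config()].
#' @return an [erm_set()] with approach tag `"B"`.
#' @export
erms_approach_B <- function(tt, cfg = eemd_config()) {
  stopifnot(inherits(tt, "trial_tensor"))
  conditions <- c("CT", "NCT")
  n_ch <- length(tt$channels)
  n_s <- dim(tt$data)[2L]
  modes <- array(0, dim = c(n_ch, 2L, cfg$n_imfs + 1L, n_s))
  for (cond_i in 1:2) {
    sel <- which(tt$conditions == conditions[cond_i])
    if (!length(sel)) {
      stopf("erm_empty_condition", "no trials with condition %s",
            conditions[cond_i])
    }
    for (c_i in seq_len(n_ch)) {
      cellcfg <- cell_config(cfg, c_i, cond_i)
      acc <- matrix(0, cfg$n_imfs + 1L, n_s)
      for (tr in sel) {
        acc <- acc + eemd(standardize(tt$data[c_i, , tr]), cellcfg,
                          tt$sample_rate)$modes
      }
      modes[c_i, cond_i, , ] <- acc / length(sel)
    }
  }
  erm_set(modes, tt$channels, conditions, "B", cfg, tt$sample_rate,
          tt$onset_index)
}

#' Partial reconstruction of an ERM set
#'
#' Sums a chosen subset of modes per channel and condition. Summing all
#' modes recovers the (standardized) input up to the ensemble-noise residual;
#' summing an interior subset (default modes 3-7) gives a denoised
#' reconstruction that drops the two fastest modes (broadband noise) and the
#' trend.
#'
#' @param erms an [erm_set()].
#' @param modes mode indices to sum (default 3:7).
#' @return numeric 3-d array channels x conditions x samples.
#' @export
erm_partial_reconstruction <- function(erms, modes = 3:7) {
  stopifnot(inherits(erms, "erm_set"))
  d <- dim(erms$modes)
  if (any(modes < 1L | modes > d[3L])) {
    stopf("erm_bad_input", "mode indices outside 1..%d", d[3L])
  }
  out <- array(0, dim = d[c(1L, 2L, 4L)])
  for (m in modes) out <- out + erms$modes[, , m, ]
  dimnames(out) <- list(erms$channels, erms$conditions, NULL)
  out
}

#' Windowed mode amplitudes of an ERM set
#'
#' Mean amplitude of one mode (or of a partial reconstruction) within an
#' analysis window, for every channel and condition.
#'
#' @param erms an [erm_set()].
#' @param window a [window_def()].
#' @param mode single mode index, or a vector of indices to sum before
#'   windowing.
#' @return numeric matrix channels x conditions.
#' @export
erm_window_amplitude <- function(erms, window, mode = 5L) {
  stopifnot(inherits(erms, "erm_set"))
  series <- erm_partial_reconstruction(erms, modes = mode)
  idx <- window_sample_range(window, erms$sample_rate, erms$onset_index,
                             dim(series)[3L])
  out <- apply(series[, , idx, drop = FALSE], c(1L, 2L), mean)
  dimnames(out) <- list(erms$channels, erms$conditions)
  out
}

#' Latency of the extremal amplitude in a time range
#'
#' @param x numeric epoch.
#' @param range_ms `c(lo, hi)` search range in ms relative to onset.
#' @param sign `+1` to locate the maximum, `-1` the minimum.
#' @param sample_rate samples/s (default 500).
#' @param onset_index pre-stimulus samples (default 75).
#' @return peak latency in ms relative to onset.
#' @export
peak_latency <- function(x, range_ms, sign = 1, sample_rate = 500,
                         onset_index = 75L) {
  w <- window_def("P100", "early", interval_ms = range_ms)
  idx <- window_sample_range(w, sample_rate, onset_index, length(x))
  k <- if (sign >= 0) idx[which.max(x[idx])] else idx[which.min(x[idx])]
  (k - 1L - onset_index) * 1000 / sample_rate
}
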