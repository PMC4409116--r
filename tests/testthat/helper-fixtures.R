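# Shared fixtures: a 16-channel montage spanning the posterior-to-frontal
# axis, the planted-effect map used by recovery tests, and small builders.

fixture_channels <- function() {
  c("O1", "O2", "PO4", "PO8", "P4", "P8", "CP4", "CP6",
    "C3", "C4", "CP3", "C6", "F4", "F6", "AF4", "AF8")
}

fixture_effect_channels <- function() {
  list(early = c("O2", "PO4", "P4", "P8"),
       late = c("F4", "F6", "AF4", "AF8"))
}

fixture_effect_map <- function(delta = -1.2) {
  s <- fixture_effect_channels()
  list(list(channels = s$early, window_ms = c(150, 210), delta = delta),
       list(channels = s$late, window_ms = c(200, 260), delta = delta))
}

# Tiny deterministic trial tensor: every trial of a condition identical.
fixture_identical_trials <- function(n_channels = 2L, n_trials = 3L,
                                     n_samples = 500L, seed = 5L) {
  base <- ermtools:::local_seed(seed, {
    t <- seq(0, (n_samples - 1) / 500, by = 1 / 500)
    rbind(
      sin(2 * pi * 7 * t) + 0.5 * sin(2 * pi * 21 * t),
      cos(2 * pi * 11 * t) + 0.3 * t
    )[seq_len(n_channels), , drop = FALSE]
  })
  data <- array(0, dim = c(n_channels, n_samples, 2L * n_trials))
  conditions <- rep(c("CT", "NCT"), each = n_trials)
  for (tr in seq_len(2L * n_trials)) {
    shift <- if (conditions[tr] == "CT") 0 else 0.25
    data[, , tr] <- base + shift * base^2
  }
  trial_tensor("fix", paste0("ch", seq_len(n_channels)), data, conditions)
}
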