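# Synthetic EEG generator: determinism, planted components and effects,
# convergence of the evoked average.

small_layout <- function() default_layout()

test_that("no noise and no effects make the two conditions identical", {
  cfg <- eeg_sim_config(
    n_subjects = 1, channels = c("O2", "C4", "F4"),
    n_trials_per_condition = 4, noise_sd = 0,
    band_oscillations = data.frame(freq_hz = numeric(0),
                                   amplitude = numeric(0)),
    effect_map = list(), seed = 3
  )
  tt <- synth_eeg_dataset(cfg)[[1]]
  erp_ct <- erp_average(tt, "CT")
  erp_nct <- erp_average(tt, "NCT")
  expect_identical(erp_ct, erp_nct)
})

test_that("deterministic components peak at their configured latencies", {
  cfg <- eeg_sim_config(
    n_subjects = 1, channels = c("O2", "F4"),
    n_trials_per_condition = 2, noise_sd = 0,
    band_oscillations = data.frame(freq_hz = numeric(0),
                                   amplitude = numeric(0)),
    subject_amp_sd = 0, latency_jitter_sd_ms = 0, seed = 9
  )
  tt <- synth_eeg_dataset(cfg)[[1]]
  erp <- erp_average(tt, "CT")
  # posterior P100 at 100 ms: 0-based sample 75 + 50, i.e. R index 126
  w <- window_def("P100", "early")
  idx <- ermtools:::window_sample_range(w, 500, 75L, 500L)
  expect_identical(idx[which.max(erp["O2", idx])], 126L)
  # frontal P100 at the late latency, 170 ms -> R index 161
  wl <- window_def("P100", "late", interval_ms = c(130, 210))
  idxl <- ermtools:::window_sample_range(wl, 500, 75L, 500L)
  expect_identical(idxl[which.max(erp["F4", idxl])], 161L)
  # posterior N200 minimum at 180 ms -> R index 166
  wn <- window_def("N200", "early")
  idxn <- ermtools:::window_sample_range(wn, 500, 75L, 500L)
  expect_identical(idxn[which.min(erp["O2", idxn])], 166L)
})

test_that("planted window delta is recovered within closed-form standard error", {
  n_tr <- 400L
  delta <- 0.8
  w <- window_def("N200", "early")
  cfg <- eeg_sim_config(
    n_subjects = 1, channels = c("O2", "O1"),
    n_trials_per_condition = n_tr, noise_exponent = 0, noise_sd = 1,
    subject_amp_sd = 0, latency_jitter_sd_ms = 0,
    band_oscillations = data.frame(freq_hz = numeric(0),
                                   amplitude = numeric(0)),
    effect_map = list(list(channels = "O2", window_ms = c(150, 210),
                           delta = delta)),
    seed = 21
  )
  tt <- synth_eeg_dataset(cfg)[[1]]
  diff_obs <- window_mean_amplitude(erp_average(tt, "CT")["O2", ], w) -
    window_mean_amplitude(erp_average(tt, "NCT")["O2", ], w)
  # closed-form SE of a difference of two window means of white noise:
  # var = sigma^2 / (w_samples * n_trials) per condition
  n_w <- length(ermtools:::window_sample_range(w, 500, 75L, 500L))
  se <- sqrt(2 / (n_w * n_tr))
  expect_lt(abs(diff_obs - delta), 3 * se)
  # control channel carries no planted difference
  diff_ctl <- window_mean_amplitude(erp_average(tt, "CT")["O1", ], w) -
    window_mean_amplitude(erp_average(tt, "NCT")["O1", ], w)
  expect_lt(abs(diff_ctl), 3 * se)
})

test_that("window-mean error shrinks with the trial count", {
  w <- window_def("N200", "early")
  delta <- 0.8
  err_at <- function(n_tr, seed) {
    cfg <- eeg_sim_config(
      n_subjects = 1, channels = "O2", n_trials_per_condition = n_tr,
      noise_exponent = 0, noise_sd = 1, subject_amp_sd = 0,
      latency_jitter_sd_ms = 0,
      band_oscillations = data.frame(freq_hz = numeric(0),
                                     amplitude = numeric(0)),
      effect_map = list(list(channels = "O2", window_ms = c(150, 210),
                             delta = delta)),
      seed = seed
    )
    tt <- synth_eeg_dataset(cfg)[[1]]
    d <- window_mean_amplitude(erp_average(tt, "CT")["O2", ], w) -
      window_mean_amplitude(erp_average(tt, "NCT")["O2", ], w)
    d - delta
  }
  n_w <- length(ermtools:::window_sample_range(w, 500, 75L, 500L))
  for (seed in 1:5) {
    expect_lt(abs(err_at(50L, seed)), 3 * sqrt(2 / (n_w * 50)))
    expect_lt(abs(err_at(400L, seed)), 3 * sqrt(2 / (n_w * 400)))
  }
})

test_that("generation is bit-reproducible under a fixed seed", {
  cfg <- eeg_sim_config(n_subjects = 2, channels = c("O2", "F4"),
                        n_trials_per_condition = 3, seed = 33)
  a <- synth_eeg_dataset(cfg)
  b <- synth_eeg_dataset(cfg)
  expect_identical(a[[1]]$data, b[[1]]$data)
  expect_identical(a[[2]]$data, b[[2]]$data)
  cfg2 <- cfg
  cfg2$seed <- 34L
  expect_false(identical(synth_eeg_dataset(cfg2)[[1]]$data, a[[1]]$data))
})

test_that("invalid configurations are rejected", {
  expect_error(
    eeg_sim_config(channels = "O2",
                   effect_map = list(list(channels = "O2",
                                          window_ms = c(800, 900),
                                          delta = 1))),
    class = "erm_bad_input"
  )
  expect_error(
    eeg_sim_config(channels = "O2",
                   effect_map = list(list(channels = "F4",
                                          window_ms = c(100, 200),
                                          delta = 1))),
    class = "erm_bad_input"
  )
  expect_error(
    trial_tensor("s", c("a", "b"), array(0, c(2, 10, 2)), c("CT", "XX")),
    class = "erm_bad_label"
  )
  expect_error(
    trial_tensor("s", c("a", "b", "c"), array(0, c(2, 10, 2)), c("CT", "NCT")),
    class = "erm_dim_mismatch"
  )
})
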