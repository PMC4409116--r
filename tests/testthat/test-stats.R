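# Channel-wise paired statistics, electrode pooling and topographies.

test_that("paired test degenerates correctly when conditions agree", {
  amp <- matrix(rnorm(18 * 3), 18, 3, dimnames = list(NULL, c("a", "b", "c")))
  st <- condition_difference_stats(amp, amp)
  expect_true(all(st$t_value == 0))
  expect_true(all(st$p_value == 1))
  expect_true(all(st$tier == "ns"))
  expect_error(condition_difference_stats(amp[1, , drop = FALSE],
                                          amp[1, , drop = FALSE]),
               class = "erm_bad_input")
})

test_that("paired test matches stats::t.test and tiers follow p", {
  set.seed(42)
  ct <- matrix(rnorm(18 * 4, 1.5, 0.7), 18, 4)
  nct <- matrix(rnorm(18 * 4, 1.0, 0.7), 18, 4)
  colnames(ct) <- colnames(nct) <- paste0("ch", 1:4)
  st <- condition_difference_stats(ct, nct)
  for (j in 1:4) {
    ref <- stats::t.test(abs(ct[, j]), abs(nct[, j]), paired = TRUE)
    expect_equal(st$t_value[j], unname(ref$statistic), tolerance = 1e-12)
    expect_equal(st$p_value[j], ref$p.value, tolerance = 1e-12)
  }
  expect_identical(st$tier,
                   ifelse(st$p_value < 0.001, "***",
                          ifelse(st$p_value < 0.01, "**",
                                 ifelse(st$p_value < 0.05, "*", "ns"))))
})

test_that("type-I error rate is calibrated at the nominal level", {
  n_chan <- 1000L
  n_sub <- 18L
  rejections <- ermtools:::local_seed(2024L, {
    d_ct <- matrix(rnorm(n_sub * n_chan, 5, 1), n_sub, n_chan)
    d_nct <- matrix(rnorm(n_sub * n_chan, 5, 1), n_sub, n_chan)
    st <- condition_difference_stats(d_ct, d_nct)
    sum(st$p_value < 0.05)
  })
  expect_gte(rejections / n_chan, 0.035)
  expect_lte(rejections / n_chan, 0.065)
})

test_that("power at a planted unit difference matches the closed form", {
  n_sub <- 18L
  n_sim <- 500L
  hits <- ermtools:::local_seed(77L, {
    # per-subject paired difference d_i ~ N(1, 1) on positive amplitudes
    nct <- matrix(rnorm(n_sub * n_sim, 5, 0.5), n_sub, n_sim)
    ct <- nct + matrix(rnorm(n_sub * n_sim, 1, 1), n_sub, n_sim)
    st <- condition_difference_stats(ct, nct)
    sum(st$p_value < 0.05)
  })
  # closed-form paired-t power at d = 1, sd = 1: ncp = sqrt(18)
  ncp <- sqrt(n_sub)
  crit <- stats::qt(0.975, n_sub - 1)
  power <- 1 - stats::pt(crit, n_sub - 1, ncp) +
    stats::pt(-crit, n_sub - 1, ncp)
  expect_gte(hits / n_sim, 0.95)
  expect_lt(abs(hits / n_sim - power), 0.03)
})

test_that("cluster pooling averages the right channels", {
  tt <- fixture_identical_trials()
  cfg <- eemd_config(ensemble_size = 1, noise_ratio = 0, seed = 2)
  erms <- erms_approach_A(tt, cfg)
  layout <- data.frame(label = c("ch1", "ch2"), x = c(-0.5, 0.5),
                       y = c(0, 0), hemisphere = c("L", "R"),
                       cluster = c("OC", "OC"))
  pooled <- pool_electrodes(erms, layout, "OC", mode = 1:8)
  manual <- (erm_partial_reconstruction(erms, 1:8)["ch1", "CT", ] +
               erm_partial_reconstruction(erms, 1:8)["ch2", "CT", ]) / 2
  expect_equal(pooled["CT", ], manual, tolerance = 1e-12)
  # singleton cluster is the identity
  lay1 <- layout[1, ]
  p1 <- pool_electrodes(erms, lay1, "OC", mode = 1:8)
  expect_equal(p1["NCT", ],
               erm_partial_reconstruction(erms, 1:8)["ch1", "NCT", ],
               tolerance = 1e-12)
  expect_error(pool_electrodes(erms, layout, "FR"), class = "erm_bad_input")
})

test_that("pooled posterior responses lead pooled frontal responses", {
  chans <- fixture_channels()
  cfg <- eeg_sim_config(n_subjects = 2, channels = chans,
                        n_trials_per_condition = 30, seed = 5)
  ds <- synth_eeg_dataset(cfg)
  ecfg <- eemd_config(ensemble_size = 2, noise_ratio = 0.2, seed = 5)
  layout <- subset_layout(default_layout(), chans)
  lat <- sapply(c("OC", "FR"), function(cl) {
    acc <- 0
    for (tt in ds) {
      erms <- erms_approach_A(tt, ecfg)
      acc <- acc + pool_electrodes(erms, layout, cl, mode = 3:7)["CT", ]
    }
    peak_latency(acc / length(ds), c(100, 350), sign = -1)
  })
  expect_lt(lat["OC"], lat["FR"])
})

test_that("topographies carry values, masks and exact knot interpolation", {
  layout <- subset_layout(default_layout(), c("O1", "O2", "P4", "F4"))
  st <- data.frame(channel = c("O1", "O2", "P4", "F4"),
                   mean_diff = c(0.5, -0.3, 0.2, 0.0),
                   t_value = c(3.5, -2.8, 1.0, 0.0),
                   p_value = c(0.004, 0.02, 0.3, 1.0),
                   tier = c("**", "*", "ns", "ns"))
  class(st) <- c("channel_stats", "data.frame")
  topo <- topography_values(st, layout)
  expect_identical(topo$significant, c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(topo$value, st$mean_diff)
  interp <- interpolate_topography(topo, grid_n = 21L)
  for (i in seq_len(nrow(topo))) {
    gi <- which.min(abs(interp$x - topo$x[i]))
    gj <- which.min(abs(interp$y - topo$y[i]))
    if (abs(interp$x[gi] - topo$x[i]) < 1e-9 &&
        abs(interp$y[gj] - topo$y[i]) < 1e-9) {
      expect_equal(interp$value[gj, gi], topo$value[i], tolerance = 1e-9)
    }
  }
  # missing channels are an error, not a silent drop
  st2 <- st[-1, ]
  class(st2) <- c("channel_stats", "data.frame")
  expect_error(topography_values(st2, layout), class = "erm_missing_channel")
  # all-ns stats give an empty mask
  st$tier <- "ns"
  expect_false(any(topography_values(st, layout)$significant))
})
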