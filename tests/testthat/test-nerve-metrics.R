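test_that("constant nerve activity has zero modulation", {
  br <- exact_breaths(period = 0.5, n = 40)
  s <- sampled_signal(rep(2, 20000), 1000)
  m <- respiratory_modulation(s, br, min_cycles = 10)
  expect_equal(m$modulation_amplitude, 0)
  expect_equal(m$modulation_percent, 0)
  # zero-mean epoch makes percent undefined
  z <- sampled_signal(rep(0, 20000), 1000)
  expect_error(respiratory_modulation(z, br, min_cycles = 10),
               class = "resphrv_invalid_argument")
})

test_that("cardiac-vagal-like modulation depth is recovered in percent", {
  br <- generate_breath_train(resp_params(), 60, seed = 6)
  cv <- synthesize_nerve(br, "cardiac-vagal-like", tonic_level = 0.2,
                         mod_fraction = 0.5, noise_sd = 0.02, seed = 6)
  m <- respiratory_modulation(cv, br, min_cycles = 40)
  expect_equal(m$modulation_percent, 50, tolerance = 0.1)
  # multiplicative rescaling leaves the percent unchanged
  cv2 <- sampled_signal(7 * cv$value, sig_rate(cv))
  m2 <- respiratory_modulation(cv2, br, min_cycles = 40)
  expect_equal(m2$modulation_percent, m$modulation_percent, tolerance = 1e-9)
  # mod_fraction = 0 reads as no modulation within noise
  cv0 <- synthesize_nerve(br, "cardiac-vagal-like", tonic_level = 0.2,
                          mod_fraction = 0, noise_sd = 0.02, seed = 6)
  m0 <- respiratory_modulation(cv0, br, min_cycles = 40)
  expect_lt(m0$modulation_percent, 8)  # range of binned noise at this SNR
})

test_that("baseline-normalized modulation uses the reference amplitude", {
  br <- generate_breath_train(resp_params(), 60, seed = 8)
  cv <- synthesize_nerve(br, "cardiac-vagal-like", mod_fraction = 0.5,
                         seed = 8)
  m <- respiratory_modulation(cv, br, min_cycles = 40)
  mb <- respiratory_modulation(cv, br, min_cycles = 40,
                               normalize = "baseline",
                               baseline_amplitude = m$modulation_amplitude / 2)
  expect_equal(mb$modulation_percent, 200, tolerance = 1e-9)
  expect_error(respiratory_modulation(cv, br, min_cycles = 40,
                                      normalize = "baseline"),
               class = "resphrv_invalid_argument")
})

test_that("synaptic drive reads square-pulse volleys exactly", {
  v <- rep(0, 60000)
  onsets <- seq(2000, 56000, by = 6000)
  for (o in onsets) v[o:(o + 599)] <- 50
  cur <- sampled_signal(v, 1000, units = "pA")
  bursts <- tibble::tibble(onset = (onsets - 1) / 1000,
                           offset = (onsets + 599) / 1000)
  sd10 <- synaptic_drive(cur, bursts, n_bursts = 10)
  expect_equal(sd10$mean_amplitude, 50, tolerance = 0.02)
  expect_equal(nrow(tidy(sd10)), 10)
  # adding a constant holding current changes nothing
  cur2 <- sampled_signal(v - 30, 1000, units = "pA")
  sd2 <- synaptic_drive(cur2, bursts, n_bursts = 10)
  expect_equal(sd2$mean_amplitude, sd10$mean_amplitude, tolerance = 1e-9)
  # zero current reads zero
  sd0 <- synaptic_drive(sampled_signal(rep(0, 60000), 1000), bursts)
  expect_equal(sd0$mean_amplitude, 0)
  # shortfall is named
  expect_error(synaptic_drive(cur, bursts[1:4, ], n_bursts = 10),
               regexp = "shortfall", class = "resphrv_shortfall")
})

test_that("noisy inhibitory-current volleys are recovered within 10%", {
  # slice-like rhythm: slow bursting, brief inspiratory volleys
  br <- generate_breath_train(
    resp_params(base_frequency = 10, frequency_cv = 0.1,
                inspiration_fraction = 0.15), 90, seed = 12)
  cur <- synthesize_nerve(br, "inhibitory-current", burst_amplitude = 50,
                          noise_sd = 2, seed = 12)
  bursts <- tibble::tibble(onset = br$onset, offset = br$end_inspiration)
  drv <- synaptic_drive(cur, bursts, n_bursts = 10)
  expect_equal(drv$mean_amplitude, 50, tolerance = 0.1)
  expect_equal(glance(drv)$n_bursts, 10)
})

test_that("burst frequency counts onsets per minute", {
  expect_equal(burst_frequency(tibble::tibble(onset = seq(0, 59, by = 5)),
                               c(0, 60)), 12)
  expect_equal(burst_frequency(tibble::tibble(onset = numeric(0)), c(0, 60)),
               0)
  expect_error(burst_frequency(tibble::tibble(onset = 1), c(10, 10)),
               class = "resphrv_invalid_argument")
  # phrenic-like channel bursts at the respiratory base frequency
  br <- generate_breath_train(resp_params(), 61, seed = 9)
  ph <- synthesize_nerve(br, "phrenic-like", noise_sd = 0.05, seed = 9)
  bursts <- detect_bursts(ph, min_interval = 0.1)
  expect_equal(burst_frequency(bursts, c(0, 60)), 125,
               tolerance = 3 / 125)
})

test_that("a 1.47x rate increase reads as a +47% burst-frequency delta", {
  br1 <- generate_breath_train(resp_params(base_frequency = 8), 300,
                               seed = 10)
  br2 <- generate_breath_train(resp_params(base_frequency = 8 * 1.47), 300,
                               seed = 11)
  f1 <- burst_frequency(tibble::tibble(onset = br1$onset), c(0, 300))
  f2 <- burst_frequency(tibble::tibble(onset = br2$onset), c(0, 300))
  d <- epoch_delta(f1, f2, "percent")
  expect_equal(d$delta, 47, tolerance = 8 / 47)
})
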