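test_that("instantaneous HR is exact for constant beat spacing", {
  hr600 <- instantaneous_hr(tibble::tibble(time = seq(0, 2, by = 0.1)))
  expect_true(all(abs(hr600$value - 600) < 1e-9))
  expect_equal(sig_units(hr600), "bpm")
  hr60 <- instantaneous_hr(seq(0, 10, by = 1))
  expect_true(all(abs(hr60$value - 60) < 1e-9))
  expect_error(instantaneous_hr(tibble::tibble(time = 1)),
               class = "resphrv_invalid_argument")
  expect_error(instantaneous_hr(c(1, 1, 2)),
               class = "resphrv_invalid_argument")
})

test_that("alternating RR gives alternating plateaus with the right mean", {
  rr <- rep(c(0.10, 0.12), 50)
  beats <- cumsum(c(0, rr))
  hr <- instantaneous_hr(beats, out_rate = 1000)
  expect_setequal(round(unique(hr$value), 9), c(600, 500))
  expect_equal(mean(hr$value), brute_hr_time_average(beats), tolerance = 0.01)
})

test_that("triggered average of constant HR is flat and amplitude zero", {
  br <- exact_breaths(period = 0.5, n = 40)
  hr <- instantaneous_hr(seq(0, 20, by = 0.1))
  ta <- triggered_average(hr, br, min_cycles = 10)
  expect_true(all(abs(ta$mean_hr - 600) < 1e-9))
  expect_lt(resphrv_amplitude(ta), 1e-9)
  expect_lt(abs(resphrv_amplitude(ta, correct_sampling = TRUE)), 1e-8)
})

test_that("a square HR modulation is recovered bin-exactly", {
  # HR 510 over inspiration [onset, ei), 490 over expiration, exact cycles
  br <- exact_breaths(period = 0.5, n = 40, fi = 0.5)
  tt <- seq(0, 20 - 1e-3, by = 1e-3)
  phase <- (tt %% 0.5) / 0.5
  hr <- sampled_signal(ifelse(phase < 0.5, 510, 490), 1000, units = "bpm")
  ta <- triggered_average(hr, br, min_cycles = 10)
  expect_equal(max(ta$mean_hr), 510)
  expect_equal(min(ta$mean_hr), 490)
  expect_equal(resphrv_amplitude(ta), 20)
})

test_that("cycle-count policies refuse with an explicit shortfall", {
  br <- exact_breaths(n = 20)
  hr <- instantaneous_hr(seq(0, 10, by = 0.1))
  err <- tryCatch(triggered_average(hr, br, min_cycles = 40),
                  condition = function(e) e)
  expect_s3_class(err, "resphrv_shortfall")
  expect_match(conditionMessage(err), "requires 40")
  expect_match(conditionMessage(err), "19")
  # policy objects carry their own minimums
  expect_error(triggered_average(hr, br,
                                 min_cycles = condition_policy("stress")),
               class = "resphrv_shortfall")
  ta <- triggered_average(hr, br, min_cycles = condition_policy("whbp"))
  expect_gte(ta$n_cycles, 15)
})

test_that("amplitude is shift-invariant and scales linearly with HR", {
  ses <- cached("evt13", {
    sched <- epoch_schedule("a", 0, 120)
    build_session(sched, resp_params(), cardiac_params(),
                  channels = character(0), seed = 13)
  })
  hr <- instantaneous_hr(ses$beats)
  br <- ses$breaths
  ta <- triggered_average(hr, br)
  base_amp <- resphrv_amplitude(ta)
  hr_shift <- sampled_signal(hr$value + 100, sig_rate(hr), sig_t0(hr), "bpm")
  hr_scale <- sampled_signal(hr$value * 3, sig_rate(hr), sig_t0(hr), "bpm")
  expect_equal(resphrv_amplitude(triggered_average(hr_shift, br)), base_amp)
  expect_equal(resphrv_amplitude(triggered_average(hr_scale, br)),
               3 * base_amp, tolerance = 1e-9)
  # uniform time shift of both inputs leaves the average unchanged
  hr_t <- sampled_signal(hr$value, sig_rate(hr), sig_t0(hr) + 5, "bpm")
  br_t <- br
  for (col in c("onset", "end_inspiration", "end")) br_t[[col]] <- br[[col]] + 5
  expect_equal(triggered_average(hr_t, br_t)$mean_hr, ta$mean_hr)
})

test_that("sampling-corrected amplitude recovers the set modulation depth", {
  ses <- cached("evt3", {
    sched <- epoch_schedule("a", 0, 120)
    build_session(sched, resp_params(), cardiac_params(),
                  channels = character(0), seed = 3)
  })
  hr <- instantaneous_hr(ses$beats)
  ta <- triggered_average(hr, ses$breaths, min_cycles = 60)
  expect_gte(ta$n_cycles, 60)
  expect_equal(resphrv_amplitude(ta, correct_sampling = TRUE), 13.2,
               tolerance = 0.05)
  # the raw value is attenuated by beat sampling at ~4 beats per breath
  expect_lt(resphrv_amplitude(ta), 13.2)
})

test_that("raw amplitude is unbiased in the fine-beat-sampling regime", {
  # 600 bpm over 30 cpm: ~20 beats per cycle, noiseless, 200 cycles
  sched <- epoch_schedule("a", 0, 410)
  ses <- build_session(sched, resp_params(base_frequency = 30),
                       cardiac_params(base_hr = 600, hr_noise_sd = 0),
                       channels = character(0), seed = 21)
  hr <- instantaneous_hr(ses$beats)
  ta <- triggered_average(hr, ses$breaths, min_cycles = 200)
  expect_equal(resphrv_amplitude(ta), 13.2, tolerance = 0.02)
})

test_that("epoch metrics reproduce trivial rates and the ground truth", {
  br <- exact_breaths(period = 60 / 125, n = 130, fi = 0.35)
  beats <- tibble::tibble(time = seq(0, 62, by = 0.1))
  m <- epoch_metrics(beats, br, c(0, 60), policy = 40, label = "demo")
  expect_equal(m$mhr, 600)
  expect_equal(m$resp_frequency, 125)
  expect_equal(m$resphrv, 0)
  expect_equal(m$label, "demo")

  ses <- cached("evt13", {
    sched <- epoch_schedule("a", 0, 120)
    build_session(sched, resp_params(), cardiac_params(),
                  channels = character(0), seed = 13)
  })
  m2 <- epoch_metrics(ses$beats, ses$breaths, c(0, 120),
                      policy = condition_policy("freely_moving"))
  expect_equal(m2$mhr, ses$ground_truth$true_mhr, tolerance = 0.01)
  expect_equal(m2$resphrv_corrected, ses$ground_truth$true_resphrv,
               tolerance = 0.05)
  expect_equal(m2$resp_frequency, 125, tolerance = 0.05)
})

test_that("stability profile flags stationarity and sees gain steps", {
  ses <- cached("evt13", {
    sched <- epoch_schedule("a", 0, 120)
    build_session(sched, resp_params(), cardiac_params(),
                  channels = character(0), seed = 13)
  })
  sp <- stability_profile(ses$beats, ses$breaths, window = 40, step = 20,
                          policy = 40)
  expect_lt(sp$cv, 0.1)
  expect_true(sp$stable)

  # gain step mid-recording: two plateaus
  sched2 <- epoch_schedule(c("lo", "hi"), c(0, 120), c(120, 240),
                           overrides = list(NULL, list(gain = 2)))
  ses2 <- build_session(sched2, resp_params(), cardiac_params(),
                        channels = character(0), seed = 14)
  sp2 <- stability_profile(ses2$beats, ses2$breaths, window = 40, step = 40,
                           policy = 40, correct_sampling = TRUE)
  prof <- tidy(sp2)
  lo <- prof$amplitude[prof$time < 110]
  hi <- prof$amplitude[prof$time > 130]
  expect_gt(min(hi) / max(lo), 1.5)
  expect_false(sp2$stable)

  # constant HR: every window reads zero
  beats <- tibble::tibble(time = seq(0, 60, by = 0.1))
  br <- exact_breaths(period = 0.5, n = 120)
  sp3 <- stability_profile(beats, br, window = 30, step = 15, policy = 15)
  expect_true(all(tidy(sp3)$amplitude < 1e-9))

  expect_error(stability_profile(ses$beats, ses$breaths, window = 5,
                                 step = 5, policy = 40),
               class = "resphrv_invalid_argument")
})
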