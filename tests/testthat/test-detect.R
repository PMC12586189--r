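test_that("flat or empty-ish signals yield empty detections with a warning", {
  flat <- sampled_signal(rep(0, 5000), 1000)
  expect_warning(b <- detect_beats(flat), "flat")
  expect_equal(nrow(b), 0)
  expect_warning(br <- segment_breaths(flat), "no respiratory cycles")
  expect_equal(nrow(br), 0)
  expect_equal(nrow(detect_bursts(flat)), 0)
})

test_that("a single QRS is found at its true time", {
  ecg <- synthesize_ecg(tibble::tibble(time = 1.0), duration = 2)
  b <- detect_beats(ecg)
  expect_equal(nrow(b), 1)
  expect_equal(b$time, 1.0, tolerance = 1e-3)
})

test_that("refractory shorter than two samples is refused", {
  s <- sampled_signal(rnorm(100), 10)
  expect_error(detect_beats(s, refractory = 0.05),
               class = "resphrv_invalid_argument")
})

test_that("all detectors are exact on noiseless generator output", {
  # boundary events whose waveform is clipped by the recording edges are
  # excluded from matching; everything inside must be found exactly
  inner <- function(x, lo = 0.5, hi = 59.5) x[x > lo & x < hi]
  sched <- epoch_schedule("a", 0, 60)
  ses <- build_session(sched, resp_params(), cardiac_params(hr_noise_sd = 0),
                       channels = c("ecg", "pleth", "phrenic"), seed = 11,
                       channel_noise = list(ecg = 0, pleth = 0, phrenic = 0))
  b <- match_events(inner(detect_beats(ses$signals$ecg)$time),
                    inner(ses$beats$time), 0.002)
  expect_equal(b$recall, 1)
  expect_equal(b$precision, 1)

  det_br <- segment_breaths(ses$signals$pleth)
  r <- match_events(inner(det_br$end_inspiration, 1, 59),
                    inner(ses$breaths$end_inspiration, 1, 59), 0.01)
  expect_equal(r$recall, 1)
  expect_equal(r$precision, 1)

  bursts <- detect_bursts(ses$signals$phrenic)
  r2 <- match_events(inner(bursts$onset, 1, 59),
                     inner(ses$breaths$onset, 1, 59), 0.01)
  expect_equal(r2$precision, 1)
  expect_equal(r2$recall, 1)
})

test_that("beats are recovered completely with < 2 ms jitter at SNR 10", {
  br <- generate_breath_train(resp_params(), 11, seed = 7)
  cardiac <- cardiac_params(base_hr = 500, resp_mod_depth = 0,
                            hr_noise_sd = 0)
  beats <- simulate_beats_ipfm(cardiac, br, 10, seed = 7)
  ecg <- synthesize_ecg(beats, noise_sd = 0.1, seed = 7, duration = 10)
  det <- detect_beats(ecg)
  m <- match_events(det$time, beats$time, 0.002)
  expect_equal(m$recall, 1)
  expect_equal(m$precision, 1)
  expect_lt(m$jitter, 0.002)
})

test_that("breath cycles are recovered at SNR 10 within 10 ms", {
  ses <- fm_session(2)
  det <- segment_breaths(ses$signals$pleth)
  tei <- ses$breaths$end_inspiration
  dei <- det$end_inspiration
  m <- match_events(dei[dei > 1 & dei < 179], tei[tei > 1 & tei < 179], 0.01)
  expect_gte(m$recall, 0.99)
  expect_gte(m$precision, 0.99)
})

test_that("detection is equivariant to time shifts and gain changes", {
  br <- generate_breath_train(resp_params(), 11, seed = 3)
  beats <- simulate_beats_ipfm(cardiac_params(hr_noise_sd = 0), br, 10)
  ecg <- synthesize_ecg(beats, noise_sd = 0.05, seed = 1, duration = 10)
  t1 <- detect_beats(ecg)$time
  # gain: doubling the signal leaves fractional-threshold detections alone
  ecg2 <- sampled_signal(2 * ecg$value, sig_rate(ecg), units = "mV")
  expect_equal(detect_beats(ecg2)$time, t1)
  # shift by k samples
  k <- 500
  shifted <- sampled_signal(c(rep(0, k), ecg$value), sig_rate(ecg))
  t2 <- detect_beats(shifted)$time
  common <- seq_len(min(length(t1), length(t2)))
  expect_equal(t2[common], t1[common] + k / sig_rate(ecg), tolerance = 1e-6)
})

test_that("a pure sinusoid segments into cycles peaking at its maxima", {
  tt <- seq(0, 10, by = 1e-3)
  s <- sampled_signal(sin(2 * pi * 2.5 * tt), 1000)
  br <- segment_breaths(s, min_cycle = 0.2)
  expect_gte(nrow(br), 23)
  true_peaks <- 0.1 + 0.4 * (0:24)
  m <- match_events(br$end_inspiration, true_peaks, 0.005)
  expect_gte(m$recall, nrow(br) / 25)
  expect_lt(m$jitter, 0.002)
  # rolling-median baseline wobbles over a 2.5-cycle window, so amplitude is
  # only approximate here; peak timing is the contract
  expect_true(all(br$amplitude > 0.6 & br$amplitude < 1.2))
})

test_that("square bursts are delimited exactly with their peak value", {
  v <- rep(0, 20000)
  onsets <- c(2000, 6000, 10000, 14000)
  for (o in onsets) v[o:(o + 399)] <- 1
  b <- detect_bursts(sampled_signal(v, 1000))
  expect_equal(nrow(b), 4)
  expect_equal(b$onset, (onsets - 1) / 1000, tolerance = 2e-3)
  expect_equal(b$offset - b$onset, rep(0.399, 4), tolerance = 5e-3)
  expect_equal(b$peak_value, rep(1, 4), tolerance = 1e-6)
})

test_that("phrenic-like burst onsets align with inspiration at SNR 10", {
  br <- generate_breath_train(resp_params(), 61, seed = 5)
  ph <- synthesize_nerve(br, "phrenic-like", noise_sd = 0.1, seed = 5)
  bursts <- detect_bursts(ph, min_duration = 0.05, min_interval = 0.1)
  m <- match_events(bursts$onset, br$onset, 0.01)
  expect_gte(m$recall, 0.99)
  expect_lt(m$jitter, 0.01)
})
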