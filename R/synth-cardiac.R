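#' Respiratory modulation waveform of the instantaneous heart rate
#'
#' Zero-mean waveform with peak-to-trough 1 over one respiratory cycle,
#' peaking at mid-inspiration: a full-cycle raised cosine
#' `0.5 * cos(2 * pi * (phase - inspiration_fraction / 2))`. With this shape
#' the IPFM rate `base_hr + gain * depth * s(phase)` has peak-to-trough
#' exactly `gain * depth`, so the generator's depth parameter is the true
#' RespHRV amplitude of the underlying rate.
#'
#' @param phase Respiratory phase in `[0, 1)` measured from cycle onset.
#' @param inspiration_fraction Fraction of the cycle occupied by inspiration.
#' @return Numeric vector in `[-0.5, 0.5]`.
#' @export
resp_mod_waveform <- function(phase, inspiration_fraction = 0.35) {
  0.5 * cos(2 * pi * (phase - inspiration_fraction / 2))
}

# instantaneous-rate grid (bpm) for a breath train and per-sample cardiac
# params; returns list(t, m_clean, m) at sim_rate
ipfm_rate_grid <- function(breaths, duration, sim_rate,
                           base_hr, depth, gain, mhr_shift, noise_sd,
                           resp_lag = 0) {
  t <- seq(0, duration, by = 1 / sim_rate)
  tl <- t - resp_lag
  ci <- pmin(pmax(findInterval(tl, breaths$onset), 1L), nrow(breaths))
  period <- breaths$end[ci] - breaths$onset[ci]
  u <- (tl - breaths$onset[ci]) / period
  fi <- (breaths$end_inspiration[ci] - breaths$onset[ci]) / period
  s <- resp_mod_waveform(u, fi)
  m_clean <- base_hr + mhr_shift + gain * depth * s
  m <- m_clean
  if (any(noise_sd > 0)) m <- m + rnorm(length(t), 0, noise_sd)
  list(t = t, m_clean = m_clean, m = m)
}

# integrate-and-fire: a beat is emitted whenever the integral of m/60 crosses
# successive integers; zero-order-hold integration on the grid makes the
# constant-rate case exact to machine precision
ipfm_fire <- function(t, m, start_integral = 0) {
  if (any(m <= 0)) {
    abort("instantaneous rate driven to zero or below; invalid cardiac parameters.",
          class = "resphrv_invalid_params")
  }
  dt <- diff(t)
  cc <- start_integral + c(0, cumsum(m[-length(m)] * dt)) / 60
  n_max <- floor(cc[length(cc)] + 1e-9)
  if (n_max < 1L) return(numeric(0))
  n <- seq_len(n_max)
  idx <- findInterval(n, cc)
  idx <- pmin(idx, length(t) - 1L)
  beats <- t[idx] + (n - cc[idx]) * 60 / m[idx]
  pmin(pmax(beats, t[1]), t[length(t)])
}

#' Simulate heartbeats by integral pulse frequency modulation (IPFM)
#'
#' The instantaneous rate is
#' `m(t) = base_hr + mhr_shift + gain * resp_mod_depth * s(phase(t)) + noise`,
#' where `s` is [resp_mod_waveform()] evaluated on the respiratory phase of
#' the supplied breath train and the noise is white Gaussian at the
#' simulation grid rate. A beat is emitted each time the running integral of
#' `m/60` crosses a successive integer, so the inter-beat interval under a
#' constant rate `m` is exactly `60/m`.
#'
#' @param cardiac A [cardiac_params()] object.
#' @param breaths A `breath_train` covering `[0, duration]`.
#' @param duration Duration to simulate, s.
#' @param seed Optional seed.
#' @param sim_rate Integration grid rate, Hz (default 1000).
#' @return A tibble with column `time`: strictly increasing beat times, s.
#' @examples
#' br <- generate_breath_train(resp_params(120, frequency_cv = 0), 2)
#' b <- simulate_beats_ipfm(cardiac_params(600, resp_mod_depth = 0,
#'                                         hr_noise_sd = 0), br, 1)
#' b$time  # 0.1, 0.2, ..., 1.0
#' @export
simulate_beats_ipfm <- function(cardiac, breaths, duration, seed = NULL,
                                sim_rate = 1000) {
  stopifnot(inherits(cardiac, "cardiac_params"), is.data.frame(breaths))
  check_number(duration, "duration", lower = 0, strict = TRUE)
  if (max(breaths$end) < duration - 1e-9) {
    abort("breath train does not cover the requested duration.",
          class = "resphrv_invalid_argument")
  }
  maybe_seed(seed)
  g <- ipfm_rate_grid(breaths, duration, sim_rate,
                      base_hr = cardiac$base_hr,
                      depth = cardiac$resp_mod_depth, gain = cardiac$gain,
                      mhr_shift = cardiac$mhr_shift,
                      noise_sd = cardiac$hr_noise_sd,
                      resp_lag = cardiac$resp_lag)
  tibble::tibble(time = ipfm_fire(g$t, g$m))
}

# stereotyped QRS template sampled at `rate`; returns list(values, center)
qrs_template <- function(rate, amplitude = 1) {
  tt <- seq(-0.02, 0.02, by = 1 / rate)
  r <- exp(-(tt / 0.0025)^2)              # R wave
  q <- -0.25 * exp(-((tt + 0.007) / 0.003)^2)
  s <- -0.30 * exp(-((tt - 0.007) / 0.003)^2)
  list(values = amplitude * (r + q + s), center = which.min(abs(tt)))
}

#' Render a synthetic ECG from beat times
#'
#' Places one stereotyped QRS template (R wave with Q/S lobes, total width
#' 40 ms) centred at each beat time on a zero baseline, plus optional white
#' noise.
#'
#' @param beats Tibble with a `time` column (or numeric vector), s.
#' @param rate Sampling rate, Hz; at least 1000.
#' @param qrs_amplitude R-wave amplitude (signal units).
#' @param noise_sd SD of additive white Gaussian noise.
#' @param seed Optional seed.
#' @param duration Signal duration, s; defaults to last beat + 0.1 s.
#' @return A [sampled_signal()] in mV-like units.
#' @export
synthesize_ecg <- function(beats, rate = 1000, qrs_amplitude = 1,
                           noise_sd = 0, seed = NULL, duration = NULL) {
  times <- if (is.data.frame(beats)) beats$time else as.numeric(beats)
  check_number(rate, "rate", lower = 1000)
  check_number(qrs_amplitude, "qrs_amplitude")
  check_number(noise_sd, "noise_sd", lower = 0)
  maybe_seed(seed)
  duration <- duration %||% if (length(times)) max(times) + 0.1 else 1
  n <- ceiling(duration * rate) + 1L
  tpl <- qrs_template(rate, qrs_amplitude)
  if (length(times) > 1 && min(diff(times)) < length(tpl$values) / rate) {
    abort("inter-beat interval shorter than the QRS template width; templates would overlap.",
          class = "resphrv_invalid_argument")
  }
  v <- numeric(n)
  for (b in times) {
    c0 <- round(b * rate) + 1L
    i0 <- c0 - tpl$center + 1L
    i1 <- i0 + length(tpl$values) - 1L
    lo <- max(i0, 1L); hi <- min(i1, n)
    if (lo <= hi) v[lo:hi] <- v[lo:hi] + tpl$values[(lo - i0 + 1L):(hi - i0 + 1L)]
  }
  if (noise_sd > 0) v <- v + rnorm(n, 0, noise_sd)
  sampled_signal(v, rate_hz = rate, units = "mV")
}
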