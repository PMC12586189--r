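#' Instantaneous heart rate from beat times
#'
#' The instantaneous rate is `60/RR` for each inter-beat interval, held
#' piecewise-constant over that interval and sampled on a uniform grid.
#' The piecewise-constant convention matches the event-based nature of beat
#' timing: constant beat spacing yields an exactly constant rate.
#'
#' @param beats Tibble with column `time` (or numeric vector) of beat
#'   times, s; at least 2 beats.
#' @param out_rate Output sampling rate, Hz.
#' @return A [sampled_signal()] in bpm spanning `[first beat, last beat]`.
#' @examples
#' hr <- instantaneous_hr(tibble::tibble(time = seq(0, 1, by = 0.1)))
#' unique(hr$value)  # 600 bpm
#' @export
instantaneous_hr <- function(beats, out_rate = 100) {
  times <- if (is.data.frame(beats)) beats$time else as.numeric(beats)
  if (length(times) < 2L) {
    abort("at least 2 beats are required to form an instantaneous HR series.",
          class = "resphrv_invalid_argument")
  }
  if (any(diff(times) <= 0)) {
    abort("beat times must be strictly increasing.",
          class = "resphrv_invalid_argument")
  }
  check_number(out_rate, "out_rate", lower = 0, strict = TRUE)
  hr <- 60 / diff(times)
  tt <- seq(times[1], times[length(times)], by = 1 / out_rate)
  idx <- pmin(pmax(findInterval(tt, times), 1L), length(hr))
  sampled_signal(hr[idx], rate_hz = out_rate, t0 = times[1], units = "bpm")
}

# phase grid sample times for cycles delimited by trigger times `trig`
# returns a (n_cycles x n_bins) matrix of times
cycle_sample_times <- function(trig, n_bins) {
  nc <- length(trig) - 1L
  ub <- (seq_len(n_bins) - 0.5) / n_bins
  outer(trig[seq_len(nc)], rep(1, n_bins)) + outer(diff(trig), ub)
}

#' Respiratory-triggered average of heart rate
#'
#' Resamples each respiratory cycle of the HR series onto a common phase
#' grid running from one end-inspiration to the next (`n_bins` bins) and
#' averages the bins across cycles. This is the quantity from which the
#' RespHRV amplitude is read off (see [resphrv_amplitude()]).
#'
#' Refuses to average when fewer complete cycles are available than the
#' condition policy requires (40 freely moving, 15 anesthetized/WHBP, 100
#' stress), raising a `resphrv_shortfall` condition naming the shortfall.
#'
#' @param hr A [sampled_signal()] of instantaneous HR, bpm (see
#'   [instantaneous_hr()]).
#' @param breaths A `breath_train`.
#' @param n_bins Number of phase bins (default 100).
#' @param min_cycles Minimum cycles required: an integer or a
#'   [condition_policy()].
#' @param epoch Optional `c(start, end)` restricting the cycles used
#'   (half-open, s); `NULL` uses the full HR span.
#' @return An object of class `triggered_average`: fields `phase` (bin
#'   centres in cycle fraction), `mean_hr` (bpm per bin), `n_cycles`,
#'   `trigger`, `mean_hr_overall`, `mean_period_s`.
#' @export
triggered_average <- function(hr, breaths, n_bins = 100, min_cycles = 40,
                              epoch = NULL) {
  stopifnot(inherits(hr, "sampled_signal"), is.data.frame(breaths))
  check_number(n_bins, "n_bins", lower = 2)
  need <- resolve_min_cycles(min_cycles)
  span <- c(hr$time[1], hr$time[nrow(hr)])
  if (!is.null(epoch)) {
    span <- c(max(span[1], epoch[1]), min(span[2], epoch[2]))
  }
  trig <- breaths$end_inspiration
  trig <- trig[trig >= span[1] & trig <= span[2]]
  nc <- length(trig) - 1L
  if (nc < need) abort_shortfall(max(nc, 0L), need)
  tm <- cycle_sample_times(trig, n_bins)
  vals <- matrix(signal_value_at(hr, as.vector(tm)), nrow = nc)
  keep_hr <- hr$time >= trig[1] & hr$time < trig[length(trig)]
  structure(list(
    phase = (seq_len(n_bins) - 0.5) / n_bins,
    mean_hr = colMeans(vals),
    n_cycles = nc,
    trigger = "end_inspiration",
    mean_hr_overall = mean(hr$value[keep_hr]),
    mean_period_s = mean(diff(trig)),
    units = sig_units(hr)
  ), class = "triggered_average")
}

#' @export
print.triggered_average <- function(x, ...) {
  cat(sprintf("<triggered_average> %d cycles, %d bins, trigger = %s\n",
              x$n_cycles, length(x$phase), x$trigger))
  cat(sprintf("  amplitude (max - min): %.3f %s\n",
              resphrv_amplitude(x), x$units))
  invisible(x)
}

#' RespHRV amplitude from a triggered average
#'
#' The raw amplitude is `max - min` of the cycle-averaged HR: the difference
#' between maximal HR during inspiration and minimal HR during expiration.
#'
#' With few heartbeats per breath (e.g. a mouse at 532 bpm breathing at
#' 125 cpm has ~4.3), the piecewise-constant HR assigns each instant the
#' mean rate over its enclosing RR interval, which convolves the true
#' modulation with a triangle kernel of half-width `RR/period` in cycle
#' units and attenuates the raw amplitude (by `sinc^2(pi * RR/period)` for
#' the fundamental, about 17% at the rates above). Setting
#' `correct_sampling = TRUE` deconvolves that kernel in the Fourier domain,
#' keeping only harmonics the kernel transmits with gain at least
#' `min_transmission` so that noise is never amplified more than
#' `1/min_transmission`-fold. Use the corrected value when the goal is the
#' underlying modulation depth of the cardiac rate; the raw value is the
#' conventional reported RespHRV amplitude.
#'
#' @param ta A [triggered_average()].
#' @param correct_sampling Apply the finite-beat-sampling deconvolution.
#' @param min_transmission Minimum kernel transmission for a harmonic to be
#'   deconvolved rather than dropped (default 0.5).
#' @return RespHRV amplitude in bpm (non-negative scalar).
#' @export
resphrv_amplitude <- function(ta, correct_sampling = FALSE,
                              min_transmission = 0.5) {
  stopifnot(inherits(ta, "triggered_average"))
  if (!correct_sampling) return(max(ta$mean_hr) - min(ta$mean_hr))
  nb <- length(ta$mean_hr)
  w <- (60 / ta$mean_hr_overall) / ta$mean_period_s  # RR / period, cycle units
  h <- c(0, seq_len(nb - 1))
  h <- pmin(h, nb - h)                               # harmonic index per FFT bin
  att <- (sin(pi * h * w) / (pi * h * w))^2
  att[h == 0] <- 1
  Fc <- fft(ta$mean_hr - mean(ta$mean_hr)) / nb
  keep <- att >= min_transmission
  rec <- Re(fft(ifelse(keep, Fc / att, 0), inverse = TRUE))
  max(rec) - min(rec)
}

#' Per-epoch cardiorespiratory metrics
#'
#' Computes, over a half-open analysis window: the mean heart rate (time
#' average of the piecewise-constant instantaneous HR), the RespHRV
#' amplitude via respiratory-triggered averaging (both raw and
#' sampling-corrected, see [resphrv_amplitude()]), the respiratory frequency
#' (cycle onsets per minute) and the mean respiratory cycle amplitude.
#'
#' @param beats Tibble of beat times (column `time`).
#' @param breaths A `breath_train`.
#' @param epoch `c(start, end)`, seconds (half-open).
#' @param policy A [condition_policy()] or integer minimum cycle count.
#' @param n_bins Phase bins for the triggered average.
#' @param out_rate Sampling rate of the internal HR series, Hz.
#' @param label Optional epoch label for the output row.
#' @return A one-row tibble: `label`, `mhr`, `resphrv`, `resphrv_corrected`,
#'   `resp_frequency`, `resp_amplitude`, `n_cycles`.
#' @export
epoch_metrics <- function(beats, breaths, epoch,
                          policy = condition_policy("freely_moving"),
                          n_bins = 100, out_rate = 200, label = NA_character_) {
  stopifnot(length(epoch) == 2L, epoch[2] > epoch[1])
  times <- if (is.data.frame(beats)) beats$time else as.numeric(beats)
  # pad by one beat either side so the HR series covers the window edges
  lo <- max(1L, findInterval(epoch[1], times))
  hi <- min(length(times), findInterval(epoch[2], times) + 1L)
  hr <- instantaneous_hr(times[lo:hi], out_rate = out_rate)
  in_win <- hr$time >= epoch[1] & hr$time < epoch[2]
  ta <- triggered_average(hr, breaths, n_bins = n_bins, min_cycles = policy,
                          epoch = epoch)
  on_in <- breaths$onset >= epoch[1] & breaths$onset < epoch[2]
  tibble::tibble(
    label = label,
    mhr = mean(hr$value[in_win]),
    resphrv = resphrv_amplitude(ta),
    resphrv_corrected = resphrv_amplitude(ta, correct_sampling = TRUE),
    resp_frequency = sum(on_in) / (epoch[2] - epoch[1]) * 60,
    resp_amplitude = mean(breaths$amplitude[on_in]),
    n_cycles = ta$n_cycles
  )
}

#' Sliding-window stability profile of RespHRV amplitude
#'
#' Computes the RespHRV amplitude in sliding windows and flags the recording
#' stable when the coefficient of variation across windows is below
#' `cv_bound`. This windowed-CV criterion is this package's own stability
#' metric.
#'
#' @param beats Tibble of beat times.
#' @param breaths A `breath_train`.
#' @param window Window length, s; must be able to hold the policy minimum
#'   number of cycles at the observed respiratory rate.
#' @param step Step between window starts, s.
#' @param policy A [condition_policy()] or integer minimum cycle count.
#' @param cv_bound CV bound for the stability flag.
#' @param correct_sampling Passed to [resphrv_amplitude()].
#' @param n_bins Phase bins.
#' @return An object of class `stability_profile`: tibble `profile`
#'   (`time` = window centre, `amplitude`, `n_cycles`), `cv`, `stable`.
#' @export
stability_profile <- function(beats, breaths, window = 60, step = 30,
                              policy = condition_policy("freely_moving"),
                              cv_bound = 0.1, correct_sampling = FALSE,
                              n_bins = 100) {
  check_number(window, "window", lower = 0, strict = TRUE)
  check_number(step, "step", lower = 0, strict = TRUE)
  need <- resolve_min_cycles(policy)
  mean_period <- mean(breaths$end - breaths$onset)
  if (window < (need + 1) * mean_period) {
    abort(sprintf("window of %g s cannot hold the required %d cycles at the observed respiratory rate.",
                  window, need),
          class = "resphrv_invalid_argument")
  }
  times <- if (is.data.frame(beats)) beats$time else as.numeric(beats)
  t_end <- min(max(times), max(breaths$end))
  starts <- seq(max(times[1], breaths$onset[1]), t_end - window, by = step)
  rows <- purrr::map(starts, function(s0) {
    m <- tryCatch(
      epoch_metrics(tibble::tibble(time = times), breaths, c(s0, s0 + window),
                    policy = policy, n_bins = n_bins),
      resphrv_shortfall = function(e) NULL
    )
    if (is.null(m)) return(NULL)
    tibble::tibble(
      time = s0 + window / 2,
      amplitude = if (correct_sampling) m$resphrv_corrected else m$resphrv,
      n_cycles = m$n_cycles
    )
  })
  prof <- dplyr::bind_rows(rows)
  cv <- stats::sd(prof$amplitude) / mean(prof$amplitude)
  structure(list(profile = prof, cv = cv,
                 stable = is.finite(cv) && cv < cv_bound,
                 cv_bound = cv_bound),
            class = "stability_profile")
}

#' @export
print.stability_profile <- function(x, ...) {
  cat(sprintf("<stability_profile> %d windows, CV = %.3f (%s, bound %.2f)\n",
              nrow(x$profile), x$cv,
              if (x$stable) "stable" else "not stable", x$cv_bound))
  invisible(x)
}
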