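#' Respiratory modulation of an integrated nerve signal
#'
#' Applies the same cycle-triggered averaging machinery as the RespHRV
#' analysis to an integrated nerve channel: the signal is resampled onto a
#' common phase grid across respiratory cycles, bins are averaged, and the
#' modulation amplitude is `max - min` of the average. The percent
#' modulation is, by default, the amplitude relative to the epoch mean of
#' the signal (`normalize = "epoch_mean"`); `normalize = "baseline"`
#' expresses it relative to a reference modulation amplitude instead (e.g.
#' the pre-drug epoch), via `baseline_amplitude`.
#'
#' @param nerve A [sampled_signal()] (integrated nerve activity).
#' @param cycles A `breath_train` (cycles trigger on end-inspiration) or a
#'   burst tibble with an `onset` column (cycles run onset to onset).
#' @param epoch Optional `c(start, end)` window, s.
#' @param n_bins Phase bins.
#' @param min_cycles Minimum cycles, integer or [condition_policy()].
#' @param normalize `"epoch_mean"` or `"baseline"`.
#' @param baseline_amplitude Reference amplitude when
#'   `normalize = "baseline"`.
#' @return A one-row tibble: `modulation_amplitude` (signal units),
#'   `modulation_percent`, `epoch_mean`, `n_cycles`.
#' @export
respiratory_modulation <- function(nerve, cycles, epoch = NULL, n_bins = 100,
                                   min_cycles = 15,
                                   normalize = c("epoch_mean", "baseline"),
                                   baseline_amplitude = NULL) {
  stopifnot(inherits(nerve, "sampled_signal"), is.data.frame(cycles))
  normalize <- rlang::arg_match(normalize)
  need <- resolve_min_cycles(min_cycles)
  span <- c(nerve$time[1], nerve$time[nrow(nerve)])
  if (!is.null(epoch)) span <- c(max(span[1], epoch[1]), min(span[2], epoch[2]))
  trig <- if ("end_inspiration" %in% names(cycles)) {
    cycles$end_inspiration
  } else {
    cycles$onset
  }
  trig <- trig[trig >= span[1] & trig <= span[2]]
  nc <- length(trig) - 1L
  if (nc < need) abort_shortfall(max(nc, 0L), need)
  tm <- cycle_sample_times(trig, n_bins)
  vals <- matrix(signal_value_at(nerve, as.vector(tm)), nrow = nc)
  avg <- colMeans(vals)
  amp <- max(avg) - min(avg)
  in_span <- nerve$time >= span[1] & nerve$time < span[2]
  epoch_mean <- mean(nerve$value[in_span])
  pct <- switch(normalize,
    epoch_mean = {
      if (abs(epoch_mean) < 1e-12) {
        abort("epoch mean is zero: percent modulation is undefined.",
              class = "resphrv_invalid_argument")
      }
      100 * amp / epoch_mean
    },
    baseline = {
      if (is.null(baseline_amplitude)) {
        abort("`baseline_amplitude` is required when normalize = 'baseline'.",
              class = "resphrv_invalid_argument")
      }
      100 * amp / baseline_amplitude
    }
  )
  tibble::tibble(modulation_amplitude = amp, modulation_percent = pct,
                 epoch_mean = epoch_mean, n_cycles = nc)
}

#' Synaptic drive over consecutive inspiratory bursts
#'
#' Quantifies the inhibitory synaptic drive received during inspiratory
#' bursts as the maximal low-pass envelope amplitude of the current within
#' each burst, baseline-subtracted, averaged over the first `n_bursts`
#' consecutive bursts of the trace (default 10). Outward (inhibitory)
#' currents are treated as positive; use `sign = "outward_negative"` for the
#' opposite recording convention. The envelope is the trace, rectified about
#' its median, low-pass filtered at `envelope_cutoff` with a zero-phase
#' Butterworth filter; the per-burst baseline is the mean envelope in a
#' window preceding the burst onset.
#'
#' @param current A [sampled_signal()] of membrane current.
#' @param bursts Burst tibble (`onset`, `offset`), e.g. from
#'   [detect_bursts()] on a simultaneously recorded population channel.
#' @param n_bursts Number of consecutive bursts to average (default 10).
#' @param envelope_cutoff Low-pass cutoff, Hz (default 10: separates the
#'   volley envelope from spiking texture at slice time scales).
#' @param sign `"outward_positive"` or `"outward_negative"`.
#' @param baseline_window `c(before, gap)`: baseline is averaged over
#'   `[onset - before, onset - gap]`, s.
#' @return An object of class `synaptic_drive`: `per_burst` tibble
#'   (`burst`, `onset`, `amplitude`), `mean_amplitude`, `n_bursts`, `units`.
#' @export
synaptic_drive <- function(current, bursts, n_bursts = 10,
                           envelope_cutoff = 10,
                           sign = c("outward_positive", "outward_negative"),
                           baseline_window = c(0.5, 0.05)) {
  stopifnot(inherits(current, "sampled_signal"), is.data.frame(bursts))
  sign <- rlang::arg_match(sign)
  check_number(n_bursts, "n_bursts", lower = 1)
  check_number(envelope_cutoff, "envelope_cutoff", lower = 0, strict = TRUE)
  if (nrow(bursts) < n_bursts) {
    abort(sprintf("%d bursts required but only %d present in the trace (shortfall of %d).",
                  as.integer(n_bursts), nrow(bursts),
                  as.integer(n_bursts) - nrow(bursts)),
          class = "resphrv_shortfall")
  }
  rate <- sig_rate(current)
  x <- current$value
  if (sign == "outward_negative") x <- -x
  med <- median(x)
  y <- pmax(x - med, 0)
  # first-order Butterworth: monotonic step response, so square volleys are
  # not overshot by filter ringing
  bf <- signal::butter(1, min(envelope_cutoff / (rate / 2), 0.99))
  env <- as.numeric(signal::filtfilt(bf, y))
  idx_at <- function(tt) pmin(pmax(floor((tt - sig_t0(current)) * rate) + 1, 1),
                              length(env))
  use <- utils::head(dplyr::arrange(bursts, .data$onset), n_bursts)
  amps <- vapply(seq_len(nrow(use)), function(i) {
    i0 <- idx_at(use$onset[i]); i1 <- idx_at(use$offset[i])
    b0 <- idx_at(use$onset[i] - baseline_window[1])
    b1 <- idx_at(use$onset[i] - baseline_window[2])
    base <- if (b1 > b0) mean(env[b0:b1]) else 0
    max(env[i0:i1]) - base
  }, numeric(1))
  structure(list(
    per_burst = tibble::tibble(burst = seq_len(nrow(use)), onset = use$onset,
                               amplitude = amps),
    mean_amplitude = mean(amps),
    n_bursts = nrow(use),
    units = sig_units(current)
  ), class = "synaptic_drive")
}

#' @export
print.synaptic_drive <- function(x, ...) {
  cat(sprintf("<synaptic_drive> mean %.2f %s over %d bursts\n",
              x$mean_amplitude, x$units, x$n_bursts))
  invisible(x)
}

#' Burst frequency over an epoch
#'
#' @param bursts Burst tibble with an `onset` column.
#' @param epoch `c(start, end)`, s (half-open).
#' @return Bursts per minute (scalar).
#' @examples
#' burst_frequency(tibble::tibble(onset = seq(0, 59, by = 5)), c(0, 60))
#' @export
burst_frequency <- function(bursts, epoch) {
  stopifnot(length(epoch) == 2L)
  if (epoch[2] <= epoch[1]) {
    abort("epoch must have positive duration.",
          class = "resphrv_invalid_argument")
  }
  n <- sum(bursts$onset >= epoch[1] & bursts$onset < epoch[2])
  n / (epoch[2] - epoch[1]) * 60
}
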