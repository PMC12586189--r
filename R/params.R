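#' Respiratory rhythm parameters
#'
#' Parameters of the synthetic breathing rhythm. Defaults describe an awake,
#' freely moving mouse breathing at ~125 cycles per minute with moderate
#' cycle-to-cycle variability; anesthetized preparations breathe slower (set
#' `base_frequency` accordingly).
#'
#' @param base_frequency Mean respiratory frequency, cycles per minute (> 0).
#' @param frequency_cv Coefficient of variation of the cycle period (>= 0).
#' @param inspiration_fraction Fraction of the cycle occupied by inspiration,
#'   strictly between 0 and 1.
#' @param amplitude_mean Mean cycle amplitude, arbitrary units (> 0).
#' @param amplitude_cv Coefficient of variation of cycle amplitude (>= 0).
#' @return A list of class `resp_params`.
#' @examples
#' resp_params(base_frequency = 125)
#' @export
resp_params <- function(base_frequency = 125, frequency_cv = 0.1,
                        inspiration_fraction = 0.35,
                        amplitude_mean = 1, amplitude_cv = 0.1) {
  check_number(base_frequency, "base_frequency", lower = 0, strict = TRUE)
  check_number(frequency_cv, "frequency_cv", lower = 0)
  check_number(inspiration_fraction, "inspiration_fraction",
               lower = 0, upper = 1, strict = TRUE)
  check_number(amplitude_mean, "amplitude_mean", lower = 0, strict = TRUE)
  check_number(amplitude_cv, "amplitude_cv", lower = 0)
  structure(list(base_frequency = base_frequency, frequency_cv = frequency_cv,
                 inspiration_fraction = inspiration_fraction,
                 amplitude_mean = amplitude_mean, amplitude_cv = amplitude_cv),
            class = "resp_params")
}

#' Cardiac rhythm parameters
#'
#' Parameters of the IPFM heartbeat generator. `base_hr` is the mean heart
#' rate; `resp_mod_depth` is the peak-to-trough inspiratory modulation of the
#' instantaneous rate (the RespHRV depth, bpm); `gain` multiplies that depth
#' and stands for the oxytocinergic amplification of RespHRV; `mhr_shift`
#' shifts the mean rate (bpm) and is typically overridden per epoch;
#' `hr_noise_sd` is the standard deviation of white Gaussian noise added to
#' the instantaneous rate at the simulation grid rate; `resp_lag` is a fixed
#' cardio-respiratory latency in seconds (default 0).
#'
#' @param base_hr Mean heart rate, bpm (> 0). Default 532 bpm (freely moving
#'   mouse at rest).
#' @param resp_mod_depth Peak-to-trough respiratory modulation, bpm (>= 0).
#'   Default 13.2 bpm.
#' @param gain Dimensionless multiplier on `resp_mod_depth` (>= 0).
#' @param hr_noise_sd White rate noise SD, bpm (>= 0).
#' @param mhr_shift Additive shift of the mean rate, bpm.
#' @param resp_lag Fixed lag between respiration and its cardiac effect, s.
#' @return A list of class `cardiac_params`.
#' @export
cardiac_params <- function(base_hr = 532, resp_mod_depth = 13.2, gain = 1,
                           hr_noise_sd = 10, mhr_shift = 0, resp_lag = 0) {
  check_number(base_hr, "base_hr", lower = 0, strict = TRUE)
  check_number(resp_mod_depth, "resp_mod_depth", lower = 0)
  check_number(gain, "gain", lower = 0)
  check_number(hr_noise_sd, "hr_noise_sd", lower = 0)
  check_number(mhr_shift, "mhr_shift")
  check_number(resp_lag, "resp_lag")
  if (base_hr + mhr_shift - gain * resp_mod_depth / 2 <= 0) {
    abort("cardiac parameters drive the instantaneous rate to zero or below.",
          class = "resphrv_invalid_params")
  }
  structure(list(base_hr = base_hr, resp_mod_depth = resp_mod_depth,
                 gain = gain, hr_noise_sd = hr_noise_sd,
                 mhr_shift = mhr_shift, resp_lag = resp_lag),
            class = "cardiac_params")
}

#' Epoch schedule
#'
#' Named, time-ordered, non-overlapping analysis epochs with optional
#' per-epoch parameter overrides (e.g. `gain`, `mhr_shift`,
#' `base_frequency`). Epochs are half-open intervals `[start, end)` in
#' seconds from recording start.
#'
#' @param label Character vector of epoch names.
#' @param start,end Numeric vectors of epoch bounds, seconds.
#' @param overrides A list (one element per epoch) of named lists of
#'   parameter overrides, or `NULL` for none.
#' @return A tibble of class `epoch_schedule` with columns `label`, `start`,
#'   `end`, `overrides` (list-column).
#' @examples
#' epoch_schedule(c("baseline", "stim", "recovery"), c(0, 60, 120),
#'                c(60, 120, 180),
#'                overrides = list(NULL, list(gain = 1.5, mhr_shift = -35), NULL))
#' @export
epoch_schedule <- function(label, start, end, overrides = NULL) {
  if (length(label) != length(start) || length(start) != length(end)) {
    abort("`label`, `start` and `end` must have equal length.",
          class = "resphrv_invalid_argument")
  }
  if (any(end <= start)) {
    abort("each epoch must satisfy end > start.",
          class = "resphrv_invalid_argument")
  }
  if (is.unsorted(start, strictly = TRUE) ||
      any(start[-1] < end[-length(end)] - 1e-12)) {
    abort("epochs must be time-ordered and non-overlapping.",
          class = "resphrv_invalid_argument")
  }
  if (is.null(overrides)) overrides <- rep(list(NULL), length(label))
  out <- tibble::tibble(label = as.character(label),
                        start = as.numeric(start), end = as.numeric(end),
                        overrides = overrides)
  class(out) <- c("epoch_schedule", class(out))
  out
}

#' Condition policy: minimum averaged cycles per preparation
#'
#' Each experimental condition fixes the minimum number of respiratory
#' cycles that must enter a triggered average: 40 for freely moving mice,
#' 15 for anesthetized preparations and the working heart-brainstem
#' preparation (WHBP), and 100 for stress/recovery telemetry sessions.
#'
#' @param condition One of `"freely_moving"`, `"anesthetized"`, `"whbp"`,
#'   `"stress"`.
#' @param min_cycles Optional override of the policy minimum.
#' @return A list of class `condition_policy` with fields `condition`,
#'   `min_cycles`, `window_s` (default analysis window length in seconds).
#' @export
condition_policy <- function(condition = c("freely_moving", "anesthetized",
                                           "whbp", "stress"),
                             min_cycles = NULL) {
  condition <- match.arg(condition)
  defaults <- c(freely_moving = 40L, anesthetized = 15L, whbp = 15L,
                stress = 100L)
  windows <- c(freely_moving = 30, anesthetized = 30, whbp = 30, stress = 300)
  mc <- if (is.null(min_cycles)) defaults[[condition]] else as.integer(min_cycles)
  structure(list(condition = condition, min_cycles = mc,
                 window_s = windows[[condition]]),
            class = "condition_policy")
}

resolve_min_cycles <- function(x) {
  if (inherits(x, "condition_policy")) x$min_cycles else as.integer(x)
}

#' Photostimulation session protocol
#'
#' Builds the schedule and analysis windows of a 1-min photostimulation
#' session: a baseline epoch, a stimulation epoch during which the RespHRV
#' gain is raised and the mean heart rate shifted, and a recovery epoch.
#' Following the convention that stimulation effects are maximal and stable
#' in the second half of a 1-min stimulation, the analysis window of each
#' epoch is its final `window_s` seconds.
#'
#' @param baseline,stim,recovery Epoch durations, seconds.
#' @param stim_gain RespHRV gain during stimulation (default 1.5, the ratio
#'   19.5/13.2 bpm).
#' @param stim_mhr_shift Mean-HR shift during stimulation, bpm (default -35).
#' @param window_s Analysis window length, seconds (default 30).
#' @return A list of class `session_protocol`: `schedule`
#'   ([epoch_schedule()]), `windows` (tibble of label/start/end), `policy`.
#' @export
protocol_photostim <- function(baseline = 60, stim = 60, recovery = 60,
                               stim_gain = 1.5, stim_mhr_shift = -35,
                               window_s = 30) {
  sched <- epoch_schedule(
    label = c("baseline", "stim", "recovery"),
    start = c(0, baseline, baseline + stim),
    end = c(baseline, baseline + stim, baseline + stim + recovery),
    overrides = list(NULL,
                     list(gain = stim_gain, mhr_shift = stim_mhr_shift),
                     NULL)
  )
  windows <- tibble::tibble(label = sched$label,
                            start = sched$end - window_s, end = sched$end)
  structure(list(schedule = sched, windows = windows,
                 policy = condition_policy("freely_moving")),
            class = "session_protocol")
}

#' Restraint-stress session protocol
#'
#' Builds the schedule and analysis windows of a restraint-stress session:
#' a pre-stress baseline, a 10-min restraint during which RespHRV gain is
#' suppressed and mean HR elevated, and a timed recovery. Stress effects are
#' quantified in the first 5 min after the restraint; recovery is probed in
#' two 10-min bins, 25-35 min and 55-65 min post stress. The `restore`
#' argument controls when the RespHRV gain returns to baseline:
#' `"immediate"` restores it 10 min after the restraint ends (recovered by
#' the 25-35 min bin, the vehicle pattern), `"delayed"` restores it 50 min
#' after (recovered only by the 55-65 min bin).
#'
#' @param restore `"immediate"` or `"delayed"` gain restoration.
#' @param baseline Pre-stress baseline duration, s.
#' @param stress Restraint duration, s (default 600 = 10 min).
#' @param stress_gain RespHRV gain while suppressed (default 0.5).
#' @param stress_mhr_shift Mean-HR elevation during restraint, bpm.
#' @return A `session_protocol` list (schedule, windows, policy).
#' @export
protocol_stress <- function(restore = c("immediate", "delayed"),
                            baseline = 600, stress = 600,
                            stress_gain = 0.5, stress_mhr_shift = 80) {
  restore <- match.arg(restore)
  s0 <- baseline                  # restraint start
  p0 <- baseline + stress         # post-stress time origin
  restore_at <- p0 + if (restore == "immediate") 600 else 3000
  end <- p0 + 65 * 60
  sched <- epoch_schedule(
    label = c("baseline", "restraint", "post_impaired", "post_recovered"),
    start = c(0, s0, p0, restore_at),
    end = c(s0, p0, restore_at, end),
    overrides = list(
      NULL,
      list(gain = stress_gain, mhr_shift = stress_mhr_shift),
      list(gain = stress_gain, mhr_shift = stress_mhr_shift / 2),
      NULL
    )
  )
  windows <- tibble::tibble(
    label = c("baseline", "stress", "25-35", "55-65"),
    start = c(s0 - 540, p0, p0 + 25 * 60, p0 + 55 * 60),
    end = c(s0 - 60, p0 + 300, p0 + 35 * 60, p0 + 65 * 60)
  )
  structure(list(schedule = sched, windows = windows,
                 policy = condition_policy("stress")),
            class = "session_protocol")
}
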