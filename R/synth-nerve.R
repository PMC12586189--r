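#' Render a synthetic integrated nerve or current channel
#'
#' Three channel kinds keyed to the breath train:
#' \describe{
#'   \item{`"phrenic-like"`}{square-ish bursts of height `burst_amplitude`
#'     spanning inspiration (10 ms edge ramps) on a `tonic_level` baseline;
#'     emulates integrated phrenic nerve activity.}
#'   \item{`"cardiac-vagal-like"`}{tonic activity `tonic_level` with
#'     multiplicative respiratory modulation of peak-to-trough depth
#'     `mod_fraction` (fraction of the tonic level), minimal during
#'     inspiration; emulates integrated cardiac vagal branch activity.}
#'   \item{`"inhibitory-current"`}{raised-cosine volleys of outward current
#'     of peak `burst_amplitude` during inspiration on a zero baseline;
#'     emulates the inhibitory synaptic volleys received by nucleus ambiguus
#'     neurons during inspiratory bursts.}
#' }
#'
#' @param breaths A `breath_train` tibble.
#' @param kind One of `"phrenic-like"`, `"cardiac-vagal-like"`,
#'   `"inhibitory-current"`.
#' @param burst_amplitude Burst/volley peak height (signal units).
#' @param tonic_level Baseline tonic activity (signal units).
#' @param mod_fraction Respiratory modulation depth as a fraction of the
#'   tonic level, in `[0, 1]` (cardiac-vagal-like only).
#' @param rate Sampling rate, Hz.
#' @param noise_sd SD of additive white Gaussian noise.
#' @param seed Optional seed.
#' @param duration Signal duration, s; defaults to the end of the last cycle.
#' @return A [sampled_signal()].
#' @export
synthesize_nerve <- function(breaths,
                             kind = c("phrenic-like", "cardiac-vagal-like",
                                      "inhibitory-current"),
                             burst_amplitude = 1, tonic_level = 0.2,
                             mod_fraction = 0.5, rate = 1000, noise_sd = 0,
                             seed = NULL, duration = NULL) {
  stopifnot(is.data.frame(breaths))
  kind <- rlang::arg_match(kind)
  check_number(mod_fraction, "mod_fraction", lower = 0, upper = 1)
  check_number(rate, "rate", lower = 0, strict = TRUE)
  check_number(noise_sd, "noise_sd", lower = 0)
  maybe_seed(seed)
  duration <- duration %||% max(breaths$end)
  t <- seq(0, duration, by = 1 / rate)
  t <- t[t < duration + 1e-12]
  ci <- pmin(pmax(findInterval(t, breaths$onset), 1L), nrow(breaths))
  period <- breaths$end[ci] - breaths$onset[ci]
  u <- pmin(pmax((t - breaths$onset[ci]) / period, 0), 1)
  fi <- (breaths$end_inspiration[ci] - breaths$onset[ci]) / period
  v <- switch(kind,
    "phrenic-like" = {
      # trapezoid over [0, fi] in phase with 10 ms ramps (in time)
      ramp_u <- pmin(0.01 / period, fi / 4)
      inside <- u <= fi
      h <- numeric(length(t))
      h[inside] <- pmin(1, u[inside] / ramp_u[inside],
                        (fi[inside] - u[inside]) / ramp_u[inside])
      h[h < 0] <- 0
      tonic_level + burst_amplitude * h
    },
    "cardiac-vagal-like" = {
      # zero-mean peak-to-trough-1 waveform, minimal at mid-inspiration
      vmod <- -resp_mod_waveform(u, fi)
      tonic_level * (1 + mod_fraction * vmod)
    },
    "inhibitory-current" = {
      inside <- u <= fi
      h <- numeric(length(t))
      h[inside] <- 0.5 * (1 - cos(2 * pi * u[inside] / fi[inside]))
      burst_amplitude * h
    }
  )
  if (noise_sd > 0) v <- v + rnorm(length(v), 0, noise_sd)
  units <- if (kind == "inhibitory-current") "pA" else "a.u."
  sampled_signal(v, rate_hz = rate, units = units)
}
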