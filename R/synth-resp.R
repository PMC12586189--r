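#' Generate a synthetic breath train
#'
#' Draws a sequence of respiratory cycles tiling `[0, duration]`. Each cycle
#' period is drawn from a normal distribution with mean `60/base_frequency`
#' and the stated coefficient of variation (truncated at 20% of the mean to
#' keep periods positive); end-inspiration falls at
#' `onset + inspiration_fraction * period`; cycle amplitudes are drawn with
#' their own mean and CV (truncated at zero).
#'
#' @param resp A [resp_params()] object.
#' @param duration Recording duration, seconds (> 0).
#' @param seed Optional integer seed for reproducibility.
#' @return A tibble of class `breath_train` with columns `onset`,
#'   `end_inspiration`, `end`, `amplitude` (one row per cycle, contiguous
#'   and time-ordered).
#' @examples
#' br <- generate_breath_train(resp_params(120, frequency_cv = 0), 60, seed = 1)
#' nrow(br)  # exactly 120 cycles of 0.5 s
#' @export
generate_breath_train <- function(resp, duration, seed = NULL) {
  stopifnot(inherits(resp, "resp_params"))
  if (!is.numeric(duration) || length(duration) != 1L || duration <= 0) {
    abort("`duration` must be a single positive number of seconds.",
          class = "resphrv_invalid_argument")
  }
  maybe_seed(seed)
  breath_train_from_fn(function(t) resp, duration)
}

# internal generator: `param_fn(t)` returns the resp_params in force at time
# t, allowing stepwise per-epoch parameter changes
breath_train_from_fn <- function(param_fn, duration) {
  n_guess <- ceiling(duration / (60 / param_fn(0)$base_frequency) * 1.5) + 16L
  onset <- numeric(n_guess); ei <- numeric(n_guess)
  cend <- numeric(n_guess); amp <- numeric(n_guess)
  t <- 0; i <- 0L
  while (t < duration) {
    p <- param_fn(t)
    mu <- 60 / p$base_frequency
    period <- max(0.2 * mu, rnorm(1, mu, p$frequency_cv * mu))
    a <- max(0, rnorm(1, p$amplitude_mean, p$amplitude_cv * p$amplitude_mean))
    i <- i + 1L
    if (i > length(onset)) {  # grow
      onset <- c(onset, numeric(n_guess)); ei <- c(ei, numeric(n_guess))
      cend <- c(cend, numeric(n_guess)); amp <- c(amp, numeric(n_guess))
    }
    onset[i] <- t
    ei[i] <- t + p$inspiration_fraction * period
    cend[i] <- t + period
    amp[i] <- a
    t <- t + period
  }
  out <- tibble::tibble(onset = onset[seq_len(i)],
                        end_inspiration = ei[seq_len(i)],
                        end = cend[seq_len(i)], amplitude = amp[seq_len(i)])
  class(out) <- c("breath_train", class(out))
  out
}

#' Render a plethysmography-like signal from a breath train
#'
#' Each cycle is rendered as a smooth waveform rising over inspiration
#' (raised-cosine ramp) to a peak at end-inspiration, falling back to
#' baseline over an equal interval of early expiration (mirrored
#' raised-cosine), and staying at baseline for the rest of expiration ---
#' as in chamber-pressure recordings, where expiratory flow ends well
#' before the next inspiration. The peak is locally symmetric, which is
#' what makes its position estimable to sub-sample precision. Peak value =
#' cycle amplitude; inspiration is the positive deflection.
#'
#' @param breaths A `breath_train` tibble.
#' @param rate Sampling rate, Hz.
#' @param noise_sd SD of additive white Gaussian noise (signal units).
#' @param seed Optional seed.
#' @param duration Signal duration, s; defaults to the end of the last cycle.
#' @return A [sampled_signal()] in arbitrary units.
#' @export
synthesize_pleth <- function(breaths, rate = 1000, noise_sd = 0, seed = NULL,
                             duration = NULL) {
  stopifnot(is.data.frame(breaths))
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
  a <- breaths$amplitude[ci]
  fe <- pmin(fi, 1 - fi)  # early-expiratory fall, mirroring the rise
  w <- numeric(length(t))
  insp <- u <= fi
  fall <- !insp & u <= fi + fe
  w[insp] <- 0.5 * (1 - cos(pi * u[insp] / fi[insp]))
  w[fall] <- 0.5 * (1 + cos(pi * (u[fall] - fi[fall]) / fe[fall]))
  v <- a * w
  if (noise_sd > 0) v <- v + rnorm(length(v), 0, noise_sd)
  sampled_signal(v, rate_hz = rate, units = "a.u.")
}
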