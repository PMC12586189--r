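#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a triggered average
#'
#' @param x A [triggered_average()].
#' @param ... Unused.
#' @return `tidy()`: tibble with `phase` (cycle fraction from
#'   end-inspiration) and `mean_hr`; `glance()`: one row with `n_cycles`,
#'   `amplitude`, `amplitude_corrected`, `mean_hr`, `mean_period_s`,
#'   `trigger`.
#' @export
tidy.triggered_average <- function(x, ...) {
  tibble::tibble(phase = x$phase, mean_hr = x$mean_hr)
}

#' @rdname tidy.triggered_average
#' @export
glance.triggered_average <- function(x, ...) {
  tibble::tibble(n_cycles = x$n_cycles,
                 amplitude = resphrv_amplitude(x),
                 amplitude_corrected = resphrv_amplitude(x, correct_sampling = TRUE),
                 mean_hr = x$mean_hr_overall,
                 mean_period_s = x$mean_period_s,
                 trigger = x$trigger)
}

#' Tidy a Pearson correlation fit
#'
#' @param x A [pearson_regression()] fit.
#' @param ... Unused.
#' @return `tidy()`: one row per regression term (`term`, `estimate`);
#'   `glance()`: one row with `r`, `r_squared`, `slope`, `intercept`,
#'   `p_two_sided`, `n`.
#' @export
tidy.pearson_fit <- function(x, ...) {
  tibble::tibble(term = c("(Intercept)", "x"),
                 estimate = c(x$intercept, x$slope))
}

#' @rdname tidy.pearson_fit
#' @export
glance.pearson_fit <- function(x, ...) {
  tibble::tibble(r = x$r, r_squared = x$r^2, slope = x$slope,
                 intercept = x$intercept, p_two_sided = x$p_two_sided,
                 n = x$n)
}

#' Tidy a stability profile
#'
#' @param x A [stability_profile()].
#' @param ... Unused.
#' @return `tidy()`: the per-window tibble (`time`, `amplitude`,
#'   `n_cycles`); `glance()`: one row with `n_windows`, `cv`, `stable`.
#' @export
tidy.stability_profile <- function(x, ...) x$profile

#' @rdname tidy.stability_profile
#' @export
glance.stability_profile <- function(x, ...) {
  tibble::tibble(n_windows = nrow(x$profile), cv = x$cv, stable = x$stable)
}

#' Tidy a recovery result
#'
#' @param x A [recovery_kinetics()] result.
#' @param ... Unused.
#' @return `tidy()`: the per-bin tibble; `glance()`: one row with
#'   `recovery_bin`, `baseline`, `criterion_band`.
#' @export
tidy.recovery_result <- function(x, ...) x$bins

#' @rdname tidy.recovery_result
#' @export
glance.recovery_result <- function(x, ...) {
  tibble::tibble(recovery_bin = x$recovery_bin, baseline = x$baseline,
                 criterion_band = x$criterion_band)
}

#' Tidy a synaptic drive result
#'
#' @param x A [synaptic_drive()] result.
#' @param ... Unused.
#' @return `tidy()`: per-burst amplitudes; `glance()`: one row with
#'   `mean_amplitude`, `n_bursts`.
#' @export
tidy.synaptic_drive <- function(x, ...) x$per_burst

#' @rdname tidy.synaptic_drive
#' @export
glance.synaptic_drive <- function(x, ...) {
  tibble::tibble(mean_amplitude = x$mean_amplitude, n_bursts = x$n_bursts)
}
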