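#' Plot a respiratory-triggered HR average
#'
#' Mean HR per respiratory phase bin, from one end-inspiration to the next,
#' with the cycle count annotated.
#'
#' @param object A [triggered_average()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.triggered_average <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$phase, y = .data$mean_hr)) +
    ggplot2::geom_line(linewidth = 0.8, colour = "#b2182b") +
    ggplot2::labs(
      x = "respiratory phase (end-inspiration → end-inspiration)",
      y = sprintf("mean HR (%s)", object$units),
      title = sprintf("Respiratory-triggered HR average (%d cycles)",
                      object$n_cycles),
      subtitle = sprintf("RespHRV amplitude: %.2f %s",
                         resphrv_amplitude(object), object$units)
    ) +
    ggplot2::theme_minimal()
}

#' Plot a sliding-window RespHRV stability profile
#'
#' @param object A [stability_profile()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.stability_profile <- function(object, ...) {
  ggplot2::ggplot(tidy(object),
                  ggplot2::aes(x = .data$time, y = .data$amplitude)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::labs(x = "time (s)", y = "RespHRV amplitude (bpm)",
                  title = sprintf("Windowed RespHRV amplitude (CV = %.1f%%, %s)",
                                  100 * object$cv,
                                  if (object$stable) "stable" else "not stable")) +
    ggplot2::theme_minimal()
}

#' Plot a Pearson correlation with its regression line
#'
#' @param object A [pearson_regression()] fit.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.pearson_fit <- function(object, ...) {
  ggplot2::ggplot(object$data, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_point() +
    ggplot2::geom_abline(slope = object$slope, intercept = object$intercept,
                         colour = "#2166ac") +
    ggplot2::labs(title = sprintf("r = %.3f, p = %.3g (two-sided), n = %d",
                                  object$r, object$p_two_sided, object$n)) +
    ggplot2::theme_minimal()
}

#' Plot stress-recovery kinetics
#'
#' Per-bin percent deltas versus the pre-stress baseline with the recovery
#' criterion band shaded.
#'
#' @param object A [recovery_kinetics()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.recovery_result <- function(object, ...) {
  df <- tidy(object)
  df$label <- factor(df$label, levels = df$label)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$label, y = .data$delta_percent)) +
    ggplot2::annotate("rect", xmin = -Inf, xmax = Inf,
                      ymin = -object$criterion_band,
                      ymax = object$criterion_band,
                      alpha = 0.15, fill = "#4daf4a") +
    ggplot2::geom_hline(yintercept = 0, linetype = 2) +
    ggplot2::geom_col(ggplot2::aes(fill = .data$recovered), width = 0.6) +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "#4daf4a",
                                          `FALSE` = "#e41a1c"),
                               guide = "none") +
    ggplot2::labs(x = "post-stress bin", y = "Δ vs baseline (%)",
                  title = sprintf("Recovery at: %s",
                                  if (is.na(object$recovery_bin)) "none"
                                  else object$recovery_bin)) +
    ggplot2::theme_minimal()
}
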