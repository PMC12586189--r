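#' Pre/post effect of a stimulus on a single value
#'
#' Delta values in percent express the change in the post-stimulus value
#' relative to the pre-stimulus value: `100 * (post - pre) / pre`. Absolute
#' deltas are `post - pre`. Full precision is retained; use
#' [report_delta()] for report-layer integer rounding.
#'
#' @param pre,post Scalar values (pre must be nonzero for percent).
#' @param unit `"absolute"` or `"percent"` (selects the `delta` column; both
#'   are always returned when defined).
#' @return A one-row tibble of class `effect_result`: `pre`, `post`,
#'   `delta_abs`, `delta_percent`, `delta`, `unit`.
#' @examples
#' epoch_delta(269.5, 264.5, "absolute")$delta     # -5 bpm
#' epoch_delta(3.8, 5.8, "percent")$delta          # +52.63...%
#' @export
epoch_delta <- function(pre, post, unit = c("absolute", "percent")) {
  unit <- rlang::arg_match(unit)
  check_number(pre, "pre"); check_number(post, "post")
  if (unit == "percent" && pre == 0) {
    abort("percent delta undefined: `pre` is zero.",
          class = "resphrv_invalid_argument")
  }
  d_abs <- post - pre
  d_pct <- if (pre != 0) 100 * d_abs / pre else NA_real_
  out <- tibble::tibble(pre = pre, post = post, delta_abs = d_abs,
                        delta_percent = d_pct,
                        delta = if (unit == "absolute") d_abs else d_pct,
                        unit = unit)
  class(out) <- c("effect_result", class(out))
  out
}

#' Round a delta for reporting
#'
#' Report-layer convention: deltas in bpm and percent are rounded to the
#' nearest integer; the underlying tables keep full precision.
#'
#' @param x Numeric delta(s).
#' @return Integer-rounded numeric.
#' @export
report_delta <- function(x) round(x)

#' Group-level pre/post effect over subjects
#'
#' Two conventions are supported and labelled in the output:
#' `"per_subject_mean"` (default) averages each subject's own delta --- the
#' convention consistent with printed group Delta-percent panels --- while
#' `"group_mean_delta"` takes the delta of the group means. Both are
#' returned with the SEM of the per-subject deltas.
#'
#' @param data A data frame with columns `pre` and `post` (one row per
#'   subject; a `subject` column is carried through if present).
#' @param convention `"per_subject_mean"` or `"group_mean_delta"`.
#' @param unit `"percent"` or `"absolute"`.
#' @return A one-row tibble: `delta` (group effect under the chosen
#'   convention), `sem` (SEM of per-subject deltas), `n`, `convention`,
#'   `unit`, plus `pre_mean`, `post_mean`.
#' @export
group_effect <- function(data,
                         convention = c("per_subject_mean", "group_mean_delta"),
                         unit = c("percent", "absolute")) {
  convention <- rlang::arg_match(convention)
  unit <- rlang::arg_match(unit)
  if (!all(c("pre", "post") %in% names(data))) {
    abort("`data` must have `pre` and `post` columns.",
          class = "resphrv_invalid_argument")
  }
  pre <- data$pre; post <- data$post
  if (length(pre) != length(post) || anyNA(pre) || anyNA(post)) {
    abort("pre/post pairs are mismatched or incomplete.",
          class = "resphrv_invalid_argument")
  }
  if (length(pre) < 2L) {
    abort("at least 2 subjects are required for a group effect.",
          class = "resphrv_invalid_argument")
  }
  per <- if (unit == "percent") 100 * (post - pre) / pre else post - pre
  delta <- switch(convention,
    per_subject_mean = mean(per),
    group_mean_delta = if (unit == "percent") {
      100 * (mean(post) - mean(pre)) / mean(pre)
    } else {
      mean(post) - mean(pre)
    }
  )
  tibble::tibble(delta = delta, sem = sd(per) / sqrt(length(per)),
                 n = length(per), convention = convention, unit = unit,
                 pre_mean = mean(pre), post_mean = mean(post))
}

#' Pearson correlation with fitted regression line
#'
#' Product-moment correlation with a two-sided p value from the t transform
#' on `n - 2` degrees of freedom, and the least-squares line, matching the
#' "Pearson two-sided correlation analysis, simple linear regression
#' plotted" convention.
#'
#' @param data A data frame.
#' @param x,y Unquoted column names of the predictor and response.
#' @return An object of class `pearson_fit`: `r`, `slope`, `intercept`, `n`,
#'   `p_two_sided`, and the `data` used. Methods: [generics::tidy()],
#'   [generics::glance()], [ggplot2::autoplot()].
#' @examples
#' d <- data.frame(x = 1:10, y = 2 * (1:10) + 1)
#' glance(pearson_regression(d, x, y))
#' @export
pearson_regression <- function(data, x, y) {
  xv <- rlang::eval_tidy(rlang::enquo(x), data)
  yv <- rlang::eval_tidy(rlang::enquo(y), data)
  ok <- stats::complete.cases(xv, yv)
  xv <- xv[ok]; yv <- yv[ok]
  n <- length(xv)
  if (n < 3L) {
    abort("at least 3 complete pairs are required.",
          class = "resphrv_invalid_argument")
  }
  if (sd(xv) == 0 || sd(yv) == 0) {
    abort("zero variance in x or y: correlation undefined.",
          class = "resphrv_invalid_argument")
  }
  ct <- cor.test(xv, yv, method = "pearson", alternative = "two.sided")
  fit <- lm(yv ~ xv)
  structure(list(r = unname(ct$estimate), slope = unname(coef(fit)[2]),
                 intercept = unname(coef(fit)[1]), n = n,
                 p_two_sided = ct$p.value,
                 data = tibble::tibble(x = xv, y = yv)),
            class = "pearson_fit")
}

#' @export
print.pearson_fit <- function(x, ...) {
  cat(sprintf("<pearson_fit> r = %.3f, p = %.3g, n = %d; y = %.3g x + %.3g\n",
              x$r, x$p_two_sided, x$n, x$slope, x$intercept))
  invisible(x)
}

#' Stress-recovery kinetics against a pre-stress baseline
#'
#' Expresses each timed post-stress bin as a percent delta versus the
#' pre-stress baseline and finds the first bin whose delta lies within the
#' recovery criterion band (`|delta_percent| <= criterion_band`).
#'
#' @param baseline Pre-stress baseline value (scalar, nonzero).
#' @param bins A data frame with columns `label` and `value`, time-ordered.
#' @param criterion_band Recovery band, percent (default 10).
#' @return An object of class `recovery_result`: `bins` tibble (`label`,
#'   `value`, `delta_percent`, `recovered`), `recovery_bin` (label of the
#'   first recovered bin, or `NA`), `baseline`, `criterion_band`.
#' @examples
#' r <- recovery_kinetics(10, data.frame(label = c("25-35", "55-65"),
#'                                       value = c(5, 9.8)))
#' r$recovery_bin
#' @export
recovery_kinetics <- function(baseline, bins, criterion_band = 10) {
  if (missing(baseline) || is.null(baseline) || !is.finite(baseline)) {
    abort("a finite pre-stress `baseline` value is required.",
          class = "resphrv_invalid_argument")
  }
  if (baseline == 0) {
    abort("baseline of zero: percent deltas undefined.",
          class = "resphrv_invalid_argument")
  }
  if (!all(c("label", "value") %in% names(bins)) || nrow(bins) < 1L) {
    abort("`bins` must have at least one row with `label` and `value` columns.",
          class = "resphrv_invalid_argument")
  }
  check_number(criterion_band, "criterion_band", lower = 0)
  d <- 100 * (bins$value - baseline) / baseline
  rec <- abs(d) <= criterion_band
  out <- tibble::tibble(label = as.character(bins$label), value = bins$value,
                        delta_percent = d, recovered = rec)
  structure(list(bins = out,
                 recovery_bin = if (any(rec)) out$label[which(rec)[1]]
                                else NA_character_,
                 baseline = baseline, criterion_band = criterion_band),
            class = "recovery_result")
}

#' @export
print.recovery_result <- function(x, ...) {
  cat(sprintf("<recovery_result> baseline %.3g, band ±%g%%, recovery at: %s\n",
              x$baseline, x$criterion_band,
              if (is.na(x$recovery_bin)) "none" else x$recovery_bin))
  print(x$bins)
  invisible(x)
}
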