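#' Detect heartbeats from ECG or arterial pressure
#'
#' Finds local maxima exceeding a fraction of a rolling amplitude estimate
#' (trailing maximum over a 2 s window of the baseline-removed signal),
#' separated by at least a refractory interval. Works for ECG R waves and
#' for systolic blood-pressure peaks; use `polarity = "negative"` for
#' downward deflections.
#'
#' @param signal A [sampled_signal()].
#' @param threshold_fraction Fraction of the rolling amplitude a peak must
#'   exceed, in `(0, 1]`.
#' @param refractory Minimum separation between detections, s (default
#'   0.03 s, mouse-scale: supports > 1000 bpm with margin).
#' @param polarity `"positive"` or `"negative"` deflections.
#' @param amplitude_window Trailing window of the rolling amplitude
#'   estimate, s.
#' @param smoothing Width of the pre-detection moving average, s; roughly
#'   the QRS width, so it acts as a crude matched filter that stabilizes
#'   sub-sample peak interpolation against noise.
#' @return A tibble with column `time` (strictly increasing event times, s).
#'   A flat signal yields an empty tibble with a warning.
#' @export
detect_beats <- function(signal, threshold_fraction = 0.5, refractory = 0.03,
                         polarity = c("positive", "negative"),
                         amplitude_window = 2, smoothing = 0.005) {
  stopifnot(inherits(signal, "sampled_signal"))
  polarity <- rlang::arg_match(polarity)
  check_number(threshold_fraction, "threshold_fraction", lower = 0, upper = 1,
               strict = FALSE)
  if (threshold_fraction <= 0) {
    abort("`threshold_fraction` must be in (0, 1].",
          class = "resphrv_invalid_argument")
  }
  check_number(refractory, "refractory", lower = 0, strict = TRUE)
  rate <- sig_rate(signal)
  if (refractory < 2 / rate) {
    abort("sampling rate too low to honor the refractory period.",
          class = "resphrv_invalid_argument")
  }
  x <- signal$value
  if (polarity == "negative") x <- -x
  n <- length(x)
  bw <- min(n, as.integer(rate))  # 1 s baseline window
  base <- if (n > 10) rolling_median(x, bw) else rep(median(x), n)
  y <- x - base
  sw <- as.integer(smoothing * rate)
  if (sw %% 2L == 0L) sw <- sw + 1L
  if (sw >= 3L) y <- moving_average(y, sw)
  if (max(y) - min(y) <= .Machine$double.eps * 100) {
    warn("flat signal: no beats detected.")
    return(tibble::tibble(time = numeric(0)))
  }
  wn <- as.integer(amplitude_window * rate)
  amp <- pmax(slide_max_trailing(y, wn),
              rev(slide_max_trailing(rev(y), wn)))  # leading window too, so
  amp <- pmax(amp, 1e-12)                           # the edges see a beat
  is_peak <- c(FALSE, y[2:(n - 1)] > y[1:(n - 2)] &
                      y[2:(n - 1)] >= y[3:n], FALSE)
  cand <- which(is_peak & y >= threshold_fraction * amp)
  if (length(cand) == 0L) {
    warn("no peaks exceeded the detection threshold.")
    return(tibble::tibble(time = numeric(0)))
  }
  # refractory: keep the larger of two competing peaks
  ref_n <- refractory * rate
  keep <- integer(length(cand)); k <- 0L
  for (i in cand) {
    if (k > 0L && (i - keep[k]) < ref_n) {
      if (y[i] > y[keep[k]]) keep[k] <- i
    } else {
      k <- k + 1L
      keep[k] <- i
    }
  }
  keep <- keep[seq_len(k)]
  # sub-sample refinement: 3-point parabolic interpolation around each peak
  tt <- signal$time[keep]
  inner <- keep > 1L & keep < n
  ym <- y[pmax(keep - 1L, 1L)]; y0 <- y[keep]; yp <- y[pmin(keep + 1L, n)]
  den <- ym - 2 * y0 + yp
  delta <- ifelse(inner & den < 0, 0.5 * (ym - yp) / den, 0)
  delta <- pmin(pmax(delta, -0.5), 0.5)
  tibble::tibble(time = tt + delta / rate)
}

# quadratic-vertex refinement of a smooth peak: least-squares parabola over
# +/- half samples around index i; returns fractional offset in samples
refine_peak_quad <- function(y, i, half) {
  lo <- max(1L, i - half); hi <- min(length(y), i + half)
  u <- (lo:hi) - i
  v <- y[lo:hi]
  X <- cbind(1, u, u^2)
  cf <- tryCatch(qr.coef(qr(X), v), error = function(e) c(NA, NA, NA))
  if (anyNA(cf) || cf[3] >= 0) return(0)
  off <- -cf[2] / (2 * cf[3])
  if (!is.finite(off) || abs(off) > half) 0 else off
}

#' Segment respiratory cycles from a plethysmography signal
#'
#' Smooths the signal, removes a 1 s rolling-median baseline, and marks
#' cycle onsets at upward zero crossings. End-inspiration is the intra-cycle
#' maximum of the baseline-removed signal (inspiration = positive
#' deflection; set `invert = TRUE` for the opposite convention) and the
#' cycle amplitude is that peak height. Cycles shorter than `min_cycle` are
#' merged with their successor.
#'
#' @param signal A [sampled_signal()].
#' @param smoothing Moving-average width, s.
#' @param min_cycle Minimum plausible cycle duration, s; must exceed two
#'   sample intervals.
#' @param invert Flip the signal before segmenting.
#' @param refine_window Half-width of the quadratic peak-refinement window,
#'   s; small enough that the waveform is locally symmetric about its peak.
#' @return A `breath_train` tibble (columns `onset`, `end_inspiration`,
#'   `end`, `amplitude`). No detectable cycles yields an empty train with a
#'   warning.
#' @export
segment_breaths <- function(signal, smoothing = 0.02, min_cycle = 0.15,
                            invert = FALSE, refine_window = 0.06) {
  stopifnot(inherits(signal, "sampled_signal"))
  rate <- sig_rate(signal)
  check_number(min_cycle, "min_cycle", lower = 2 / rate, strict = TRUE)
  x <- signal$value
  if (invert) x <- -x
  n <- length(x)
  empty <- function() {
    warn("no respiratory cycles found.")
    out <- tibble::tibble(onset = numeric(0), end_inspiration = numeric(0),
                          end = numeric(0), amplitude = numeric(0))
    class(out) <- c("breath_train", class(out))
    out
  }
  if (max(x) - min(x) <= .Machine$double.eps * 100) return(empty())
  sm <- moving_average(x, max(1L, as.integer(smoothing * rate)))
  base <- rolling_median(sm, min(n, as.integer(rate)))
  y <- sm - base
  # end-inspiratory peaks: local maxima above a fraction of the rolling
  # amplitude, at least min_cycle apart (larger peak wins)
  amp_roll <- pmax(slide_max_trailing(y, min(n, as.integer(3 * rate))), 1e-12)
  is_peak <- c(FALSE, y[2:(n - 1)] > y[1:(n - 2)] &
                      y[2:(n - 1)] >= y[3:n], FALSE)
  cand <- which(is_peak & y >= 0.3 * amp_roll)
  if (length(cand) < 2L) return(empty())
  min_n <- min_cycle * rate
  peaks <- integer(length(cand)); k <- 0L
  for (i in cand) {
    if (k > 0L && (i - peaks[k]) < min_n) {
      if (y[i] > y[peaks[k]]) peaks[k] <- i
    } else {
      k <- k + 1L
      peaks[k] <- i
    }
  }
  peaks <- peaks[seq_len(k)]
  # cycle onset: last upward zero crossing before each peak
  up <- which(y[-n] < 0 & y[-1] >= 0) + 1L
  if (length(up) == 0L) return(empty())
  cross_of <- findInterval(peaks, up)
  ok <- cross_of >= 1L
  peaks <- peaks[ok]; cross_of <- cross_of[ok]
  # peaks sharing one crossing belong to one cycle: keep the larger
  if (length(peaks) == 0L) return(empty())
  best <- tapply(seq_along(peaks), cross_of,
                 function(ii) ii[which.max(y[peaks[ii]])])
  peaks <- peaks[sort(as.integer(best))]
  onset_i <- up[findInterval(peaks, up)]
  if (length(peaks) < 2L) return(empty())
  # refine each end-inspiratory peak by a least-squares parabola on the
  # smoothed signal; unbiased when the peak is locally symmetric, and the
  # wide window averages the noise down to sub-sample precision
  half <- max(3L, as.integer(refine_window * rate))
  peak_t <- signal$time[peaks] +
    vapply(peaks, function(i) refine_peak_quad(sm, i, half), numeric(1)) / rate
  out <- tibble::tibble(
    onset = signal$time[onset_i[-length(onset_i)]],
    end_inspiration = peak_t[-length(peak_t)],
    end = signal$time[onset_i[-1]],
    amplitude = pmax(y[peaks[-length(peaks)]], 0)
  )
  class(out) <- c("breath_train", class(out))
  out
}

#' Detect bursts on an integrated nerve or current trace
#'
#' Marks contiguous regions where the signal exceeds a rolling-median
#' baseline by `threshold_sd` robust standard deviations (MAD of the
#' baseline residual), lasting at least `min_duration`; regions separated by
#' gaps shorter than `min_interval` are merged. The per-burst peak is the
#' baseline-subtracted maximum.
#'
#' @param signal A [sampled_signal()].
#' @param threshold_sd Threshold in baseline-SD units (> 0).
#' @param min_duration Minimum burst duration, s.
#' @param min_interval Gaps shorter than this are merged, s.
#' @param baseline_window Rolling-median window, s; must be more than twice
#'   the longest burst so the median stays on the baseline.
#' @return A tibble with columns `onset`, `offset`, `peak_value` (ordered,
#'   non-overlapping).
#' @export
detect_bursts <- function(signal, threshold_sd = 3, min_duration = 0.05,
                          min_interval = 0.05, baseline_window = 1) {
  stopifnot(inherits(signal, "sampled_signal"))
  check_number(threshold_sd, "threshold_sd", lower = 0, strict = TRUE)
  check_number(min_duration, "min_duration", lower = 0, strict = TRUE)
  check_number(min_interval, "min_interval", lower = 0)
  rate <- sig_rate(signal)
  x <- signal$value
  n <- length(x)
  base <- rolling_median(x, min(n, as.integer(baseline_window * rate)))
  resid <- x - base
  sigma <- mad(resid)
  above <- resid > threshold_sd * sigma
  if (!any(above)) {
    return(tibble::tibble(onset = numeric(0), offset = numeric(0),
                          peak_value = numeric(0)))
  }
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  on_i <- starts[r$values]
  off_i <- ends[r$values]
  # merge gaps < min_interval
  if (length(on_i) > 1L) {
    gap <- (on_i[-1] - off_i[-length(off_i)]) / rate
    grp <- cumsum(c(1L, gap >= min_interval))
    on_i <- tapply(on_i, grp, min)
    off_i <- tapply(off_i, grp, max)
  }
  dur <- (off_i - on_i + 1L) / rate
  sel <- dur >= min_duration
  on_i <- on_i[sel]; off_i <- off_i[sel]
  peaks <- mapply(function(a, b) max(resid[a:b]), on_i, off_i)
  tibble::tibble(onset = signal$time[on_i], offset = signal$time[off_i],
                 peak_value = as.numeric(peaks))
}
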