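#' Uniformly sampled signal
#'
#' A `sampled_signal` is a tibble with columns `time` (seconds) and `value`,
#' plus metadata attributes: sampling rate (Hz), start time `t0` (s) and
#' units. It is the container for every raw channel handled by the package
#' (ECG, blood/perfusion pressure, whole-body plethysmography, integrated
#' nerve activity, patch-clamp current).
#'
#' @param values Numeric vector of samples (finite, length >= 1).
#' @param rate_hz Sampling rate in Hz (> 0).
#' @param t0 Time of the first sample, seconds.
#' @param units Unit label, e.g. `"mV"`, `"bpm"`, `"a.u."`.
#' @return A tibble of class `sampled_signal` with columns `time`, `value`.
#' @examples
#' s <- sampled_signal(sin(2 * pi * 2 * (0:999) / 1000), rate_hz = 1000)
#' sig_rate(s)
#' @export
sampled_signal <- function(values, rate_hz, t0 = 0, units = "a.u.") {
  if (!is.numeric(values) || length(values) < 1L) {
    abort("`values` must be a non-empty numeric vector.",
          class = "resphrv_invalid_argument")
  }
  if (any(!is.finite(values))) {
    abort("`values` must be finite.", class = "resphrv_invalid_argument")
  }
  check_number(rate_hz, "rate_hz", lower = 0, strict = TRUE)
  check_number(t0, "t0")
  out <- tibble::tibble(
    time = t0 + (seq_along(values) - 1) / rate_hz,
    value = as.numeric(values)
  )
  attr(out, "rate_hz") <- rate_hz
  attr(out, "t0") <- t0
  attr(out, "units") <- units
  class(out) <- c("sampled_signal", class(out))
  out
}

#' Signal metadata accessors
#'
#' @param x A [sampled_signal()].
#' @return `sig_rate()` the sampling rate in Hz, `sig_t0()` the start time in
#'   seconds, `sig_units()` the unit label, `sig_duration()` the covered
#'   duration in seconds.
#' @export
sig_rate <- function(x) attr(x, "rate_hz")

#' @rdname sig_rate
#' @export
sig_t0 <- function(x) attr(x, "t0")

#' @rdname sig_rate
#' @export
sig_units <- function(x) attr(x, "units")

#' @rdname sig_rate
#' @export
sig_duration <- function(x) nrow(x) / sig_rate(x)

#' @export
print.sampled_signal <- function(x, ...) {
  cat(sprintf("<sampled_signal> %d samples @ %g Hz, t0 = %g s, units = %s\n",
              nrow(x), sig_rate(x), sig_t0(x), sig_units(x)))
  NextMethod()
}

# value of the signal at arbitrary times (sample-and-hold on the grid)
signal_value_at <- function(x, times) {
  idx <- floor((times - sig_t0(x)) * sig_rate(x)) + 1
  idx <- pmin(pmax(idx, 1L), nrow(x))
  x$value[idx]
}

#' Restrict a signal to a half-open time window
#'
#' @param x A [sampled_signal()].
#' @param start,end Window bounds in seconds; samples with
#'   `start <= time < end` are kept.
#' @return A [sampled_signal()] covering the window.
#' @export
signal_window <- function(x, start, end) {
  check_number(start, "start"); check_number(end, "end")
  if (end <= start) abort("`end` must exceed `start`.",
                          class = "resphrv_invalid_argument")
  keep <- x$time >= start & x$time < end
  if (!any(keep)) abort("window contains no samples.",
                        class = "resphrv_invalid_argument")
  sampled_signal(x$value[keep], sig_rate(x), t0 = x$time[which(keep)[1]],
                 units = sig_units(x))
}

#' Read or write a sampled signal as delimited text
#'
#' The on-disk format is plain text: comment header lines `# rate_hz=...`,
#' `# units=...`, `# t0=...`, followed by one sample value per line. The
#' round trip is lossless at the written precision.
#'
#' @param path File path.
#' @param signal A [sampled_signal()].
#' @param digits Significant digits written (default 17: full double
#'   precision, bit-exact round trip).
#' @return `read_signal()` returns a [sampled_signal()]; `write_signal()`
#'   returns `path` invisibly.
#' @export
read_signal <- function(path) {
  lines <- readLines(path, n = 50L)
  hdr_idx <- grep("^#", lines)
  if (length(hdr_idx) == 0L || any(diff(hdr_idx) != 1L) || hdr_idx[1] != 1L) {
    abort(sprintf("malformed signal file '%s': header '#' lines must lead the file (line %d).",
                  path, if (length(hdr_idx)) hdr_idx[1] else 1L),
          class = "resphrv_parse_error")
  }
  hdr <- lines[hdr_idx]
  get_field <- function(key, required = TRUE) {
    m <- grep(sprintf("^#\\s*%s\\s*=", key), hdr)
    if (length(m) == 0L) {
      if (required) {
        abort(sprintf("malformed signal file '%s': missing '%s' header (searched lines 1-%d).",
                      path, key, length(hdr)),
              class = "resphrv_parse_error")
      }
      return(NA_character_)
    }
    sub(sprintf("^#\\s*%s\\s*=\\s*", key), "", hdr[m[1]])
  }
  rate <- suppressWarnings(as.numeric(get_field("rate_hz")))
  if (!is.finite(rate)) {
    abort(sprintf("malformed signal file '%s': non-numeric rate_hz header.", path),
          class = "resphrv_parse_error")
  }
  t0 <- suppressWarnings(as.numeric(get_field("t0", required = FALSE)))
  units <- get_field("units", required = FALSE)
  vals <- scan(path, what = double(), comment.char = "#", quiet = TRUE)
  sampled_signal(vals, rate_hz = rate,
                 t0 = if (is.finite(t0)) t0 else 0,
                 units = if (is.na(units)) "a.u." else units)
}

#' @rdname read_signal
#' @export
write_signal <- function(signal, path, digits = 17) {
  stopifnot(inherits(signal, "sampled_signal"))
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(c(
    sprintf("# rate_hz=%.10g", sig_rate(signal)),
    sprintf("# units=%s", sig_units(signal)),
    sprintf("# t0=%.10g", sig_t0(signal)),
    sprintf("%.*g", digits, signal$value)
  ), con)
  invisible(path)
}

#' Read or write event times as two-column delimited text
#'
#' Events (heartbeats, burst onsets) are written as tab-separated
#' `time_s<TAB>mark` rows with a header line.
#'
#' @param events A tibble with a `time` column (and optionally `mark`).
#' @param path File path.
#' @return `read_events()` returns a tibble with columns `time`, `mark`.
#' @export
write_events <- function(events, path) {
  df <- tibble::tibble(time_s = events$time,
                       mark = if ("mark" %in% names(events)) events$mark
                              else rep("", nrow(events)))
  readr::write_tsv(df, path)
  invisible(path)
}

#' @rdname write_events
#' @export
read_events <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE)
  if (!"time_s" %in% names(df)) {
    abort(sprintf("malformed events file '%s': missing time_s column.", path),
          class = "resphrv_parse_error")
  }
  tibble::tibble(time = as.numeric(df$time_s),
                 mark = if ("mark" %in% names(df)) as.character(df$mark)
                        else "")
}
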