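# shared fixtures, built in code and cached per test run
.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# stationary freely-moving mouse session (ECG + pleth rendered)
fm_session <- function(seed) {
  cached(paste0("fm", seed), {
    sched <- epoch_schedule("baseline", 0, 180)
    build_session(sched, resp_params(), cardiac_params(), seed = seed)
  })
}

# exact breath train: constant period, onset 0
exact_breaths <- function(period = 0.5, n = 120, fi = 0.5, amplitude = 1) {
  onsets <- (seq_len(n) - 1) * period
  out <- tibble::tibble(onset = onsets,
                        end_inspiration = onsets + fi * period,
                        end = onsets + period,
                        amplitude = amplitude)
  class(out) <- c("breath_train", class(out))
  out
}

# match detected events to ground truth within a tolerance
match_events <- function(detected, truth, tol) {
  if (length(truth) == 0 || length(detected) == 0) {
    return(list(recall = 0, precision = 0, jitter = NA_real_))
  }
  i <- pmin(pmax(findInterval(truth, detected), 1L), length(detected))
  j <- pmin(i + 1L, length(detected))
  nearest <- pmin(abs(truth - detected[i]), abs(truth - detected[j]))
  i2 <- pmin(pmax(findInterval(detected, truth), 1L), length(truth))
  j2 <- pmin(i2 + 1L, length(truth))
  nearest2 <- pmin(abs(detected - truth[i2]), abs(detected - truth[j2]))
  list(recall = mean(nearest <= tol),
       precision = mean(nearest2 <= tol),
       jitter = if (any(nearest <= tol)) max(nearest[nearest <= tol])
                else NA_real_)
}

# fresh scratch directory under the session tempdir
withr_local_tempdir <- function() {
  d <- tempfile("resphrv-test-")
  dir.create(d)
  d
}

# independent brute-force Pearson r via the covariance formula
brute_pearson_r <- function(x, y) {
  n <- length(x)
  sxy <- sum((x - mean(x)) * (y - mean(y))) / (n - 1)
  sxy / (sqrt(sum((x - mean(x))^2) / (n - 1)) *
         sqrt(sum((y - mean(y))^2) / (n - 1)))
}

# independent continuous time-average of piecewise-constant HR
brute_hr_time_average <- function(beat_times) {
  rr <- diff(beat_times)
  sum((60 / rr) * rr) / sum(rr)
}
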