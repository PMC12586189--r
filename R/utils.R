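#' @importFrom rlang abort warn %||% .data
#' @importFrom stats rnorm runmed sd median mad fft cor.test lm coef setNames
#' @importFrom utils head tail
NULL

# trailing sliding maximum over a window of `w` samples (including the current
# one); O(n) two-pass block algorithm.
slide_max_trailing <- function(x, w) {
  n <- length(x)
  w <- as.integer(w)
  if (w <= 1L || n == 0L) return(x)
  if (w >= n) return(cummax(x))
  nblk <- ceiling(n / w)
  pad <- nblk * w - n
  xp <- c(x, rep(-Inf, pad))
  m <- matrix(xp, nrow = w)
  left <- apply(m, 2, cummax)                       # prefix max within block
  right <- apply(m[w:1, , drop = FALSE], 2, cummax)[w:1, , drop = FALSE]
  left <- as.vector(left)[seq_len(n)]
  right <- as.vector(right)
  i <- seq_len(n)
  j <- i - w + 1L
  out <- left
  ok <- j >= 1L
  out[ok] <- pmax(left[ok], right[j[ok]])
  out
}

# centred rolling median; width in samples, forced odd
rolling_median <- function(x, width) {
  k <- as.integer(width)
  if (k %% 2L == 0L) k <- k + 1L
  if (k >= length(x)) return(rep(median(x), length(x)))
  if (k <= 1L) return(x)
  as.numeric(runmed(x, k, endrule = "median"))
}

# centred moving average via cumulative sums
moving_average <- function(x, width) {
  w <- as.integer(width)
  if (w <= 1L) return(x)
  n <- length(x)
  cs <- cumsum(c(0, x))
  half <- w %/% 2L
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + half, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

check_number <- function(x, name, lower = -Inf, upper = Inf, strict = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort(sprintf("`%s` must be a single finite number.", name),
          class = "resphrv_invalid_argument")
  }
  bad <- if (strict) (x <= lower || x >= upper) else (x < lower || x > upper)
  if (bad) {
    abort(sprintf("`%s` = %g is outside the allowed range %s%g, %g%s.",
                  name, x, if (strict) "(" else "[", lower, upper,
                  if (strict) ")" else "]"),
          class = "resphrv_invalid_argument")
  }
  invisible(x)
}

maybe_seed <- function(seed) {
  if (!is.null(seed)) {
    check_number(seed, "seed")
    set.seed(as.integer(seed))
  }
  invisible(NULL)
}

# shortfall refusal used by cycle-count policies
abort_shortfall <- function(found, needed, what = "respiratory cycles") {
  abort(
    sprintf("Refusing to average: %d %s available but the policy requires %d (shortfall of %d).",
            found, what, needed, needed - found),
    class = "resphrv_shortfall", found = found, needed = needed
  )
}
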