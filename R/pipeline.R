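#' Run the full cardiorespiratory analysis pipeline
#'
#' Binds the stages together: obtain a session (simulate a protocol or read
#' channel files), extract heartbeats and respiratory cycles from the raw
#' channels, compute per-window cardiorespiratory metrics under the
#' condition policy, and tabulate pre/post effects. Every policy decision
#' (windows, cycle counts, conventions) is logged, and the run is
#' deterministic for a fixed seed.
#'
#' The configuration is a list (or path to a YAML file) with fields:
#' \describe{
#'   \item{`seed`}{integer seed.}
#'   \item{`condition`}{one of the [condition_policy()] names.}
#'   \item{`simulate`}{list: `protocol` (`"photostim"` or `"stress"`),
#'     optional `args` for the protocol, optional `resp`/`cardiac` parameter
#'     overrides, optional `channels`.}
#'   \item{`signals`}{alternative to `simulate`: named file paths (`ecg`
#'     and/or `pressure`, `pleth`) written by [write_signal()].}
#'   \item{`windows`}{required with `signals`: list of
#'     `{label, start, end}` analysis windows (protocols supply their own).}
#'   \item{`effects`}{list of `{pre, post}` window-label pairs.}
#' }
#'
#' @param config A list or YAML file path.
#' @return A list of class `resphrv_pipeline`: `metrics` (one row per
#'   window), `effects` (one row per metric and window pair), `beats`,
#'   `breaths`, `log`, `config_hash`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  log <- character(0)
  note <- function(...) log <<- c(log, sprintf(...))
  seed <- config$seed %||% 1L
  policy <- condition_policy(config$condition %||% "freely_moving")
  note("condition policy: %s (min %d cycles)", policy$condition,
       policy$min_cycles)
  hash <- rlang::hash(config)

  ground_truth <- NULL
  if (!is.null(config$simulate)) {
    sim <- config$simulate
    proto <- switch(sim$protocol %||% "photostim",
      photostim = do.call(protocol_photostim, sim$args %||% list()),
      stress = do.call(protocol_stress, sim$args %||% list()),
      abort(sprintf("unknown protocol '%s'.", sim$protocol),
            class = "resphrv_invalid_argument")
    )
    resp <- do.call(resp_params, sim$resp %||% list())
    cardiac <- do.call(cardiac_params, sim$cardiac %||% list())
    channels <- sim$channels %||% c("ecg", "pleth")
    ses <- build_session(proto$schedule, resp, cardiac,
                         channels = channels, seed = seed)
    ground_truth <- ses$ground_truth
    signals <- ses$signals
    windows <- proto$windows
    note("simulated '%s' protocol, seed %d", sim$protocol %||% "photostim",
         as.integer(seed))
  } else if (!is.null(config$signals)) {
    signals <- lapply(config$signals, read_signal)
    if (is.null(config$windows)) {
      abort("`windows` must be supplied with `signals`.",
            class = "resphrv_invalid_argument")
    }
    windows <- dplyr::bind_rows(lapply(config$windows, tibble::as_tibble))
    note("read %d channel file(s)", length(signals))
  } else {
    abort("config needs either `simulate` or `signals`.",
          class = "resphrv_invalid_argument")
  }

  beat_src <- intersect(c("ecg", "pressure"), names(signals))[1]
  if (is.na(beat_src)) {
    abort("no heartbeat channel ('ecg' or 'pressure') available.",
          class = "resphrv_invalid_argument")
  }
  beats <- detect_beats(signals[[beat_src]])
  note("beats: %d detected from '%s'", nrow(beats), beat_src)
  if (!"pleth" %in% names(signals)) {
    abort("no 'pleth' channel available for breath segmentation.",
          class = "resphrv_invalid_argument")
  }
  breaths <- segment_breaths(signals[["pleth"]])
  note("breaths: %d cycles segmented", nrow(breaths))

  metrics <- purrr::map_dfr(seq_len(nrow(windows)), function(i) {
    m <- tryCatch(
      epoch_metrics(beats, breaths, c(windows$start[i], windows$end[i]),
                    policy = policy, label = windows$label[i]),
      resphrv_shortfall = function(e) {
        abort(sprintf("stage epoch_metrics (window '%s'): %s",
                      windows$label[i], conditionMessage(e)),
              class = "resphrv_shortfall")
      }
    )
    note("window '%s' [%g, %g): %d cycles averaged", windows$label[i],
         windows$start[i], windows$end[i], m$n_cycles)
    m
  })

  pairs <- config$effects %||% list(list(pre = windows$label[1],
                                         post = windows$label[2]))
  effects <- purrr::map_dfr(pairs, function(p) {
    pre_row <- metrics[metrics$label == p$pre, ]
    post_row <- metrics[metrics$label == p$post, ]
    if (nrow(pre_row) != 1L || nrow(post_row) != 1L) {
      abort(sprintf("stage effects: unknown window label in pair %s -> %s.",
                    p$pre, p$post),
            class = "resphrv_invalid_argument")
    }
    purrr::map_dfr(c("mhr", "resphrv", "resphrv_corrected",
                     "resp_frequency", "resp_amplitude"), function(metric) {
      d <- epoch_delta(pre_row[[metric]], post_row[[metric]], "absolute")
      tibble::tibble(pre_window = p$pre, post_window = p$post,
                     metric = metric, pre = d$pre, post = d$post,
                     delta_abs = d$delta_abs,
                     delta_percent = d$delta_percent)
    })
  })
  note("effects: %d window pair(s), per-window values (group conventions apply across subjects)",
       length(pairs))

  structure(list(metrics = metrics, effects = effects, beats = beats,
                 breaths = breaths, ground_truth = ground_truth, log = log,
                 config_hash = hash, seed = seed),
            class = "resphrv_pipeline")
}

#' @export
print.resphrv_pipeline <- function(x, ...) {
  cat(sprintf("<resphrv_pipeline> config %s\n", x$config_hash))
  print(x$metrics)
  invisible(x)
}
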