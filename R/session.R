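resp_fields <- c("base_frequency", "frequency_cv", "inspiration_fraction",
                 "amplitude_mean", "amplitude_cv")
cardiac_fields <- c("base_hr", "resp_mod_depth", "gain", "hr_noise_sd",
                    "mhr_shift", "resp_lag")

merge_params <- function(base, overrides, fields) {
  out <- unclass(base)
  for (nm in intersect(names(overrides), fields)) out[[nm]] <- overrides[[nm]]
  class(out) <- class(base)
  out
}

#' Build a full synthetic cardiorespiratory session with ground truth
#'
#' Generates a breath train and an IPFM heartbeat train over an epoch
#' schedule, applying per-epoch parameter overrides stepwise (no ramps), and
#' optionally renders raw channels. The returned ground truth records, per
#' epoch, the true mean heart rate (time average of the noiseless
#' instantaneous rate) and the true RespHRV depth
#' (`gain * resp_mod_depth` in force during the epoch).
#'
#' @param schedule An [epoch_schedule()]; overrides may name any
#'   [resp_params()] or [cardiac_params()] field.
#' @param resp Baseline [resp_params()].
#' @param cardiac Baseline [cardiac_params()].
#' @param channels Character vector of channels to render, from
#'   `"ecg"`, `"pleth"`, `"phrenic"`, `"cardiac_vagal"`,
#'   `"inhibitory_current"`; use `character(0)` for an event-level session.
#' @param seed Integer seed; the whole session is reproducible from it.
#' @param rate Rendered channel sampling rate, Hz.
#' @param sim_rate IPFM integration grid rate, Hz.
#' @param channel_noise Named list of per-channel noise SDs.
#' @return A list of class `cardio_session`: `beats` (tibble of beat times),
#'   `breaths` (`breath_train`), `signals` (named list of
#'   [sampled_signal()]), `ground_truth` (per-epoch tibble), `schedule`,
#'   `seed`, `resp`, `cardiac`.
#' @examples
#' pr <- protocol_photostim()
#' ses <- build_session(pr$schedule, resp_params(), cardiac_params(),
#'                      channels = character(0), seed = 1)
#' ses$ground_truth
#' @export
build_session <- function(schedule, resp = resp_params(),
                          cardiac = cardiac_params(),
                          channels = c("ecg", "pleth"), seed = 1,
                          rate = 1000, sim_rate = 1000,
                          channel_noise = list(ecg = 0.1, pleth = 0.1,
                                               phrenic = 0.05,
                                               cardiac_vagal = 0.02,
                                               inhibitory_current = 2)) {
  stopifnot(inherits(schedule, "epoch_schedule"))
  known <- c(resp_fields, cardiac_fields)
  for (ov in schedule$overrides) {
    bad <- setdiff(names(ov), known)
    if (length(bad)) {
      abort(sprintf("unknown parameter override(s): %s",
                    paste(bad, collapse = ", ")),
            class = "resphrv_invalid_argument")
    }
  }
  if (length(channels)) {
    channels <- match.arg(channels, c("ecg", "pleth", "phrenic",
                                      "cardiac_vagal", "inhibitory_current"),
                          several.ok = TRUE)
  }
  maybe_seed(seed)
  duration <- max(schedule$end)
  ne <- nrow(schedule)
  epoch_at <- function(t) {
    i <- findInterval(t, schedule$start)
    i[i < 1L] <- 1L
    i
  }
  resp_by_epoch <- lapply(seq_len(ne), function(i)
    merge_params(resp, schedule$overrides[[i]], resp_fields))
  card_by_epoch <- lapply(seq_len(ne), function(i)
    merge_params(cardiac, schedule$overrides[[i]], cardiac_fields))

  breaths <- breath_train_from_fn(function(t) resp_by_epoch[[epoch_at(t)]],
                                  duration)

  t <- seq(0, duration, by = 1 / sim_rate)
  ei_t <- epoch_at(t)
  fld <- function(f) vapply(card_by_epoch, function(p) p[[f]], numeric(1))[ei_t]
  g <- ipfm_rate_grid(breaths, duration, sim_rate,
                      base_hr = fld("base_hr"), depth = fld("resp_mod_depth"),
                      gain = fld("gain"), mhr_shift = fld("mhr_shift"),
                      noise_sd = fld("hr_noise_sd"),
                      resp_lag = cardiac$resp_lag)
  beats <- tibble::tibble(time = ipfm_fire(g$t, g$m))

  gt <- tibble::tibble(
    label = schedule$label, start = schedule$start, end = schedule$end,
    true_mhr = vapply(seq_len(ne), function(i) {
      keep <- t >= schedule$start[i] & t < schedule$end[i]
      mean(g$m_clean[keep])
    }, numeric(1)),
    true_resphrv = vapply(seq_len(ne), function(i)
      card_by_epoch[[i]]$gain * card_by_epoch[[i]]$resp_mod_depth, numeric(1)),
    gain = vapply(card_by_epoch, function(p) p$gain, numeric(1)),
    resp_frequency = vapply(resp_by_epoch, function(p) p$base_frequency,
                            numeric(1))
  )

  signals <- list()
  for (ch in channels) {
    signals[[ch]] <- switch(ch,
      ecg = synthesize_ecg(beats, rate = rate,
                           noise_sd = channel_noise$ecg %||% 0,
                           duration = duration),
      pleth = synthesize_pleth(breaths, rate = rate,
                               noise_sd = channel_noise$pleth %||% 0,
                               duration = duration),
      phrenic = synthesize_nerve(breaths, "phrenic-like", rate = rate,
                                 noise_sd = channel_noise$phrenic %||% 0,
                                 duration = duration),
      cardiac_vagal = synthesize_nerve(breaths, "cardiac-vagal-like",
                                       rate = rate,
                                       noise_sd = channel_noise$cardiac_vagal %||% 0,
                                       duration = duration),
      inhibitory_current = synthesize_nerve(breaths, "inhibitory-current",
                                            burst_amplitude = 50,
                                            rate = rate,
                                            noise_sd = channel_noise$inhibitory_current %||% 0,
                                            duration = duration)
    )
  }

  structure(list(beats = beats, breaths = breaths, signals = signals,
                 ground_truth = gt, schedule = schedule, seed = seed,
                 resp = resp, cardiac = cardiac, rate = rate),
            class = "cardio_session")
}

#' @export
print.cardio_session <- function(x, ...) {
  cat(sprintf("<cardio_session> %.1f s, %d beats, %d breaths, channels: %s\n",
              max(x$schedule$end), nrow(x$beats), nrow(x$breaths),
              if (length(x$signals)) paste(names(x$signals), collapse = ", ")
              else "(events only)"))
  print(x$ground_truth)
  invisible(x)
}

#' Write or read a session directory of delimited text files
#'
#' One text file per rendered channel (see [write_signal()]), plus
#' `beats.tsv`, `breaths.tsv`, `ground_truth.tsv` and a `session.yaml`
#' holding the schedule and seed.
#'
#' @param session A `cardio_session`.
#' @param dir Directory to create/read.
#' @return `write_session()` returns `dir` invisibly; `read_session()`
#'   returns a `cardio_session`-like list.
#' @export
write_session <- function(session, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (ch in names(session$signals)) {
    write_signal(session$signals[[ch]], file.path(dir, paste0(ch, ".txt")))
  }
  write_events(session$beats, file.path(dir, "beats.tsv"))
  readr::write_tsv(session$breaths, file.path(dir, "breaths.tsv"))
  readr::write_tsv(session$ground_truth, file.path(dir, "ground_truth.tsv"))
  sched <- session$schedule
  yaml::write_yaml(list(
    seed = session$seed, rate = session$rate,
    epochs = lapply(seq_len(nrow(sched)), function(i) list(
      label = sched$label[i], start = sched$start[i], end = sched$end[i],
      overrides = sched$overrides[[i]]
    ))
  ), file.path(dir, "session.yaml"))
  invisible(dir)
}

#' @rdname write_session
#' @export
read_session <- function(dir) {
  cfg <- yaml::read_yaml(file.path(dir, "session.yaml"))
  sched <- epoch_schedule(
    label = vapply(cfg$epochs, `[[`, character(1), "label"),
    start = vapply(cfg$epochs, `[[`, numeric(1), "start"),
    end = vapply(cfg$epochs, `[[`, numeric(1), "end"),
    overrides = lapply(cfg$epochs, `[[`, "overrides")
  )
  sig_files <- setdiff(list.files(dir, pattern = "\\.txt$"), character(0))
  signals <- lapply(file.path(dir, sig_files), read_signal)
  names(signals) <- sub("\\.txt$", "", sig_files)
  breaths <- readr::read_tsv(file.path(dir, "breaths.tsv"),
                             show_col_types = FALSE)
  class(breaths) <- c("breath_train", class(breaths))
  structure(list(
    beats = read_events(file.path(dir, "beats.tsv"))["time"],
    breaths = breaths,
    signals = signals,
    ground_truth = readr::read_tsv(file.path(dir, "ground_truth.tsv"),
                                   show_col_types = FALSE),
    schedule = sched, seed = cfg$seed, rate = cfg$rate
  ), class = "cardio_session")
}
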