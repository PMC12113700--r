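# Behavior-aligned trace extraction and artifact rejection.
#
# Candidate windows are non-overlapping `trace_len` windows tiled from each
# episode onset, ordered by start time across the session; the first
# `max_traces` candidates surviving QC are kept.  QC applies the two
# exclusion rules: voltage saturation (>= `sat_run` consecutive raw samples
# at the rail, checked first) and abrupt excursions (any filtered sample
# further than 10 session SDs from the session mean, with the SD taken over
# the whole filtered session channel so a fully saturated trace cannot mask
# itself).

#' Candidate trace windows for one behavior
#'
#' Pure schedule arithmetic: each episode of the behavior contributes
#' `floor(length / trace_len)` windows tiled from its onset.
#'
#' @param episodes data.frame `behavior`, `onset_s`, `offset_s`.
#' @param behavior behavior label.
#' @param trace_len window length in seconds (default 5).
#' @return data.frame `start_s`, `end_s` ordered by start time.
#' @export
extract_trace_windows <- function(episodes, behavior, trace_len = 5) {
  sel <- episodes[episodes$behavior == behavior, , drop = FALSE]
  starts <- numeric(0)
  for (i in seq_len(nrow(sel))) {
    k <- floor((sel$offset_s[i] - sel$onset_s[i]) / trace_len + 1e-9)
    if (k >= 1) {
      starts <- c(starts, sel$onset_s[i] + (seq_len(k) - 1) * trace_len)
    }
  }
  starts <- sort(starts)
  data.frame(start_s = starts, end_s = starts + trace_len)
}

#' Artifact QC status of one trace
#'
#' Saturation is checked first on the raw samples: a run of at least
#' `sat_run` consecutive samples equal to the rail (or, when the rail is
#' unknown, equal to the channel's maximum absolute value).  Otherwise the
#' trace is excluded as an excursion if any filtered sample deviates more
#' than `n_sd` session SDs from the session mean.
#'
#' @param filtered filtered trace samples.
#' @param session_sd SD of the full filtered session channel (> 0).
#' @param raw raw trace samples (defaults to `filtered`).
#' @param rail known saturation level in microvolts, or `NA`.
#' @param channel_absmax maximum absolute raw value over the session
#'   channel; used for the rail-unknown saturation rule.
#' @param session_mean mean of the filtered session channel (default 0).
#' @param n_sd excursion threshold in session SDs (default 10).
#' @param sat_run run length defining saturation (default 5 samples).
#' @return `"ok"`, `"excluded_saturation"` or `"excluded_excursion"`.
#' @export
flag_artifacts <- function(filtered, session_sd, raw = filtered, rail = NA,
                           channel_absmax = NA, session_mean = 0,
                           n_sd = 10, sat_run = 5) {
  stopifnot(session_sd > 0)
  level <- if (!is.na(rail) && is.finite(rail)) rail else channel_absmax
  if (!is.na(level) && max_clip_run_cpp(raw, level) >= sat_run) {
    return("excluded_saturation")
  }
  if (any(abs(filtered - session_mean) > n_sd * session_sd)) {
    return("excluded_excursion")
  }
  "ok"
}

# Filter every channel of a session with the analysis settings.
filter_session <- function(session, config) {
  fs <- session$fs
  pad <- min(length(session$channels[[1]]) - 1, as.integer(round(fs)))
  bp <- butter_bandpass_sos(config$bp_low, config$bp_high, fs,
                            config$bp_order)
  nc <- notch_cascade_sos(fs, base = config$notch_base,
                          max_freq = config$bp_high, q = config$notch_q)
  sos <- rbind(bp, nc)
  lapply(session$channels, function(x) filtfilt_sos(sos, x, pad = pad))
}

#' Extract QC-passed behavior traces from a session
#'
#' Shared candidate windows (tiled from episode onsets) are evaluated per
#' channel in time order; the first `max_traces` survivors per channel are
#' returned.  A warning is raised when a channel cannot supply
#' `max_traces`.
#'
#' @param session a `recording_session`.
#' @param behavior behavior label (must be a known annotation).
#' @param trace_len trace length in seconds (default 5).
#' @param max_traces traces to keep per channel (default 5).
#' @param config an `analysis_config` (filter settings); defaults match
#'   the session's sampling rate only at full scale, so pass the matching
#'   config for reduced-rate sessions.
#' @param filtered optional precomputed `filter_session` output (saves
#'   refiltering when extracting several behaviors).
#' @param qc apply artifact rejection (default TRUE).
#' @return list of traces; each trace is a list with `rat_id`, `group`,
#'   `week`, `structure`, `behavior`, `start_s`, `end_s`, `samples`
#'   (filtered), `qc`.  Attribute `n_excluded` counts rejected candidates.
#' @export
extract_traces <- function(session, behavior, trace_len = 5, max_traces = 5,
                           config = analysis_config(), filtered = NULL,
                           qc = TRUE) {
  known <- union(BEHAVIORS, unique(session$episodes$behavior))
  if (!behavior %in% known) {
    stop("unknown behavior: ", behavior, call. = FALSE)
  }
  if (is.null(filtered)) filtered <- filter_session(session, config)
  fs <- session$fs
  wins <- extract_trace_windows(session$episodes, behavior, trace_len)
  nw <- as.integer(round(trace_len * fs))
  out <- list()
  n_excluded <- 0L
  for (st in names(session$channels)) {
    fch <- filtered[[st]]
    rch <- session$channels[[st]]
    mu <- mean(fch)
    sdv <- stats::sd(fch)
    absmax <- if (length(rch)) max(abs(rch)) else NA_real_
    kept <- 0L
    for (i in seq_len(nrow(wins))) {
      if (kept >= max_traces) break
      i0 <- as.integer(round(wins$start_s[i] * fs)) + 1L
      i1 <- i0 + nw - 1L
      if (i1 > length(fch)) next
      fl <- fch[i0:i1]
      status <- if (qc && sdv > 0) {
        flag_artifacts(fl, session_sd = sdv, raw = rch[i0:i1],
                       rail = session$rail, channel_absmax = absmax,
                       session_mean = mu)
      } else "ok"
      if (status != "ok") {
        n_excluded <- n_excluded + 1L
        next
      }
      kept <- kept + 1L
      out[[length(out) + 1L]] <- list(
        rat_id = session$rat_id, group = session$group,
        week = session$week, structure = st, behavior = behavior,
        start_s = wins$start_s[i], end_s = wins$end_s[i],
        samples = fl, qc = status)
    }
    if (kept < max_traces) {
      warning(sprintf("%s %s W%d %s: only %d/%d traces available",
                      session$rat_id, st, session$week, behavior, kept,
                      max_traces), call. = FALSE)
    }
  }
  attr(out, "n_excluded") <- n_excluded
  out
}
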