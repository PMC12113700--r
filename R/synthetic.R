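# Seeded synthetic cohort generator.
#
# The generator emulates the statistical structure the analysis assumes:
# power-law (1/f^alpha) extracellular background whose 300-500 Hz band
# dominates the 300-3000 Hz range, five annotated behaviors on an
# alternating-renewal schedule, multiplicative group x week x behavior gains
# on the 300-500 Hz component (cerebellar hyperactivity in early weeks of
# the lesioned group), episode-duration effects (hypokinesia: longer
# resting, shorter grooming/rearing/sniffing in week 1), duration-coupled
# band power (negative for grooming, positive for sniffing), 60 Hz mains
# with harmonics, and saturation/excursion artifacts.

BEHAVIORS <- c("resting", "grooming", "locomotion", "rearing", "sniffing")
STRUCTURES <- c("CrusII", "IO", "DN")
GROUPS <- c("control", "experimental")

# Deterministic sub-seed scheme: fold a string key into a master seed by
# repeated multiply-add modulo 2^31 - 1.  Stated so any session is
# independently reproducible from (design$seed, rat_id, week).
seed_hash <- function(seed, key) {
  h <- (as.double(seed) %% 2147483647) + 1
  for (ch in utf8ToInt(key)) h <- (h * 69069 + ch) %% 2147483647
  as.integer(h)
}

# Smallest 5-smooth integer >= n: mixed-radix FFTs are fast only for small
# prime factors, and session lengths are arbitrary, so generation FFTs run
# at the padded size and the result is truncated.
next_fast_n <- function(n) {
  n <- as.integer(n)
  repeat {
    m <- n
    for (p in c(2L, 3L, 5L)) while (m %% p == 0L) m <- m %/% p
    if (m == 1L) return(n)
    n <- n + 1L
  }
}

gwb_array <- function(weeks, fill = 1) {
  array(fill, dim = c(2, weeks, length(BEHAVIORS)),
        dimnames = list(GROUPS, paste0("W", seq_len(weeks)), BEHAVIORS))
}

#' Cohort design: the stated world of the synthetic study
#'
#' Defaults encode the study design (two groups of 12 rats, 4 weekly
#' sessions of 500-800 s at 10 kHz, five behaviors, three structures) and
#' the injected effect structure: a 1.8x gain on 300-500 Hz power during
#' grooming, locomotion, rearing and sniffing in weeks 1-2 of the
#' experimental group; longer resting and shorter grooming/rearing/sniffing
#' episodes in experimental week 1; and per-second log-power coupling of
#' -0.05 for grooming and +0.05 for sniffing.
#'
#' `scale = "desk"` is a reduced-rate profile (2 kHz, 100-140 s sessions,
#' frequency axis scaled by 0.1, episode lengths scaled by 1/5) with the
#' same effect structure, used for simulation-heavy calibration so that
#' every rank-level property of the full design is preserved at a fraction
#' of the compute.
#'
#' @param scale `"full"` (default) or `"desk"`.
#' @param seed master seed; all sessions derive sub-seeds from it.
#' @param ... overrides for any design field.
#' @return an object of class `cohort_design`.
#' @export
cohort_design <- function(scale = c("full", "desk"), seed = 20250101, ...) {
  scale <- match.arg(scale)
  weeks <- 4
  d <- list(
    scale = scale,
    n_control = 12, n_experimental = 12, weeks = weeks,
    fs = 10000, session_range = c(500, 800),
    behaviors = BEHAVIORS, structures = STRUCTURES,
    spectral_exponent = 3.2, base_power = 1,
    total_band = c(300, 3000), band = c(300, 500), low_flatten = 100,
    band_gain = gwb_array(weeks),
    episode_meanlog = gwb_array(weeks, log(8)),
    episode_sdlog = gwb_array(weeks, 0.2),
    episode_rate = gwb_array(weeks, 0.6),
    duration_coupling = c(resting = 0, grooming = -0.3, locomotion = 0,
                          rearing = 0, sniffing = 0.45),
    coupling_center = 8, # s; typical episode length the coupling is centered on
    crossfade_s = 0.05,
    mains_amp = 0.5, mains_base = 60,
    artifact_rate = 2, rail = 100,
    rat_sd = 0.15,
    seed = as.integer(seed)
  )
  if (scale == "desk") {
    d$fs <- 2000
    d$session_range <- c(90, 110)
    d$total_band <- c(30, 300)
    d$band <- c(30, 50)
    d$low_flatten <- 10
    d$episode_meanlog <- gwb_array(weeks, log(8 / 5))
    d$episode_rate <- gwb_array(weeks, 3)
    # episode lengths shrink 5-fold, so the per-second coupling slope must
    # grow 5-fold to inject the same per-episode log-power spread
    d$duration_coupling <- d$duration_coupling * 5
    d$coupling_center <- 8 / 5
  }
  # injected effects (identical at both scales)
  hyper <- c("grooming", "locomotion", "rearing", "sniffing")
  d$band_gain["experimental", c("W1", "W2"), hyper] <- 1.8
  d$episode_meanlog["experimental", "W1", "resting"] <-
    d$episode_meanlog["experimental", "W1", "resting"] + log(1.6)
  hypo <- c("grooming", "rearing", "sniffing")
  d$episode_meanlog["experimental", "W1", hypo] <-
    d$episode_meanlog["experimental", "W1", hypo] + log(0.6)

  over <- list(...)
  for (nm in names(over)) {
    if (!nm %in% names(d)) stop("unknown design field: ", nm, call. = FALSE)
    d[nm] <- over[nm]
  }
  validate_design(d)
  structure(d, class = "cohort_design")
}

validate_design <- function(d) {
  stopifnot(d$n_control >= 0, d$n_experimental >= 0, d$weeks >= 1,
            d$fs > 0, d$spectral_exponent >= 0, d$base_power > 0,
            all(d$band_gain > 0), all(d$episode_rate > 0),
            d$artifact_rate >= 0, d$rat_sd >= 0)
  if (!identical(sort(d$behaviors), sort(BEHAVIORS))) {
    stop("behaviors must be exactly the five analysis labels",
         call. = FALSE)
  }
  invisible(d)
}

#' @export
print.cohort_design <- function(x, ...) {
  cat(sprintf(paste0(
    "<cohort_design> %s scale: %d + %d rats x %d weeks, fs = %g Hz,\n",
    "  sessions %g-%g s, alpha = %g, band %g-%g Hz of %g-%g Hz, seed %d\n"),
    x$scale, x$n_control, x$n_experimental, x$weeks, x$fs,
    x$session_range[1], x$session_range[2], x$spectral_exponent,
    x$band[1], x$band[2], x$total_band[1], x$total_band[2], x$seed))
  invisible(x)
}

#' Seeded power-law background noise
#'
#' Gaussian noise spectrally shaped in the frequency domain by
#' `|f|^(-alpha/2)` amplitude scaling (DC excluded), with the shaping
#' flattened below `low_flatten` Hz so that session-scale signals keep a
#' physiological amplitude.  The expected total power inside `band` equals
#' `total_power`.
#'
#' @param n_samples number of samples (>= 2).
#' @param fs sampling rate in Hz.
#' @param alpha spectral exponent (>= 0).
#' @param total_power expected power (microvolts squared) in `band`.
#' @param seed RNG seed; same seed gives a bit-identical signal.
#' @param band frequency range over which `total_power` is defined.
#' @param low_flatten flatten the shaping below this frequency (Hz).
#' @return zero-mean numeric signal of length `n_samples`.
#' @export
generate_powerlaw_noise <- function(n_samples, fs, alpha, total_power,
                                    seed = 1, band = c(300, 3000),
                                    low_flatten = 100) {
  if (n_samples < 2) stop("n_samples must be >= 2", call. = FALSE)
  if (total_power <= 0) stop("total_power must be > 0", call. = FALSE)
  if (alpha < 0) stop("alpha must be >= 0", call. = FALSE)
  n <- as.integer(n_samples)
  m <- next_fast_n(n)
  with_seed(seed, {
    xf <- stats::fft(stats::rnorm(m))
    f <- c(seq(0, floor(m / 2)), seq(-(ceiling(m / 2) - 1), -1)) * fs / m
    amp <- pmax(abs(f), low_flatten)^(-alpha / 2)
    amp[1] <- 0
    # scale so the expected two-sided power in `band` is total_power:
    # Var(x) contribution of bin k is amp_k^2 / m for unit white noise
    inband <- abs(f) >= band[1] & abs(f) <= band[2]
    pb <- sum(amp[inband]^2) / m
    amp <- amp * sqrt(total_power / pb)
    x <- Re(stats::fft(xf * amp, inverse = TRUE)) / m
    x <- x[seq_len(n)] # truncation of a stationary signal keeps its PSD
    x - mean(x)
  })
}

#' Alternating-renewal behavior schedule
#'
#' Episodes are generated sequentially: exponential gaps at the summed
#' episode rate, behavior drawn proportional to its rate, log-normal
#' episode length, truncated at the session end.  Episodes never overlap.
#'
#' @param duration session length in seconds (> 0).
#' @param params list with named-per-behavior numeric vectors `meanlog`,
#'   `sdlog` (log-normal episode length) and `rate` (episodes per second of
#'   gap time).
#' @param seed RNG seed.
#' @return data.frame with columns `behavior`, `onset_s`, `offset_s`.
#' @export
schedule_behaviors <- function(duration, params, seed = 1) {
  if (duration <= 0) stop("duration must be > 0", call. = FALSE)
  rate <- params$rate
  if (any(rate <= 0) || any(params$sdlog <= 0)) {
    stop("rates and length spreads must be > 0", call. = FALSE)
  }
  behaviors <- names(rate)
  with_seed(seed, {
    t <- 0
    beh <- character(0); on <- numeric(0); off <- numeric(0)
    total_rate <- sum(rate)
    repeat {
      t <- t + stats::rexp(1, total_rate)
      if (t >= duration) break
      b <- sample(behaviors, 1, prob = rate)
      len <- stats::rlnorm(1, params$meanlog[[b]], params$sdlog[[b]])
      end <- min(t + len, duration)
      if (end > t) {
        beh <- c(beh, b); on <- c(on, t); off <- c(off, end)
      }
      t <- end
      if (t >= duration) break
    }
    data.frame(behavior = beh, onset_s = on, offset_s = off)
  })
}

schedule_params <- function(design, group, week) {
  wk <- paste0("W", week)
  list(
    meanlog = stats::setNames(design$episode_meanlog[group, wk, ],
                              design$behaviors),
    sdlog = stats::setNames(design$episode_sdlog[group, wk, ],
                            design$behaviors),
    rate = stats::setNames(design$episode_rate[group, wk, ],
                           design$behaviors)
  )
}

# Per-rat multiplicative band-power intercept, shared across weeks (the
# repeated-measures structure the Friedman analysis relies on).
rat_intercept <- function(design, rat_id) {
  if (design$rat_sd == 0) return(1)
  exp(with_seed(seed_hash(design$seed, paste0("rat:", rat_id)),
                stats::rnorm(1, 0, design$rat_sd)))
}

# Mains interference: base frequency plus harmonics with 1/k amplitude
# roll-off, synthesized through one inverse FFT (random phases).
mains_signal <- function(n, fs, amp, base = 60, seed = 1) {
  if (amp <= 0) return(numeric(n))
  ks <- seq_len(floor((fs / 2 - 1e-9) / base))
  if (length(ks) == 0) return(numeric(n))
  m <- next_fast_n(n)
  with_seed(seed, {
    spec <- complex(m)
    for (k in ks) {
      b <- round(k * base * m / fs)
      if (b < 1 || b > floor((m - 1) / 2)) next
      a <- amp / k
      ph <- stats::runif(1, 0, 2 * pi)
      spec[b + 1] <- spec[b + 1] + a * m / 2 * exp(1i * ph)
      spec[m - b + 1] <- Conj(spec[b + 1])
    }
    (Re(stats::fft(spec, inverse = TRUE)) / m)[seq_len(n)]
  })
}

#' Generate one annotated recording session
#'
#' The three structures share one behavior schedule; each channel is an
#' independent power-law background whose in-band (default 300-500 Hz)
#' component is rescaled inside each behavior episode by
#' `gain[group, week, behavior] * exp(coupling[behavior] * episode_length)`
#' times the rat's power intercept, with a 50 ms linear cross-fade at
#' episode edges.  Mains and artifacts are injected last; injected
#' artifacts are returned in `$artifacts` for downstream bookkeeping.
#'
#' @param design a `cohort_design`.
#' @param rat_id rat identifier (e.g. `"E03"`); determines the shared
#'   per-rat intercept.
#' @param group `"control"` or `"experimental"`.
#' @param week integer week, `1..design$weeks`.
#' @param seed session seed; defaults to a stated hash of
#'   `(design$seed, rat_id, week)`.
#' @return an object of class `recording_session`.
#' @export
generate_session <- function(design, rat_id, group, week, seed = NULL) {
  stopifnot(inherits(design, "cohort_design"))
  if (!group %in% GROUPS) stop("unknown group: ", group, call. = FALSE)
  if (!week %in% seq_len(design$weeks)) {
    stop("unknown week: ", week, call. = FALSE)
  }
  if (is.null(seed)) {
    seed <- seed_hash(design$seed, paste0(rat_id, ":W", week))
  }
  duration <- with_seed(seed, stats::runif(1, design$session_range[1],
                                           design$session_range[2]))
  episodes <- schedule_behaviors(duration,
                                 schedule_params(design, group, week),
                                 seed = seed_hash(seed, "schedule"))
  n <- as.integer(round(duration * design$fs))
  eta <- rat_intercept(design, rat_id)
  wk <- paste0("W", week)

  split_sos <- NULL
  channels <- list()
  artifacts <- data.frame(structure = character(0), type = character(0),
                          start_s = numeric(0), end_s = numeric(0))
  for (st in design$structures) {
    ch_seed <- seed_hash(seed, paste0("ch:", st))
    x <- generate_powerlaw_noise(n, design$fs, design$spectral_exponent,
                                 design$base_power, seed = ch_seed,
                                 band = design$total_band,
                                 low_flatten = design$low_flatten)
    # per-episode power factors on the in-band component; the coupling is
    # centered on the typical episode length so a zero-coupling episode of
    # typical length keeps unit gain and long episodes stay bounded
    fac <- design$band_gain[group, wk, episodes$behavior] *
      exp(design$duration_coupling[episodes$behavior] *
            (episodes$offset_s - episodes$onset_s -
               design$coupling_center)) * eta
    if (nrow(episodes) > 0 && any(abs(fac - 1) > 1e-12)) {
      if (is.null(split_sos)) {
        split_sos <- butter_bandpass_sos(design$band[1], design$band[2],
                                         design$fs, 4)
      }
      comp <- filtfilt_sos(split_sos, x, pad = min(n - 1, design$fs))
      w <- amplitude_envelope(n, design$fs, episodes, sqrt(fac),
                              design$crossfade_s)
      x <- (x - comp) + comp * w
    }
    x <- x + mains_signal(n, design$fs, design$mains_amp,
                          design$mains_base,
                          seed = seed_hash(ch_seed, "mains"))
    inj <- inject_artifacts(x, design, seed = seed_hash(ch_seed, "artifacts"))
    x <- inj$x
    if (nrow(inj$events) > 0) {
      inj$events$structure <- st
      artifacts <- rbind(artifacts, inj$events[, c("structure", "type",
                                                   "start_s", "end_s")])
    }
    channels[[st]] <- x
  }
  structure(list(rat_id = rat_id, group = group, week = week,
                 fs = design$fs, channels = channels, episodes = episodes,
                 rail = design$rail, artifacts = artifacts, seed = seed),
            class = "recording_session")
}

# Piecewise amplitude envelope: 1 outside episodes, sqrt(power factor)
# inside, linear cross-fades at episode edges.
amplitude_envelope <- function(n, fs, episodes, amp, crossfade_s) {
  w <- rep(1, n)
  ramp_n <- max(1L, as.integer(round(crossfade_s * fs)))
  for (i in seq_len(nrow(episodes))) {
    a <- amp[i]
    i0 <- as.integer(floor(episodes$onset_s[i] * fs)) + 1L
    i1 <- min(n, as.integer(ceiling(episodes$offset_s[i] * fs)))
    if (i1 <= i0) next
    len <- i1 - i0 + 1L
    r <- min(ramp_n, len %/% 2L)
    seg <- rep(a, len)
    if (r > 0) {
      up <- seq(1, a, length.out = r + 1)[-1]
      seg[seq_len(r)] <- up
      seg[len - r + seq_len(r)] <- rev(up)
    }
    w[i0:i1] <- seg
  }
  w
}

# Excursion artifacts: 1-10 ms rectangular pulses at 12-20 session SDs
# (added); saturation artifacts: 5-25 consecutive samples clipped at
# +/- rail.  Counts are Poisson(artifact_rate) per channel, types 50/50.
inject_artifacts <- function(x, design, seed = 1) {
  n <- length(x)
  events <- data.frame(type = character(0), start_s = numeric(0),
                       end_s = numeric(0))
  if (design$artifact_rate <= 0 || !is.finite(design$rail)) {
    if (design$artifact_rate <= 0) return(list(x = x, events = events))
  }
  with_seed(seed, {
    n_art <- stats::rpois(1, design$artifact_rate)
    if (n_art == 0) return(list(x = x, events = events))
    sdx <- stats::sd(x)
    for (i in seq_len(n_art)) {
      saturation <- is.finite(design$rail) && stats::runif(1) < 0.5
      if (saturation) {
        len <- sample(5:25, 1)
        i0 <- sample.int(n - len, 1)
        x[i0:(i0 + len - 1)] <- sign(stats::runif(1) - 0.5) * design$rail
      } else {
        len <- max(1L, as.integer(round(stats::runif(1, 0.001, 0.010) *
                                          design$fs)))
        i0 <- sample.int(n - len, 1)
        a <- sign(stats::runif(1) - 0.5) * stats::runif(1, 12, 20) * sdx
        x[i0:(i0 + len - 1)] <- x[i0:(i0 + len - 1)] + a
      }
      events <- rbind(events, data.frame(
        type = if (saturation) "saturation" else "excursion",
        start_s = (i0 - 1) / design$fs, end_s = (i0 - 1 + len) / design$fs))
    }
    list(x = x, events = events)
  })
}

#' Rat roster for a design
#'
#' Control rats are `C01..C<n>`, experimental rats `E01..E<n>`.
#'
#' @param design a `cohort_design`.
#' @return data.frame with columns `rat_id`, `group`.
#' @export
cohort_roster <- function(design) {
  data.frame(
    rat_id = c(sprintf("C%02d", seq_len(design$n_control)),
               sprintf("E%02d", seq_len(design$n_experimental))),
    group = rep(GROUPS, c(design$n_control, design$n_experimental)))
}

#' Generate a full cohort in memory
#'
#' Convenience wrapper looping `generate_session` over the roster and
#' weeks.  For full-scale designs prefer the streaming `run_all`, which
#' never holds more than one session in memory.
#'
#' @param design a `cohort_design`.
#' @return list of `recording_session` objects.
#' @export
generate_cohort <- function(design) {
  roster <- cohort_roster(design)
  out <- list()
  for (i in seq_len(nrow(roster))) {
    for (w in seq_len(design$weeks)) {
      s <- generate_session(design, roster$rat_id[i], roster$group[i], w)
      out[[paste0(roster$rat_id[i], "_W", w)]] <- s
    }
  }
  out
}

#' @export
print.recording_session <- function(x, ...) {
  cat(sprintf(
    "<recording_session> %s (%s) W%d: %d channels x %d samples @ %g Hz, %d episodes, %d artifacts\n",
    x$rat_id, x$group, x$week, length(x$channels),
    length(x$channels[[1]]), x$fs, nrow(x$episodes), nrow(x$artifacts)))
  invisible(x)
}
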