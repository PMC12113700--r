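# Shared design constructors for the simulation tests.

behaviors5 <- c("resting", "grooming", "locomotion", "rearing", "sniffing")

unit_gain <- function(weeks = 4) {
  array(1, dim = c(2, weeks, 5),
        dimnames = list(c("control", "experimental"),
                        paste0("W", seq_len(weeks)), behaviors5))
}

zero_coupling <- stats::setNames(rep(0, 5), behaviors5)

# Null cohort for calibration: g == 1, kappa == 0; rat_sd = 0 so cells are
# independent (rank tests are exact under the null regardless of between-rat
# variance, so this only reduces the variance of the rate estimate); short
# sessions keep the simulation inside the runtime budget.
null_desk_design <- function(seed, n_control = 12) {
  cohort_design("desk", seed = seed, n_control = n_control,
                session_range = c(60, 80), rat_sd = 0,
                band_gain = unit_gain(),
                duration_coupling = zero_coupling)
}

# Full default effect structure at desk scale.
effect_desk_design <- function(seed) cohort_design("desk", seed = seed)

# A tiny fully synthetic session assembled by hand (no generator), for I/O
# and extraction tests.
toy_session <- function(fs = 1000, dur = 12, episodes = NULL,
                        rail = NA_real_) {
  n <- fs * dur
  if (is.null(episodes)) {
    episodes <- data.frame(
      behavior = c("resting", "grooming"),
      onset_s = c(0.5, 7), offset_s = c(6, 11.5))
  }
  set.seed(99)
  structure(list(rat_id = "T01", group = "control", week = 1L, fs = fs,
                 channels = list(CrusII = rnorm(n), IO = rnorm(n),
                                 DN = rnorm(n)),
                 episodes = episodes, rail = rail,
                 artifacts = NULL, seed = 99L),
            class = "recording_session")
}
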