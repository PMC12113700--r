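# Synthetic cohort generator: spectra, schedules, sessions.

test_that("white noise (alpha = 0) gives equal power in equal-width bands", {
  aucs <- sapply(1:5, function(s) {
    x <- generate_powerlaw_noise(2^16, 10000, 0, 1, seed = s,
                                 low_flatten = 0)
    psd <- periodogram_psd(x, 10000)
    c(band_auc(psd, 1000, 1200), band_auc(psd, 3000, 3200))
  })
  m <- rowMeans(aucs)
  expect_lt(abs(m[1] - m[2]) / m[1], 0.05)
})

test_that("alpha = 3 band fraction matches the closed-form integral", {
  # (300^-2 - 500^-2) / (300^-2 - 3000^-2) = 0.646465
  fr <- vapply(1:50, function(s) {
    x <- generate_powerlaw_noise(2^14, 10000, 3, 1, seed = s)
    band_table(periodogram_psd(x, 10000))$fraction[1]
  }, numeric(1))
  expect_equal(mean(fr), (300^-2 - 500^-2) / (300^-2 - 3000^-2),
               tolerance = 0.01)
})

test_that("power-law noise is seeded, scaled and validated", {
  x1 <- generate_powerlaw_noise(5000, 10000, 3.2, 1, seed = 7)
  x2 <- generate_powerlaw_noise(5000, 10000, 3.2, 1, seed = 7)
  expect_identical(x1, x2)
  expect_false(identical(
    x1, generate_powerlaw_noise(5000, 10000, 3.2, 1, seed = 8)))
  # expected in-band power equals total_power
  bp <- vapply(1:20, function(s) {
    x <- generate_powerlaw_noise(2^15, 10000, 3.2, 2.5, seed = s)
    band_auc(periodogram_psd(x, 10000), 300, 3000, closed_right = TRUE)
  }, numeric(1))
  expect_equal(mean(bp), 2.5, tolerance = 0.05)
  expect_error(generate_powerlaw_noise(1, 1000, 1, 1), "n_samples")
  expect_error(generate_powerlaw_noise(100, 1000, 1, 0), "total_power")
  expect_error(generate_powerlaw_noise(100, 1000, -1, 1), "alpha")
})

test_that("behavior schedules cover all five behaviors and never overlap", {
  d <- cohort_design()
  pars <- cerebpsd:::schedule_params(d, "control", 1)
  for (s in 1:100) {
    sc <- schedule_behaviors(600, pars, seed = s)
    expect_setequal(unique(sc$behavior), d$behaviors)
    expect_true(all(sc$onset_s < sc$offset_s))
    expect_true(all(sc$offset_s <= 600))
    o <- order(sc$onset_s)
    expect_true(all(sc$onset_s[o][-1] >= sc$offset_s[o][-nrow(sc)] - 1e-12))
    expect_lte(sum(sc$offset_s - sc$onset_s), 600)
  }
  tiny <- schedule_behaviors(0.1, pars, seed = 1)
  expect_lte(nrow(tiny), 1)
  if (nrow(tiny) == 1) expect_lte(tiny$offset_s, 0.1)
  bad <- pars; bad$rate[] <- -1
  expect_error(schedule_behaviors(10, bad), "rates")
  expect_error(schedule_behaviors(0, pars), "duration")
})

test_that("sessions are deterministic and validated", {
  d <- cohort_design("desk", seed = 5)
  s1 <- generate_session(d, "E03", "experimental", 2)
  s2 <- generate_session(d, "E03", "experimental", 2)
  expect_identical(s1$channels, s2$channels)
  expect_identical(s1$episodes, s2$episodes)
  expect_named(s1$channels, c("CrusII", "IO", "DN"))
  expect_error(generate_session(d, "E03", "lesioned", 1), "unknown group")
  expect_error(generate_session(d, "E03", "control", 9), "unknown week")
})

test_that("a no-effect session is exactly the background plus mains", {
  d <- cohort_design("desk", seed = 31, band_gain = unit_gain(),
                     duration_coupling = zero_coupling, rat_sd = 0,
                     artifact_rate = 0, mains_amp = 0)
  s <- generate_session(d, "C02", "control", 3)
  n <- length(s$channels$IO)
  bg <- generate_powerlaw_noise(
    n, d$fs, d$spectral_exponent, d$base_power,
    seed = cerebpsd:::seed_hash(s$seed, "ch:IO"),
    band = d$total_band, low_flatten = d$low_flatten)
  expect_equal(s$channels$IO, bg, tolerance = 1e-12)
})

test_that("injected band gain is recovered from trace band power", {
  # 1.8x power gain on the band of interest during grooming in W1; coupling
  # and intercepts disabled so the Monte-Carlo mean isolates the gain
  cfg <- analysis_config("desk")
  mean_power <- function(group, prefix, n_rats = 25) {
    d <- cohort_design("desk", seed = 4242,
                       duration_coupling = zero_coupling, rat_sd = 0,
                       artifact_rate = 0)
    vals <- numeric(0)
    for (i in seq_len(n_rats)) {
      s <- generate_session(d, sprintf("%s%02d", prefix, i), group, 1)
      ps <- cerebpsd:::process_session(s, cfg)
      b <- ps$band_rows
      sel <- b$behavior == "grooming" & b$band_lo == 30
      vals <- c(vals, b$normalized_psd[sel])
    }
    mean(vals)
  }
  ratio <- mean_power("experimental", "E") / mean_power("control", "C")
  expect_gt(ratio, 1.8 * 0.9)
  expect_lt(ratio, 1.8 * 1.1)
})

test_that("clean sessions produce zero flagged traces downstream", {
  d <- cohort_design("desk", seed = 77, artifact_rate = 0, rail = Inf)
  s <- generate_session(d, "C05", "control", 2)
  ps <- cerebpsd:::process_session(s, analysis_config("desk"))
  expect_equal(ps$n_excluded, 0)
})

test_that("saturation artifacts are recorded and clip at the rail", {
  d <- cohort_design("desk", seed = 13, artifact_rate = 10)
  s <- generate_session(d, "E09", "experimental", 1)
  expect_gt(nrow(s$artifacts), 0)
  sat <- s$artifacts[s$artifacts$type == "saturation", ]
  if (nrow(sat) > 0) {
    a <- sat[1, ]
    seg <- s$channels[[a$structure]][
      (floor(a$start_s * d$fs) + 1):(ceiling(a$end_s * d$fs))]
    expect_true(all(abs(seg) == d$rail))
  }
})
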