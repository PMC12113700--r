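# Trace extraction and artifact QC.

test_that("window tiling follows the stated rule", {
  lens <- c(12, 3, 7, 6, 9, 20)
  onsets <- cumsum(c(0, head(lens, -1) + 1))
  ep <- data.frame(behavior = "grooming", onset_s = onsets,
                   offset_s = onsets + lens)
  w <- extract_trace_windows(ep, "grooming", trace_len = 5)
  counts <- vapply(seq_along(lens), function(i) {
    sum(w$start_s >= onsets[i] & w$start_s < onsets[i] + lens[i])
  }, numeric(1))
  expect_equal(counts, c(2, 0, 1, 1, 1, 4)) # floor(len / 5) per episode
  expect_equal(w$start_s, sort(w$start_s)) # time ordered
  # a single 30 s episode: 5 windows from onset, 5 s apart
  ep30 <- data.frame(behavior = "resting", onset_s = 10, offset_s = 40)
  w30 <- extract_trace_windows(ep30, "resting", 5)
  expect_equal(w30$start_s, 10 + 5 * (0:5)[1:6])
  expect_equal(nrow(w30), 6)
  # shifting all episodes shifts all windows by the same constant
  ep_s <- ep; ep_s$onset_s <- ep_s$onset_s + 37; ep_s$offset_s <- ep_s$offset_s + 37
  w_s <- extract_trace_windows(ep_s, "grooming", 5)
  expect_equal(w_s$start_s, w$start_s + 37)
})

test_that("short episodes yield no windows and a warning downstream", {
  ep <- data.frame(behavior = "rearing", onset_s = c(0, 10),
                   offset_s = c(4, 14.5))
  expect_equal(nrow(extract_trace_windows(ep, "rearing", 5)), 0)
  s <- toy_session(episodes = ep)
  w <- capture_warnings(
    tr <- extract_traces(s, "rearing", trace_len = 5,
                         config = analysis_config("desk", bp_low = 30,
                                                  bp_high = 300)))
  expect_true(any(grepl("only 0/5", w)))
  expect_length(tr, 0)
})

test_that("artifact flags follow the two exclusion rules in order", {
  expect_identical(flag_artifacts(numeric(100), session_sd = 1), "ok")
  x <- rnorm(100)
  x[50] <- 12 # 12 SD excursion with session_sd = 1
  expect_identical(flag_artifacts(x, session_sd = 1), "excluded_excursion")
  raw <- rnorm(100)
  raw[20:29] <- 5 # 10 samples pinned at the rail
  expect_identical(flag_artifacts(rnorm(100), session_sd = 1, raw = raw,
                                  rail = 5), "excluded_saturation")
  # saturation is checked first even when an excursion is also present
  expect_identical(flag_artifacts(x, session_sd = 1, raw = raw, rail = 5),
                   "excluded_saturation")
  # rail unknown: ties at the channel absolute maximum
  expect_identical(flag_artifacts(rnorm(100), session_sd = 1, raw = raw,
                                  rail = NA, channel_absmax = 5),
                   "excluded_saturation")
  # fewer than 5 clipped samples is not saturation
  raw2 <- rnorm(100); raw2[20:23] <- 5
  expect_identical(flag_artifacts(rnorm(100) * 0.1, session_sd = 1,
                                  raw = raw2, rail = 5), "ok")
})

test_that("extraction returns the first five QC survivors per channel", {
  d <- cohort_design("desk", seed = 2024, artifact_rate = 0)
  s <- generate_session(d, "C01", "control", 2)
  cfg <- analysis_config("desk")
  filt <- cerebpsd:::filter_session(s, cfg)
  for (b in c("resting", "locomotion")) {
    wins <- extract_trace_windows(s$episodes, b, cfg$trace_len)
    if (nrow(wins) < 5) next
    tr <- extract_traces(s, b, trace_len = cfg$trace_len, config = cfg,
                         filtered = filt)
    per_ch <- split(tr, vapply(tr, `[[`, character(1), "structure"))
    for (ch in per_ch) {
      expect_length(ch, 5)
      starts <- vapply(ch, `[[`, numeric(1), "start_s")
      expect_equal(starts, wins$start_s[1:5]) # earliest-first, clean session
    }
  }
  expect_error(extract_traces(s, "swimming", config = cfg),
               "unknown behavior")
})

test_that("windows overlapping injected saturation artifacts are excluded", {
  d <- cohort_design("desk", seed = 404, artifact_rate = 12)
  s <- generate_session(d, "E02", "experimental", 1)
  cfg <- analysis_config("desk")
  filt <- cerebpsd:::filter_session(s, cfg)
  sat <- s$artifacts[s$artifacts$type == "saturation", ]
  expect_gt(nrow(sat), 0) # deterministic at this seed and rate
  found <- 0L
  for (i in seq_len(nrow(sat))) {
    st <- sat$structure[i]
    for (b in unique(s$episodes$behavior)) {
      wins <- extract_trace_windows(s$episodes, b, cfg$trace_len)
      hit <- wins$start_s < sat$end_s[i] & wins$end_s > sat$start_s[i]
      for (j in which(hit)) {
        i0 <- round(wins$start_s[j] * s$fs) + 1
        i1 <- i0 + cfg$trace_len * s$fs - 1
        if (i1 > length(filt[[st]])) next
        flag <- flag_artifacts(filt[[st]][i0:i1], sd(filt[[st]]),
                               raw = s$channels[[st]][i0:i1],
                               rail = s$rail,
                               session_mean = mean(filt[[st]]))
        expect_identical(flag, "excluded_saturation")
        found <- found + 1L
      }
    }
  }
  expect_gte(found, 0L)
})
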