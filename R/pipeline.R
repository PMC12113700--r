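# Orchestration: cohort -> traces -> band table -> the three statistical
# analyses (intergroup Mann-Whitney per week, intragroup Friedman with
# Holm-adjusted Wilcoxon post hocs, duration-power Spearman correlations)
# plus the behavior-duration comparison.

#' Analysis configuration
#'
#' Filter settings, trace length, the six PSD bands, the band of interest,
#' the significance level and the aggregation rule that maps trace-level
#' normalized PSD to the experimental unit (the rat).  `scale = "desk"`
#' matches the reduced-rate simulation profile (2 kHz, 1 s traces,
#' frequency axis scaled by 0.1).
#'
#' @param scale `"full"` (default) or `"desk"`.
#' @param ... overrides for any config field.
#' @return an `analysis_config` list.
#' @export
analysis_config <- function(scale = c("full", "desk"), ...) {
  scale <- match.arg(scale)
  cfg <- list(
    scale = scale,
    bp_low = 300, bp_high = 3000, bp_order = 4,
    notch_base = 60, notch_q = 35,
    bands = default_bands(), band_of_interest = c(300, 500),
    trace_len = 5, max_traces = 5,
    alpha = 0.05,
    aggregation = "per-rat-mean",
    correlation_group = "experimental",
    qc = TRUE,
    diagnostics_mc = 2000 # Lilliefors Monte-Carlo replicates in run_all
  )
  if (scale == "desk") {
    cfg$bp_low <- 30; cfg$bp_high <- 300
    cfg$bands <- default_bands(0.1)
    cfg$band_of_interest <- c(30, 50)
    cfg$trace_len <- 1
  }
  over <- list(...)
  for (nm in names(over)) {
    if (!nm %in% names(cfg)) stop("unknown config field: ", nm,
                                  call. = FALSE)
    cfg[nm] <- over[nm]
  }
  stopifnot(cfg$alpha > 0, cfg$alpha < 1,
            cfg$aggregation %in% c("per-rat-mean", "per-rat-median",
                                   "per-trace"))
  structure(cfg, class = "analysis_config")
}

# Band AUCs for many equal-length traces at once (columns = traces), via a
# single multi-column FFT.  Matches periodogram_psd + band_auc exactly.
trace_band_aucs <- function(tracemat, fs, bands) {
  n <- nrow(tracemat)
  tracemat <- sweep(tracemat, 2, colMeans(tracemat))
  xf <- stats::mvfft(tracemat)
  nh <- floor(n / 2)
  p <- Mod(xf[seq_len(nh + 1), , drop = FALSE])^2 / (fs * n)
  scale2 <- rep(2, nh + 1)
  scale2[1] <- 1
  if (n %% 2 == 0) scale2[nh + 1] <- 1
  p <- p * scale2
  freq <- (seq_len(nh + 1) - 1) * fs / n
  df <- fs / n
  k <- nrow(bands)
  out <- matrix(0, ncol(tracemat), k)
  for (i in seq_len(k)) {
    sel <- freq >= bands[i, 1] &
      (if (i == k) freq <= bands[i, 2] else freq < bands[i, 2])
    out[, i] <- colSums(p[sel, , drop = FALSE]) * df
  }
  out
}

# One session -> per-trace band rows + duration rows + exclusion count.
process_session <- function(session, config) {
  filtered <- filter_session(session, config)
  rows <- list()
  n_excluded <- 0L
  n_traces <- 0L
  behaviors <- BEHAVIORS
  bands <- as.matrix(config$bands)
  nb <- nrow(bands)
  bw <- bands[, 2] - bands[, 1]
  for (b in behaviors) {
    traces <- withCallingHandlers(
      extract_traces(session, b, trace_len = config$trace_len,
                     max_traces = config$max_traces, config = config,
                     filtered = filtered, qc = config$qc),
      warning = function(w) invokeRestart("muffleWarning"))
    n_excluded <- n_excluded + attr(traces, "n_excluded")
    if (length(traces) == 0) next
    tracemat <- vapply(traces, `[[`, numeric(length(traces[[1]]$samples)),
                       "samples")
    aucs <- trace_band_aucs(tracemat, session$fs, bands)
    total <- rowSums(aucs)
    nt <- length(traces)
    bt <- data.frame(
      band_lo = rep(bands[, 1], nt), band_hi = rep(bands[, 2], nt),
      auc = as.vector(t(aucs)),
      normalized_psd = as.vector(t(aucs)) / rep(bw, nt),
      fraction = as.vector(t(aucs / total)),
      rat_id = session$rat_id, group = session$group,
      week = session$week,
      structure = rep(vapply(traces, `[[`, character(1), "structure"),
                      each = nb),
      behavior = b,
      trace_start_s = rep(vapply(traces, `[[`, numeric(1), "start_s"),
                          each = nb))
    rows[[length(rows) + 1L]] <- bt
    n_traces <- n_traces + nt
  }
  durs <- do.call(rbind, lapply(behaviors, function(b) {
    d <- behavior_duration(session$episodes, b)
    data.frame(rat_id = session$rat_id, group = session$group,
               week = session$week, behavior = b, total_s = d$total_s,
               n_episodes = d$n_episodes)
  }))
  list(band_rows = if (length(rows)) do.call(rbind, rows) else NULL,
       durations = durs, n_excluded = n_excluded, n_traces = n_traces)
}

#' Aggregate the trace-level band table to the experimental unit
#'
#' Keeps the band of interest and reduces the (up to `max_traces`)
#' trace values per rat x week x structure x behavior with the configured
#' aggregation (default: mean).
#'
#' @param band_rows trace-level band table from `run_all`/`process_session`.
#' @param config an `analysis_config`.
#' @return data.frame with one row per rat x week x structure x behavior
#'   and columns `value` (aggregated normalized PSD), `n_traces`,
#'   `aggregation`.
#' @export
aggregate_band_table <- function(band_rows, config = analysis_config()) {
  boi <- config$band_of_interest
  sel <- band_rows[abs(band_rows$band_lo - boi[1]) < 1e-9 &
                     abs(band_rows$band_hi - boi[2]) < 1e-9, , drop = FALSE]
  if (nrow(sel) == 0) stop("band of interest not present in band table",
                           call. = FALSE)
  if (config$aggregation == "per-trace") {
    out <- sel[, c("rat_id", "group", "week", "structure", "behavior")]
    out$value <- sel$normalized_psd
    out$n_traces <- 1L
  } else {
    fun <- if (config$aggregation == "per-rat-mean") mean else stats::median
    key <- interaction(sel$rat_id, sel$week, sel$structure, sel$behavior,
                       drop = TRUE)
    first <- !duplicated(key)
    out <- sel[first, c("rat_id", "group", "week", "structure", "behavior")]
    out$value <- as.numeric(tapply(sel$normalized_psd, key, fun)[
      as.character(key[first])])
    out$n_traces <- as.integer(tapply(sel$normalized_psd, key, length)[
      as.character(key[first])])
  }
  out$aggregation <- config$aggregation
  rownames(out) <- NULL
  out
}

iqr_bounds <- function(v) stats::quantile(v, c(0.25, 0.75), names = FALSE)

#' Intergroup comparison (Mann-Whitney per structure x behavior x week)
#'
#' @param agg aggregated band table (`aggregate_band_table`).
#' @param config an `analysis_config`.
#' @return data.frame with per-cell U, p, group medians and IQRs; cells
#'   with an empty group are flagged `insufficient data`.
#' @export
run_intergroup <- function(agg, config = analysis_config()) {
  out <- list()
  for (st in unique(agg$structure)) for (b in unique(agg$behavior)) {
    for (w in sort(unique(agg$week))) {
      cell <- agg[agg$structure == st & agg$behavior == b &
                    agg$week == w, ]
      xc <- cell$value[cell$group == "control"]
      xe <- cell$value[cell$group == "experimental"]
      row <- data.frame(structure = st, behavior = b, week = w,
                        n_control = length(xc), n_experimental = length(xe),
                        median_control = stats::median(xc),
                        iqr_lo_control = NA_real_, iqr_hi_control = NA_real_,
                        median_experimental = stats::median(xe),
                        iqr_lo_experimental = NA_real_,
                        iqr_hi_experimental = NA_real_,
                        U = NA_real_, p = NA_real_, method = NA_character_,
                        note = "")
      if (length(xc) > 0) {
        row[c("iqr_lo_control", "iqr_hi_control")] <-
          as.list(iqr_bounds(xc))
      }
      if (length(xe) > 0) {
        row[c("iqr_lo_experimental", "iqr_hi_experimental")] <-
          as.list(iqr_bounds(xe))
      }
      if (length(xc) == 0 || length(xe) == 0) {
        row$note <- "insufficient data"
      } else {
        tst <- mann_whitney_u(xe, xc)
        row$U <- unname(tst$statistic); row$p <- tst$p
        row$method <- tst$method
      }
      out[[length(out) + 1L]] <- row
    }
  }
  res <- do.call(rbind, out)
  res$aggregation <- config$aggregation
  res
}

#' Intragroup comparison (Friedman across weeks, Holm-adjusted Wilcoxon
#' post hocs)
#'
#' Per structure x behavior within one group (default experimental), rats
#' missing any week are excluded listwise.  Week-pair post hocs are run
#' only where the Friedman test is significant at `config$alpha`, and Holm
#' adjustment is applied within that family of week pairs.
#'
#' @param agg aggregated band table.
#' @param config an `analysis_config`.
#' @param group group analyzed (default `"experimental"`).
#' @return list with `friedman` and `posthoc` data.frames.
#' @export
run_intragroup <- function(agg, config = analysis_config(),
                           group = "experimental") {
  ga <- agg[agg$group == group, ]
  weeks <- sort(unique(ga$week))
  fri <- list(); post <- list()
  for (st in unique(ga$structure)) for (b in unique(ga$behavior)) {
    cell <- ga[ga$structure == st & ga$behavior == b, ]
    wide <- tapply(cell$value, list(cell$rat_id, cell$week), mean)
    wide <- wide[stats::complete.cases(wide), , drop = FALSE]
    row <- data.frame(structure = st, behavior = b, group = group,
                      n_rats = nrow(wide), k_weeks = length(weeks),
                      chisq_F = NA_real_, p = NA_real_, note = "")
    if (nrow(wide) < 2 || ncol(wide) < 2) {
      row$note <- "insufficient complete blocks"
    } else {
      tst <- friedman_test(wide)
      row$chisq_F <- unname(tst$statistic); row$p <- tst$p
      if (tst$p <= config$alpha) {
        prs <- utils::combn(weeks, 2)
        praw <- numeric(ncol(prs)); wstat <- numeric(ncol(prs))
        med_a <- numeric(ncol(prs)); med_b <- numeric(ncol(prs))
        for (j in seq_len(ncol(prs))) {
          wa <- as.character(prs[1, j]); wb <- as.character(prs[2, j])
          tw <- wilcoxon_signed_rank(wide[, wb], wide[, wa])
          praw[j] <- tw$p; wstat[j] <- unname(tw$statistic)
          med_a[j] <- stats::median(wide[, wa])
          med_b[j] <- stats::median(wide[, wb])
        }
        post[[length(post) + 1L]] <- data.frame(
          structure = st, behavior = b, group = group,
          week_a = prs[1, ], week_b = prs[2, ], W = wstat,
          median_a = med_a, median_b = med_b,
          p_raw = praw, p_holm = holm_adjust(praw))
      }
    }
    fri[[length(fri) + 1L]] <- row
  }
  list(friedman = do.call(rbind, fri),
       posthoc = if (length(post)) do.call(rbind, post) else
         data.frame(structure = character(0), behavior = character(0),
                    group = character(0), week_a = integer(0),
                    week_b = integer(0), W = numeric(0),
                    median_a = numeric(0), median_b = numeric(0),
                    p_raw = numeric(0), p_holm = numeric(0)))
}

#' Behavior-duration comparison (Mann-Whitney on per-rat total durations)
#'
#' @param durations per-session duration table (`rat_id`, `group`, `week`,
#'   `behavior`, `total_s`).
#' @param config an `analysis_config`.
#' @return data.frame per behavior x week with U, p and group medians.
#' @export
run_durations <- function(durations, config = analysis_config()) {
  out <- list()
  for (b in unique(durations$behavior)) {
    for (w in sort(unique(durations$week))) {
      cell <- durations[durations$behavior == b & durations$week == w, ]
      xc <- cell$total_s[cell$group == "control"]
      xe <- cell$total_s[cell$group == "experimental"]
      row <- data.frame(behavior = b, week = w,
                        n_control = length(xc), n_experimental = length(xe),
                        median_control = stats::median(xc),
                        median_experimental = stats::median(xe),
                        U = NA_real_, p = NA_real_, note = "")
      if (length(xc) == 0 || length(xe) == 0) {
        row$note <- "insufficient data"
      } else {
        tst <- mann_whitney_u(xe, xc)
        row$U <- unname(tst$statistic); row$p <- tst$p
      }
      out[[length(out) + 1L]] <- row
    }
  }
  do.call(rbind, out)
}

#' Duration-power correlation (Spearman per structure x behavior)
#'
#' Pairs one value per rat x week within the correlation group (default
#' experimental): total behavior duration in the session against the
#' aggregated normalized PSD, pooled across weeks (the correlation is
#' computed independently of measurement week).
#'
#' @param agg aggregated band table.
#' @param durations per-session duration table.
#' @param config an `analysis_config`.
#' @return data.frame with rho, p and n per structure x behavior.
#' @export
run_correlation <- function(agg, durations, config = analysis_config()) {
  grp <- config$correlation_group
  ga <- agg[agg$group == grp, ]
  gd <- durations[durations$group == grp, ]
  out <- list()
  for (st in unique(ga$structure)) for (b in unique(ga$behavior)) {
    cell <- ga[ga$structure == st & ga$behavior == b, ]
    dd <- gd[gd$behavior == b, c("rat_id", "week", "total_s")]
    mm <- merge(cell, dd, by = c("rat_id", "week"))
    row <- data.frame(structure = st, behavior = b, group = grp,
                      n = nrow(mm), rho = NA_real_, p = NA_real_,
                      note = "")
    if (nrow(mm) < 3) {
      row$note <- "insufficient pairs"
    } else {
      ct <- spearman_cor(mm$total_s, mm$value)
      row$rho <- ct$rho; row$p <- ct$p
    }
    out[[length(out) + 1L]] <- row
  }
  do.call(rbind, out)
}

#' Normality and homoscedasticity diagnostics per cell
#'
#' Lilliefors p per group and classic Levene p between groups for every
#' structure x behavior x week cell of the aggregated band table.  The
#' diagnostics are logged alongside the report but never gate the
#' analysis: the nonparametric battery is applied unconditionally.
#'
#' @param agg aggregated band table.
#' @param config an `analysis_config`.
#' @return data.frame with one row per cell.
#' @export
run_diagnostics <- function(agg, config = analysis_config()) {
  out <- list()
  for (st in unique(agg$structure)) for (b in unique(agg$behavior)) {
    for (w in sort(unique(agg$week))) {
      cell <- agg[agg$structure == st & agg$behavior == b &
                    agg$week == w, ]
      xc <- cell$value[cell$group == "control"]
      xe <- cell$value[cell$group == "experimental"]
      lp <- function(v, seed) {
        if (length(v) < 4 || stats::sd(v) == 0) return(NA_real_)
        lilliefors_test(v, n_mc = config$diagnostics_mc, seed = seed)$p
      }
      lev <- if (length(xc) >= 2 && length(xe) >= 2) {
        tryCatch(levene_test(list(xc, xe))$p, error = function(e) NA_real_)
      } else NA_real_
      out[[length(out) + 1L]] <- data.frame(
        structure = st, behavior = b, week = w,
        lilliefors_p_control = lp(xc, 1), lilliefors_p_experimental = lp(xe, 2),
        levene_p = lev)
    }
  }
  do.call(rbind, out)
}

#' Run the full analysis over a cohort
#'
#' Sessions are either simulated in-line from `design` (streamed one at a
#' time, so full-scale cohorts never fill memory) or read from a list of
#' manifest paths.  Produces the trace-level band table, the per-session
#' duration table, and the four report tables; optionally writes them as
#' CSV with a plain-text run log.
#'
#' @param design a `cohort_design` (used when `manifests` is NULL).
#' @param config an `analysis_config`.
#' @param manifests optional character vector of manifest paths.
#' @param out_dir optional output directory for the CSV tables and log.
#' @return an `analysis_report`: list with `band_table`, `durations`,
#'   `intergroup`, `intragroup` (list `friedman` + `posthoc`),
#'   `duration_tests`, `correlation` and `log`.
#' @export
run_all <- function(design = NULL, config = analysis_config(),
                    manifests = NULL, out_dir = NULL) {
  stopifnot(!is.null(design) || !is.null(manifests))
  band_rows <- list(); durs <- list()
  n_excluded <- 0L; n_traces <- 0L; n_sessions <- 0L
  handle <- function(session) {
    ps <- process_session(session, config)
    if (!is.null(ps$band_rows)) {
      band_rows[[length(band_rows) + 1L]] <<- ps$band_rows
    }
    durs[[length(durs) + 1L]] <<- ps$durations
    n_excluded <<- n_excluded + ps$n_excluded
    n_traces <<- n_traces + ps$n_traces
    n_sessions <<- n_sessions + 1L
  }
  if (!is.null(manifests)) {
    for (mp in manifests) handle(read_session(mp))
  } else {
    roster <- cohort_roster(design)
    for (i in seq_len(nrow(roster))) {
      for (w in seq_len(design$weeks)) {
        handle(generate_session(design, roster$rat_id[i],
                                roster$group[i], w))
      }
    }
  }
  band_table <- do.call(rbind, band_rows)
  durations <- do.call(rbind, durs)
  agg <- aggregate_band_table(band_table, config)
  report <- list(
    band_table = band_table,
    durations = durations,
    aggregated = agg,
    intergroup = run_intergroup(agg, config),
    intragroup = run_intragroup(agg, config),
    diagnostics = run_diagnostics(agg, config),
    duration_tests = run_durations(durations, config),
    correlation = run_correlation(agg, durations, config),
    log = list(
      package_version = as.character(utils::packageVersion("cerebpsd")),
      design_seed = if (!is.null(design)) design$seed else NA,
      scale = config$scale, aggregation = config$aggregation,
      alpha = config$alpha, n_sessions = n_sessions,
      n_traces = n_traces, n_excluded_traces = n_excluded))
  class(report) <- "analysis_report"
  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

write_report <- function(report, out_dir) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  utils::write.csv(report$band_table,
                   file.path(out_dir, "band_table.csv"), row.names = FALSE)
  utils::write.csv(report$durations,
                   file.path(out_dir, "durations.csv"), row.names = FALSE)
  utils::write.csv(report$intergroup,
                   file.path(out_dir, "intergroup.csv"), row.names = FALSE)
  utils::write.csv(report$intragroup$friedman,
                   file.path(out_dir, "intragroup_friedman.csv"),
                   row.names = FALSE)
  utils::write.csv(report$intragroup$posthoc,
                   file.path(out_dir, "intragroup_posthoc.csv"),
                   row.names = FALSE)
  utils::write.csv(report$duration_tests,
                   file.path(out_dir, "duration_tests.csv"),
                   row.names = FALSE)
  utils::write.csv(report$correlation,
                   file.path(out_dir, "correlation.csv"), row.names = FALSE)
  utils::write.csv(report$diagnostics,
                   file.path(out_dir, "diagnostics.csv"), row.names = FALSE)
  log <- report$log
  writeLines(c("cerebpsd run log",
               sprintf("%s: %s", names(log), unlist(lapply(log, format)))),
             file.path(out_dir, "run_log.txt"))
  invisible(out_dir)
}

#' @export
print.analysis_report <- function(x, ...) {
  cat(sprintf(paste0(
    "<analysis_report> %d sessions, %d traces (%d excluded), ",
    "aggregation %s\n  intergroup cells: %d (significant: %d)\n",
    "  friedman cells: %d (significant: %d); posthoc rows: %d\n"),
    x$log$n_sessions, x$log$n_traces, x$log$n_excluded_traces,
    x$log$aggregation, nrow(x$intergroup),
    sum(x$intergroup$p <= x$log$alpha, na.rm = TRUE),
    nrow(x$intragroup$friedman),
    sum(x$intragroup$friedman$p <= x$log$alpha, na.rm = TRUE),
    nrow(x$intragroup$posthoc)))
  invisible(x)
}
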