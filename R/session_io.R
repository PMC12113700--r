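# On-disk session representation: a JSON manifest, one little-endian
# float32 binary file per channel (microvolts), and a CSV episode table
# (behavior, onset_s, offset_s with 6-decimal seconds).  Episode times are
# seconds, half-open [onset, offset).

#' Write a recording session to a directory
#'
#' @param session a `recording_session`.
#' @param directory output directory (created if needed).
#' @return the manifest (invisibly), also written as `manifest.json`.
#' @export
write_session <- function(session, directory) {
  if (!dir.exists(directory)) {
    ok <- dir.create(directory, recursive = TRUE, showWarnings = FALSE)
    if (!ok && !dir.exists(directory)) {
      stop("cannot create directory: ", directory, call. = FALSE)
    }
  }
  stem <- sprintf("%s_W%d", session$rat_id, session$week)
  chans <- list()
  for (st in names(session$channels)) {
    fn <- sprintf("%s_%s.f32", stem, st)
    path <- file.path(directory, fn)
    con <- file(path, "wb")
    on.exit(try(close(con), silent = TRUE), add = TRUE)
    writeBin(as.numeric(session$channels[[st]]), con, size = 4,
             endian = "little")
    close(con)
    on.exit()
    chans[[st]] <- list(file = fn,
                        n_samples = length(session$channels[[st]]))
  }
  epi_file <- sprintf("%s_episodes.csv", stem)
  ep <- session$episodes
  ep_out <- data.frame(behavior = ep$behavior,
                       onset_s = sprintf("%.6f", ep$onset_s),
                       offset_s = sprintf("%.6f", ep$offset_s))
  utils::write.csv(ep_out, file.path(directory, epi_file),
                   row.names = FALSE, quote = FALSE)
  manifest <- list(
    format = "cerebpsd-session-1", units = "uV",
    rat_id = session$rat_id, group = session$group, week = session$week,
    fs = session$fs, seed = session$seed,
    channels = chans, episodes_file = epi_file)
  rail <- session$rail
  if (!is.null(rail) && length(rail) == 1 && is.finite(rail)) {
    manifest$rail <- rail
  }
  jsonlite::write_json(manifest, file.path(directory, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

#' Read a recording session from a manifest
#'
#' Validates that the referenced files exist and match the manifest, that
#' channels have equal length, that episodes are well formed (onset <
#' offset, no overlap) and that structure labels are known.  Unknown
#' behavior labels (rare behaviors such as yawning or scratching) are
#' accepted with a warning.
#'
#' @param manifest_path path to `manifest.json`.
#' @return a `recording_session`.
#' @export
read_session <- function(manifest_path) {
  if (!file.exists(manifest_path)) {
    stop("manifest not found: ", manifest_path, call. = FALSE)
  }
  m <- jsonlite::read_json(manifest_path, simplifyVector = TRUE)
  dir <- dirname(manifest_path)
  if (is.null(m$fs) || m$fs <= 0) stop("manifest: invalid fs",
                                       call. = FALSE)
  if (!all(names(m$channels) %in% STRUCTURES)) {
    stop("manifest: structure labels must be within {",
         paste(STRUCTURES, collapse = ", "), "}", call. = FALSE)
  }
  channels <- list()
  for (st in names(m$channels)) {
    info <- m$channels[[st]]
    path <- file.path(dir, info$file)
    if (!file.exists(path)) {
      stop("missing signal file: ", path, call. = FALSE)
    }
    nbytes <- file.info(path)$size
    if (nbytes != 4 * info$n_samples) {
      stop(sprintf("signal file %s: %d bytes, manifest says %d samples",
                   path, nbytes, info$n_samples), call. = FALSE)
    }
    con <- file(path, "rb")
    channels[[st]] <- readBin(con, numeric(), n = info$n_samples,
                              size = 4, endian = "little")
    close(con)
  }
  if (length(unique(lengths(channels))) > 1) {
    stop("channels differ in length", call. = FALSE)
  }
  ep_path <- file.path(dir, m$episodes_file)
  if (!file.exists(ep_path)) stop("missing episode table: ", ep_path,
                                  call. = FALSE)
  ep <- utils::read.csv(ep_path, stringsAsFactors = FALSE)
  validate_episodes(ep)
  unknown <- setdiff(unique(ep$behavior), BEHAVIORS)
  if (length(unknown) > 0) {
    warning("unknown behavior label(s) accepted: ",
            paste(unknown, collapse = ", "), call. = FALSE)
  }
  structure(list(rat_id = m$rat_id, group = m$group, week = m$week,
                 fs = m$fs, channels = channels, episodes = ep,
                 rail = if (length(m$rail) == 1 && is.numeric(m$rail))
                   m$rail else NA_real_,
                 artifacts = NULL, seed = m$seed),
            class = "recording_session")
}

validate_episodes <- function(ep) {
  need <- c("behavior", "onset_s", "offset_s")
  if (!all(need %in% names(ep))) {
    stop("episode table needs columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  bad <- which(!(ep$onset_s < ep$offset_s))
  if (length(bad) > 0) {
    stop("episode rows with onset >= offset: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  if (any(ep$onset_s < 0)) stop("negative onsets", call. = FALSE)
  if (nrow(ep) > 1) {
    o <- order(ep$onset_s)
    overl <- which(ep$onset_s[o][-1] < ep$offset_s[o][-nrow(ep)] - 1e-9)
    if (length(overl) > 0) {
      stop("overlapping episode rows: ",
           paste(sort(o[c(overl, overl + 1)]), collapse = ", "),
           call. = FALSE)
    }
  }
  invisible(ep)
}
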