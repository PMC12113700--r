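# Periodogram PSD and band quantification.
#
# The primary outcome of the analysis is the bandwidth-normalized band power:
# the discrete band integral AUC[f1,f2] = sum_{f1 <= fj < f2} PSD(fj) * df
# divided by the bandwidth f2 - f1.  Bands are half-open on the right with
# the final band closed, so the six analysis bands partition [300, 3000] Hz
# exactly (the shared interior edges 500, 1000, ... are counted once).

#' The six standard analysis bands
#'
#' 300-500, 500-1000, 1000-1500, 1500-2000, 2000-2500 and 2500-3000 Hz,
#' optionally scaled (e.g. `scale = 0.1` for reduced-rate desk simulations).
#'
#' @param scale multiplicative frequency scale (default 1).
#' @return a 6 x 2 matrix with columns `lo`, `hi` in Hz.
#' @export
default_bands <- function(scale = 1) {
  b <- cbind(lo = c(300, 500, 1000, 1500, 2000, 2500),
             hi = c(500, 1000, 1500, 2000, 2500, 3000))
  b * scale
}

#' Periodogram power spectral density
#'
#' Plain (rectangular-taper) one-sided periodogram in density units
#' (microvolts squared per Hz).  The mean is removed before the transform;
#' Parseval holds exactly: `sum(psd) * df` equals the mean square of the
#' demeaned (and, for non-rectangular tapers, tapered and power-renormalized)
#' trace.
#'
#' @param x trace samples (microvolts).
#' @param fs sampling rate in Hz.
#' @param window `"rectangular"` (default, the analysis standard) or
#'   `"hann"`.
#' @return an object of class `psd_estimate`: list with `freq` (Hz, from 0
#'   to Nyquist), `psd`, `df`, `n`, `window`.
#' @export
periodogram_psd <- function(x, fs, window = c("rectangular", "hann")) {
  window <- match.arg(window)
  n <- length(x)
  if (n < 2) stop("trace must have at least 2 samples", call. = FALSE)
  x <- x - mean(x)
  if (window == "hann") {
    w <- 0.5 - 0.5 * cos(2 * pi * (seq_len(n) - 1) / n) # periodic Hann
    u <- mean(w^2)
    x <- x * w
  } else {
    u <- 1
  }
  xf <- stats::fft(x)
  nh <- floor(n / 2)
  idx <- seq_len(nh + 1) # bins 0 .. Nyquist (Nyquist only exact if n even)
  p <- (Mod(xf[idx])^2) / (fs * n * u)
  scale2 <- rep(2, nh + 1)
  scale2[1] <- 1
  if (n %% 2 == 0) scale2[nh + 1] <- 1
  p <- p * scale2
  structure(list(freq = (idx - 1) * fs / n, psd = p, df = fs / n,
                 n = n, window = window),
            class = "psd_estimate")
}

#' Welch-averaged PSD (optional alternative; not used in the standard
#' analysis, which specifies the plain periodogram)
#'
#' @param x trace samples.
#' @param fs sampling rate in Hz.
#' @param seg_len segment length in samples.
#' @param overlap fractional overlap between segments (default 0.5).
#' @param window taper per segment (default `"hann"`).
#' @return a `psd_estimate` with `df = fs / seg_len`.
#' @export
welch_psd <- function(x, fs, seg_len, overlap = 0.5,
                      window = c("hann", "rectangular")) {
  window <- match.arg(window)
  n <- length(x)
  seg_len <- as.integer(seg_len)
  stopifnot(seg_len >= 2, seg_len <= n, overlap >= 0, overlap < 1)
  step <- max(1L, as.integer(round(seg_len * (1 - overlap))))
  starts <- seq(1L, n - seg_len + 1L, by = step)
  acc <- NULL
  for (s in starts) {
    p <- periodogram_psd(x[s:(s + seg_len - 1L)], fs, window = window)
    acc <- if (is.null(acc)) p$psd else acc + p$psd
  }
  p$psd <- acc / length(starts)
  p$n <- n
  p
}

#' Band area under the PSD curve
#'
#' Discrete integral `sum PSD(fj) * df` over bins with
#' `f1 <= fj < f2` (set `closed_right = TRUE` to include `f2`, used for the
#' final band so the six bands partition the full range).
#'
#' @param psd a `psd_estimate`.
#' @param f1,f2 band edges in Hz.
#' @param closed_right include bins at exactly `f2`?
#' @return band power in microvolts squared.
#' @export
band_auc <- function(psd, f1, f2, closed_right = FALSE) {
  stopifnot(inherits(psd, "psd_estimate"))
  if (!(f1 < f2)) stop("band edges must satisfy f1 < f2", call. = FALSE)
  sel <- psd$freq >= f1 & (if (closed_right) psd$freq <= f2 else psd$freq < f2)
  if (!any(sel)) {
    warning("no frequency bins in band [", f1, ", ", f2, ")")
    return(0)
  }
  sum(psd$psd[sel]) * psd$df
}

#' Bandwidth-normalized band power
#'
#' `band_auc(psd, f1, f2) / (f2 - f1)`, in microvolts squared per Hz.  For a
#' flat spectrum of height `c` this returns `c` for any band.
#'
#' @inheritParams band_auc
#' @return normalized PSD in microvolts squared per Hz.
#' @export
normalized_band_psd <- function(psd, f1, f2, closed_right = FALSE) {
  if (f2 == f1) stop("zero-width band", call. = FALSE)
  band_auc(psd, f1, f2, closed_right = closed_right) / (f2 - f1)
}

#' Per-band AUC, normalized PSD and fraction of total power
#'
#' @param psd a `psd_estimate`.
#' @param bands `k x 2` matrix of contiguous increasing band edges
#'   (default the six standard bands).  The last band is closed on the
#'   right; all others are half-open.
#' @return data.frame with columns `band_lo`, `band_hi`, `auc`,
#'   `normalized_psd`, `fraction` (share of the total AUC over the full
#'   banded range).
#' @export
band_table <- function(psd, bands = default_bands()) {
  bands <- as.matrix(bands)
  k <- nrow(bands)
  if (any(bands[, 2] <= bands[, 1])) {
    stop("bands must have positive width", call. = FALSE)
  }
  if (k > 1 && any(abs(bands[-1, 1] - bands[-k, 2]) > 1e-9)) {
    stop("bands must be contiguous and increasing", call. = FALSE)
  }
  auc <- vapply(seq_len(k), function(i) {
    band_auc(psd, bands[i, 1], bands[i, 2], closed_right = (i == k))
  }, numeric(1))
  total <- sum(auc)
  data.frame(band_lo = bands[, 1], band_hi = bands[, 2], auc = auc,
             normalized_psd = auc / (bands[, 2] - bands[, 1]),
             fraction = if (total > 0) auc / total else rep(NA_real_, k))
}

#' @export
print.psd_estimate <- function(x, ...) {
  cat(sprintf(
    "<psd_estimate> n = %d samples, df = %.4g Hz, %s taper, %d bins\n",
    x$n, x$df, x$window, length(x$freq)))
  invisible(x)
}
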