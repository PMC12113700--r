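#' @useDynLib cerebpsd, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# ---- IIR design -------------------------------------------------------------
#
# Butterworth band-pass designed from the analog low-pass prototype
# (poles exp(i*pi*(2k + n - 1)/(2n))), low-pass -> band-pass transform with
# pre-warped edges, bilinear transform, and conversion to second-order
# sections.  Sections keep the cascade numerically well conditioned for
# narrow bands (e.g. the 300-500 Hz component split used by the simulator).

poly_from_roots <- function(r) {
  p <- 1 + 0i
  for (ri in r) p <- c(p, 0) - c(0, p * ri)
  p
}

#' Design a Butterworth band-pass as second-order sections
#'
#' Prototype order `order` gives a band-pass with `2 * order` poles; the
#' magnitude response is
#' \eqn{|H(f)|^2 = 1 / (1 + ((f^2 - f_1 f_2) / (f (f_2 - f_1)))^{2n})}
#' up to bilinear warping.
#'
#' @param low,high band edges in Hz.
#' @param fs sampling rate in Hz.
#' @param order prototype order (default 4, the analysis standard).
#' @return a `n_sections x 6` matrix of biquad coefficients
#'   `(b0, b1, b2, 1, a1, a2)`.
#' @export
butter_bandpass_sos <- function(low, high, fs, order = 4) {
  stopifnot(is.numeric(low), is.numeric(high), is.numeric(fs), order >= 1)
  if (!(low > 0 && low < high && high < fs / 2)) {
    stop("band edges must satisfy 0 < low < high < fs/2", call. = FALSE)
  }
  n <- as.integer(order)
  k <- seq_len(n)
  p_lp <- exp(1i * pi * (2 * k + n - 1) / (2 * n))

  fs2 <- 2 * fs
  w1 <- fs2 * tan(pi * low / fs)
  w2 <- fs2 * tan(pi * high / fs)
  bw <- w2 - w1
  w0 <- sqrt(w1 * w2)

  # low-pass -> band-pass: each prototype pole p yields the two roots of
  # s^2 - (p*bw) s + w0^2 = 0
  pb <- p_lp * bw / 2
  disc <- sqrt(pb^2 - w0^2)
  p_bp <- c(pb + disc, pb - disc)
  gain_a <- bw^n # n analog zeros at s = 0

  # bilinear transform
  p_d <- (fs2 + p_bp) / (fs2 - p_bp)
  gain_d <- Re(gain_a * fs2^n / prod(fs2 - p_bp)) # zeros at 0 give (fs2)^n
  z_d <- c(rep(1, n), rep(-1, n))

  zpk_to_sos(z_d, p_d, gain_d)
}

# Pair conjugate pole pairs with zero pairs: low-frequency poles get the
# z = +1 (DC-blocking) zeros, high-frequency poles the z = -1 zeros.
zpk_to_sos <- function(z, p, k) {
  stopifnot(length(z) == length(p), length(p) %% 2 == 0)
  pu <- p[Im(p) >= 0]
  pu <- pu[order(abs(Arg(pu)))]
  n2 <- length(pu)
  nz_pos <- sum(abs(z - 1) < 1e-9) / 2
  sos <- matrix(0, n2, 6)
  for (s in seq_len(n2)) {
    ps <- pu[s]
    a <- Re(poly_from_roots(c(ps, Conj(ps))))
    zz <- if (s <= nz_pos) c(1, 1) else c(-1, -1)
    b <- Re(poly_from_roots(zz))
    sos[s, ] <- c(b, a)
  }
  sos[1, 1:3] <- sos[1, 1:3] * k
  sos
}

#' Design a single IIR notch biquad
#'
#' Constrained two-pole two-zero notch with unit zeros on the unit circle at
#' the notch frequency; `bw` is the -3 dB bandwidth in Hz.
#'
#' @param f0 notch center in Hz.
#' @param bw -3 dB bandwidth in Hz.
#' @param fs sampling rate in Hz.
#' @return 1 x 6 biquad row.
#' @export
notch_sos <- function(f0, bw, fs) {
  stopifnot(f0 > 0, f0 < fs / 2, bw > 0)
  w0 <- 2 * pi * f0 / fs
  q <- f0 / bw
  alpha <- sin(w0) / (2 * q)
  b <- c(1, -2 * cos(w0), 1)
  a <- c(1 + alpha, -2 * cos(w0), 1 - alpha)
  matrix(c(b / a[1], a / a[1]), 1, 6)
}

#' Cascade of notches at a base frequency and all harmonics
#'
#' One biquad per harmonic `k * base <= max_freq` (and below Nyquist).  All
#' notches share the same absolute -3 dB bandwidth `base / q` so that even
#' high harmonics remove only a narrow sliver of spectrum.
#'
#' @inheritParams notch_filter
#' @return `n_notches x 6` SOS matrix.
#' @export
notch_cascade_sos <- function(fs, base = 60, max_freq = 3000, q = 35) {
  stopifnot(base > 0, q > 0)
  centers <- seq(base, min(max_freq, fs / 2 * 0.999), by = base)
  if (length(centers) == 0) return(matrix(numeric(0), 0, 6))
  bw <- base / q
  do.call(rbind, lapply(centers, notch_sos, bw = bw, fs = fs))
}

#' Analytic frequency response of an SOS cascade
#'
#' @param sos SOS matrix.
#' @param f frequencies in Hz.
#' @param fs sampling rate in Hz.
#' @return complex response at `f`.
#' @export
sos_freq_response <- function(sos, f, fs) {
  z1 <- exp(-1i * 2 * pi * f / fs)
  h <- rep(1 + 0i, length(f))
  for (s in seq_len(nrow(sos))) {
    num <- sos[s, 1] + sos[s, 2] * z1 + sos[s, 3] * z1^2
    den <- sos[s, 4] + sos[s, 5] * z1 + sos[s, 6] * z1^2
    h <- h * num / den
  }
  h
}

# Zero-phase (forward-backward) filtering with odd-reflection padding.
filtfilt_sos <- function(sos, x, pad = NULL) {
  n <- length(x)
  if (n < 2 || nrow(sos) == 0) return(x)
  if (is.null(pad)) pad <- min(n - 1, 3000L)
  pad <- min(pad, n - 1)
  if (pad > 0) {
    pre <- 2 * x[1] - x[seq(pad + 1, 2)]
    post <- 2 * x[n] - x[seq(n - 1, n - pad)]
    xp <- c(pre, x, post)
  } else {
    xp <- x
  }
  y <- sosfiltfilt_cpp(sos, xp)
  if (pad > 0) y <- y[(pad + 1):(pad + n)]
  y
}

#' Zero-phase Butterworth band-pass filter
#'
#' Applies the band-pass forward and backward (zero phase), so the effective
#' magnitude response is the square of the single-pass response and the
#' effective roll-off doubles the nominal order.  Session edges are padded by
#' odd reflection (`pad` samples, default 1 s) to suppress edge transients.
#'
#' @param x signal (microvolts).
#' @param fs sampling rate in Hz.
#' @param low,high band edges in Hz (defaults 300 and 3000).
#' @param order Butterworth prototype order (default 4).
#' @param pad reflection-padding length in samples; default `min(fs, n-1)`.
#' @return filtered signal, same length as `x`.
#' @export
bandpass_filter <- function(x, fs, low = 300, high = 3000, order = 4,
                            pad = NULL) {
  if (is.null(pad)) pad <- min(length(x) - 1, as.integer(round(fs)))
  sos <- butter_bandpass_sos(low, high, fs, order)
  filtfilt_sos(sos, x, pad = pad)
}

#' Zero-phase mains notch filtering at a base frequency and harmonics
#'
#' @param x signal.
#' @param fs sampling rate in Hz.
#' @param base mains frequency in Hz (default 60).
#' @param max_freq highest harmonic to notch (default 3000 Hz).
#' @param q quality factor at the base frequency; all harmonics share the
#'   absolute bandwidth `base / q` (default 35, i.e. ~1.7 Hz wide at 60 Hz).
#' @param pad reflection padding in samples (default 1 s).
#' @return filtered signal.
#' @export
notch_filter <- function(x, fs, base = 60, max_freq = 3000, q = 35,
                         pad = NULL) {
  if (is.null(pad)) pad <- min(length(x) - 1, as.integer(round(fs)))
  sos <- notch_cascade_sos(fs, base = base, max_freq = max_freq, q = q)
  filtfilt_sos(sos, x, pad = pad)
}
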