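# Internal numerical helpers shared across modules.

#' @keywords internal
#' @noRd
wrap_angle <- function(x) atan2(sin(x), cos(x))

# Odd-length unit-sum Hanning kernel spanning `width_ms` at `fs` Hz.
# The raised-cosine window of signal::hanning is zero at both ends; a
# length-1 kernel degenerates to the identity.
#' @noRd
hanning_kernel <- function(width_ms, fs) {
  n <- max(1L, round(width_ms * fs / 1000))
  if (n %% 2L == 0L) n <- n + 1L
  if (n == 1L) return(1)
  w <- signal::hanning(n)
  w / sum(w)
}

# Centred ("same") convolution with reflective padding, FFT-based.
# `k` must have odd length.
#' @noRd
conv_same_reflect <- function(x, k) {
  n <- length(x)
  m <- length(k)
  if (m == 1L) return(x * k)
  stopifnot(m %% 2L == 1L)
  h <- (m - 1L) %/% 2L
  if (h >= n) stop("kernel longer than signal")
  pad <- c(x[(h + 1L):2L], x, x[(n - 1L):(n - h)])
  np <- length(pad)
  nfft <- stats::nextn(np + m - 1L, 2)
  X <- stats::fft(c(pad, numeric(nfft - np)))
  K <- stats::fft(c(k, numeric(nfft - m)))
  y <- Re(stats::fft(X * K, inverse = TRUE)) / nfft
  # full convolution starts at lag 0; centre of kernel aligns after m-1 lags
  y[(2L * h + 1L):(2L * h + n)]
}

# Complex analytic signal via the frequency-domain Hilbert construction:
# double positive frequencies, zero negative ones (Nyquist/DC untouched).
#' @noRd
analytic_signal <- function(x) {
  n <- length(x)
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2L == 0L) {
    h[1L] <- 1
    h[n / 2L + 1L] <- 1
    h[2L:(n / 2L)] <- 2
  } else {
    h[1L] <- 1
    h[2L:((n + 1L) / 2L)] <- 2
  }
  stats::fft(X * h, inverse = TRUE) / n
}

# Zero-phase (forward-backward) Butterworth bandpass, order 4.
#' @noRd
bandpass_zero_phase <- function(x, lo, hi, fs, order = 4) {
  nyq <- fs / 2
  if (!(lo > 0 && lo < hi && hi < nyq)) {
    stop("band edges must satisfy 0 < lo < hi < Nyquist")
  }
  bf <- signal::butter(order, c(lo, hi) / nyq, type = "pass")
  as.numeric(signal::filtfilt(bf, x))
}

# FFT brick-wall lowpass at `cutoff` Hz (zero-phase by construction).
#' @noRd
fft_lowpass <- function(x, cutoff, fs) {
  n <- length(x)
  X <- stats::fft(x)
  f <- (0:(n - 1L)) * fs / n
  f <- pmin(f, fs - f)  # two-sided frequency magnitude
  X[f > cutoff] <- 0
  Re(stats::fft(X, inverse = TRUE)) / n
}

# Bandpass on a decimated working grid. A narrow low-frequency band at a
# high sampling rate makes the order-4 transfer-function Butterworth
# numerically singular, so the trace is first anti-alias lowpassed (FFT
# brick wall) and subsampled to a working rate of roughly 50x the upper
# band edge; the zero-phase Butterworth then runs on a well-conditioned
# normalised band. Returns the filtered series, its rate, and the stride.
#' @noRd
band_filter_decimated <- function(x, lo, hi, fs, order = 4) {
  q <- max(1L, floor(fs / (50 * hi)))
  if (q > 1L) {
    x <- fft_lowpass(x, 0.45 * fs / q, fs)
    x <- x[seq(1L, length(x), by = q)]
  }
  fs_w <- fs / q
  list(y = bandpass_zero_phase(x, lo, hi, fs_w, order), fs = fs_w, q = q)
}

# One-sided periodogram of the mean-removed series. Power is scaled so a
# sinusoid of amplitude A occupying an integer number of cycles yields
# A^2/2 at its frequency bin, and sum(power) equals the series variance
# (biased, 1/n) by Parseval.
#' @noRd
periodogram_onesided <- function(x, fs, pad_to = NULL) {
  x <- x - mean(x)
  n <- length(x)
  nfft <- if (is.null(pad_to)) n else max(n, pad_to)
  X <- stats::fft(c(x, numeric(nfft - n)))
  nkeep <- floor(nfft / 2) + 1L
  p <- (Mod(X[seq_len(nkeep)])^2) / (n * nfft)
  # fold negative frequencies onto positive ones (not DC; not Nyquist if even)
  fold <- 2:(nkeep - if (nfft %% 2L == 0L) 1L else 0L)
  p[fold] <- 2 * p[fold]
  list(freq = (seq_len(nkeep) - 1L) * fs / nfft, power = p)
}

# Sample indices of a half-open time window [start, end), times in seconds
# from trial start. 0-based time -> 1-based index.
#' @noRd
window_indices <- function(start, end, fs, n) {
  i0 <- floor(start * fs + 1e-6) + 1L
  i1 <- ceiling(end * fs - 1e-6)
  if (i0 < 1L || i1 > n || i0 > i1) {
    stop(sprintf("window [%g, %g) s outside trace of %d samples at %g Hz",
                 start, end, n, fs))
  }
  i0:i1
}

#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a

# Gaussian noise of SD `sd`: spectrally flat ("white") or 1/f-shaped
# ("pink", amplitude ~ 1/sqrt(f), flat below 1 Hz), generated by FFT
# shaping and rescaled to the requested SD. Uses the current RNG stream.
#' @noRd
colored_noise <- function(n, sd, fs, color = c("pink", "white")) {
  color <- match.arg(color)
  if (sd == 0) return(numeric(n))
  w <- stats::rnorm(n)
  if (color == "white") return(sd * w)
  f <- (0:(n - 1L)) * fs / n
  f <- pmin(f, fs - f)
  shape <- 1 / sqrt(pmax(f, 1))
  shape[1L] <- 0  # no DC drift
  x <- Re(stats::fft(stats::fft(w) * shape, inverse = TRUE)) / n
  sd * x / stats::sd(x)
}
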