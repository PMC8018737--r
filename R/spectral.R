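# Spectral analysis of subthreshold membrane potential: periodograms,
# band magnitudes, Morlet wavelet maps, intertrial phase coherence, and
# the oscillation-trial detector.

#' Frequency band specification
#'
#' @param name Label.
#' @param lo,hi Band edges in Hz, `0 < lo < hi`.
#' @return An object of class `band_spec`.
#' @export
band_spec <- function(name, lo, hi) {
  if (!(lo > 0 && lo < hi)) stop("band_spec: need 0 < lo < hi")
  structure(list(name = name, lo = lo, hi = hi), class = "band_spec")
}

#' The three bands reported throughout the analysis
#'
#' Theta-range 4--7 Hz (the familiarity oscillation), alpha 8--12 Hz, and
#' beta 13--30 Hz.
#'
#' @return Named list of [band_spec()]s.
#' @export
default_bands <- function() {
  list(theta = band_spec("4-7 Hz", 4, 7),
       alpha = band_spec("8-12 Hz", 8, 12),
       beta = band_spec("13-30 Hz", 13, 30))
}

#' One-sided FFT power spectrum of a trace window
#'
#' The window is mean-removed and transformed with the FFT. Power is scaled
#' so a sinusoid of amplitude A occupying an integer number of cycles
#' contributes A^2/2 at its bin and the spectrum sums to the window's
#' (biased) variance.
#'
#' @param trial A spike-removed [vm_trial()].
#' @param window Length-2 numeric, window in s after stimulus onset; `NULL`
#'   uses the whole trace.
#' @return List with `freq` (Hz) and `power` (mV^2).
#' @export
power_spectrum <- function(trial, window = NULL) {
  x <- trial$samples
  if (!is.null(window)) {
    x <- x[window_indices(trial$stim_onset + window[1],
                          trial$stim_onset + window[2],
                          trial$sampling_rate, length(x))]
  }
  periodogram_onesided(x, trial$sampling_rate)
}

#' Band magnitude of the membrane potential
#'
#' Zero-phase 4th-order Butterworth bandpass, then the time-averaged
#' analytic-signal (Hilbert) envelope over the window — an amplitude in mV
#' directly comparable across bands.
#'
#' @param trial A spike-removed [vm_trial()].
#' @param band A [band_spec()].
#' @param window Length-2 numeric in s after stimulus onset; `NULL` = whole
#'   trace.
#' @return Mean band envelope in mV.
#' @export
band_magnitude <- function(trial, band = default_bands()$theta,
                           window = NULL) {
  bp <- band_filter_decimated(trial$samples - mean(trial$samples),
                              band$lo, band$hi, trial$sampling_rate)
  env <- Mod(analytic_signal(bp$y))
  if (!is.null(window)) {
    env <- env[window_indices(trial$stim_onset + window[1],
                              trial$stim_onset + window[2], bp$fs,
                              length(env))]
  }
  mean(env)
}

#' Default wavelet frequency grid: 40 log-spaced frequencies, 2--80 Hz
#' @return Numeric vector of frequencies in Hz.
#' @export
wavelet_freqs <- function() exp(seq(log(2), log(80), length.out = 40))

# Cycle count mapped linearly from 3 to 10 across the (log-spaced) grid.
#' @noRd
wavelet_cycles <- function(freqs) {
  if (length(freqs) == 1L) return(6.5)
  seq(3, 10, length.out = length(freqs))
}

# One complex Morlet kernel, amplitude-calibrated: convolving a cosine of
# amplitude A at the kernel's centre frequency yields |W| ~ A.
#' @noRd
morlet_kernel <- function(f, cycles, fs) {
  s <- cycles / (2 * pi * f)
  half <- ceiling(4 * s * fs)
  tt <- (-half:half) / fs
  k <- exp(2i * pi * f * tt) * exp(-tt^2 / (2 * s^2))
  2 * k / (s * sqrt(2 * pi) * fs)
}

#' Complex Morlet wavelet transform of one or more trials
#'
#' Convolves each trace with complex Morlet wavelets on a log-spaced
#' frequency grid (default 2--80 Hz, 40 frequencies) with 3 to 10 cycles
#' mapped linearly across the grid. Traces are reflect-padded, so edges are
#' tapered rather than wrapped. Amplitude calibration is such that a pure
#' tone of amplitude A gives `Mod(W)` of about A at its frequency.
#'
#' @param trials A [vm_trial()] or list of them (equal length/rate).
#' @param freqs Frequency grid in Hz.
#' @param cycles Wavelet cycle counts, recycled along `freqs`.
#' @return A 3-d complex array `trial x freq x time`.
#' @export
wavelet_transform <- function(trials, freqs = wavelet_freqs(),
                              cycles = wavelet_cycles(freqs)) {
  if (inherits(trials, "vm_trial")) trials <- list(trials)
  fs <- trials[[1L]]$sampling_rate
  n <- length(trials[[1L]]$samples)
  cycles <- rep_len(cycles, length(freqs))
  W <- array(complex(real = NA_real_), dim = c(length(trials), length(freqs), n))
  kernels <- lapply(seq_along(freqs), function(j) {
    morlet_kernel(freqs[j], cycles[j], fs)
  })
  for (i in seq_along(trials)) {
    x <- trials[[i]]$samples - mean(trials[[i]]$samples)
    for (j in seq_along(freqs)) {
      k <- kernels[[j]]
      W[i, j, ] <- conv_same_reflect_cplx(x, k)
    }
  }
  dimnames(W) <- list(NULL, signif(freqs, 6), NULL)
  attr(W, "freqs") <- freqs
  attr(W, "times") <- (seq_len(n) - 1L) / fs
  attr(W, "sampling_rate") <- fs
  W
}

# complex-valued counterpart of conv_same_reflect
#' @noRd
conv_same_reflect_cplx <- function(x, k) {
  n <- length(x)
  m <- length(k)
  h <- (m - 1L) %/% 2L
  if (h >= n) stop("wavelet longer than signal; shorten the kernel or trace")
  pad <- c(x[(h + 1L):2L], x, x[(n - 1L):(n - h)])
  np <- length(pad)
  nfft <- stats::nextn(np + m - 1L, 2)
  X <- stats::fft(c(pad, complex(real = numeric(nfft - np))))
  K <- stats::fft(c(k, complex(real = numeric(nfft - m))))
  y <- stats::fft(X * K, inverse = TRUE) / nfft
  y[(2L * h + 1L):(2L * h + n)]
}

#' Wavelet power, optionally dB-normalised to a baseline window
#'
#' Trial-averaged `Mod(W)^2`. With `baseline` given (s after stimulus
#' onset), power is expressed in dB relative to the mean baseline power per
#' frequency, the normalisation used for display spectrograms.
#'
#' @param W Array from [wavelet_transform()].
#' @param baseline Length-2 numeric in s after onset, or `NULL` for raw
#'   power.
#' @param stim_onset Stimulus onset in s (needed with `baseline`).
#' @return Matrix `freq x time`.
#' @export
wavelet_power <- function(W, baseline = NULL, stim_onset = 0) {
  p <- Mod(W)^2
  pm <- apply(p, c(2, 3), mean)
  if (!is.null(baseline)) {
    fs <- attr(W, "sampling_rate")
    idx <- window_indices(stim_onset + baseline[1], stim_onset + baseline[2],
                          fs, ncol(pm))
    ref <- rowMeans(pm[, idx, drop = FALSE])
    pm <- 10 * log10(sweep(pm, 1, ref, "/"))
  }
  pm
}

#' Intertrial phase coherence
#'
#' `ITPC(f, t) = |mean over trials of exp(i * arg W(f, t))|`: 1 when every
#' trial has the same phase at that time-frequency point, approaching 0 for
#' independent phases as the trial count grows.
#'
#' @param W Array from [wavelet_transform()] (needs >= 1 trial).
#' @return Matrix `freq x time` with values in `[0, 1]`.
#' @export
itpc <- function(W) {
  ph <- W / Mod(W)
  ph[Mod(W) == 0] <- 0
  out <- apply(ph, c(2, 3), function(z) Mod(mean(z)))
  pmin(out, 1)
}

#' Oscillation-trial criterion
#'
#' A trial is an oscillation trial when its 4--7 Hz power in the response
#' window (stimulus onset to 0.5 s) exceeds `ratio_threshold` (default 10)
#' times the power of the late baseline (4.5--5 s after onset).
#'
#' @param band A [band_spec()], default 4--7 Hz.
#' @param response,baseline Length-2 windows in s after stimulus onset.
#' @param ratio_threshold Positive ratio threshold.
#' @return An object of class `oscillation_criterion`.
#' @export
oscillation_criterion <- function(band = default_bands()$theta,
                                  response = c(0, 0.5),
                                  baseline = c(4.5, 5.0),
                                  ratio_threshold = 10) {
  stopifnot(ratio_threshold > 0)
  structure(list(band = band, response = response, baseline = baseline,
                 ratio_threshold = ratio_threshold),
            class = "oscillation_criterion")
}

#' Detect oscillation trials
#'
#' Per trial: bandpass the (spike-removed) trace in the criterion band,
#' take mean squared amplitude in the response and baseline windows, flag
#' the trial when the ratio exceeds the threshold. The oscillation
#' probability is the flagged fraction.
#'
#' @param trials List of spike-removed [vm_trial()]s.
#' @param criterion An [oscillation_criterion()].
#' @return List with `ratio` (per trial), `flag` (logical), `probability`.
#' @export
detect_oscillation_trials <- function(trials,
                                      criterion = oscillation_criterion()) {
  if (inherits(trials, "vm_trial")) trials <- list(trials)
  ratio <- vapply(trials, function(tr) {
    bp <- band_filter_decimated(tr$samples - mean(tr$samples),
                                criterion$band$lo, criterion$band$hi,
                                tr$sampling_rate)
    y <- bp$y
    on <- tr$stim_onset
    resp <- y[window_indices(on + criterion$response[1],
                             on + criterion$response[2], bp$fs, length(y))]
    base <- y[window_indices(on + criterion$baseline[1],
                             on + criterion$baseline[2], bp$fs, length(y))]
    pb <- mean(base^2)
    if (pb == 0) Inf else mean(resp^2) / pb
  }, numeric(1))
  flag <- ratio > criterion$ratio_threshold
  list(ratio = ratio, flag = flag, probability = mean(flag))
}
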