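# Trial-level data model and suprathreshold/subthreshold trace analysis.

#' Construct a membrane-potential trial
#'
#' A `vm_trial` holds one whole-cell current-clamp sweep (membrane potential
#' in mV) together with the stimulus metadata every downstream analysis
#' needs: sampling rate, stimulus onset/offset, drift direction, and
#' identifiers.
#'
#' @param samples Numeric vector of membrane potential in mV.
#' @param sampling_rate Sampling rate in Hz (> 0).
#' @param stim_onset Stimulus onset in s from trial start.
#' @param stim_dur Stimulus duration in s.
#' @param direction Drift direction in degrees, or `NA` for single-direction
#'   protocols.
#' @param cell_id,trial_id Identifiers.
#' @param condition Condition label, e.g. `"naive"` or `"experienced"`.
#' @return An object of class `vm_trial`.
#' @export
vm_trial <- function(samples, sampling_rate, stim_onset, stim_dur,
                     direction = NA_real_, cell_id = "cell",
                     trial_id = 1L, condition = NA_character_) {
  samples <- as.numeric(samples)
  if (!all(is.finite(samples))) stop("vm_trial: samples must be finite")
  if (sampling_rate <= 0) stop("vm_trial: sampling_rate must be > 0")
  dur <- length(samples) / sampling_rate
  if (stim_onset < 0 || stim_onset + stim_dur > dur + 1e-9) {
    stop("vm_trial: stimulus window must lie within the trial")
  }
  structure(
    list(samples = samples, sampling_rate = sampling_rate,
         stim_onset = stim_onset, stim_dur = stim_dur,
         direction = direction, cell_id = cell_id, trial_id = trial_id,
         condition = condition),
    class = "vm_trial")
}

#' @export
print.vm_trial <- function(x, ...) {
  cat(sprintf(
    "<vm_trial %s/%s> %.3g s @ %g Hz, stim [%g, %g] s, direction %s, %s\n",
    x$cell_id, x$trial_id, length(x$samples) / x$sampling_rate,
    x$sampling_rate, x$stim_onset, x$stim_onset + x$stim_dur,
    ifelse(is.na(x$direction), "-", paste0(x$direction, "°")),
    x$condition))
  invisible(x)
}

#' Trial duration in seconds
#' @param trial A [vm_trial()].
#' @return Duration in s.
#' @export
trial_duration <- function(trial) length(trial$samples) / trial$sampling_rate

#' Construct a spike train
#'
#' @param times Strictly increasing spike times in s from trial start.
#' @param duration Trial duration in s (used for validation and rate
#'   normalisation).
#' @return An object of class `spike_train`.
#' @export
spike_train <- function(times, duration = NA_real_) {
  times <- as.numeric(times)
  if (length(times) > 1 && any(diff(times) <= 0)) {
    stop("spike_train: times must be strictly increasing")
  }
  if (!is.na(duration) && length(times) &&
      (min(times) < 0 || max(times) > duration)) {
    stop("spike_train: times outside [0, duration]")
  }
  structure(list(times = times, duration = duration), class = "spike_train")
}

#' @export
print.spike_train <- function(x, ...) {
  cat(sprintf("<spike_train> %d spikes over %s s\n", length(x$times),
              format(x$duration)))
  invisible(x)
}

#' Analysis window specification
#'
#' Response and baseline windows, both half-open `[start, end)` and given in
#' seconds relative to stimulus onset. The package defaults follow the
#' single-direction protocol: response 0.05--0.25 s, baseline 2.5--4.7 s.
#'
#' @param response Length-2 numeric, response window (s after onset).
#' @param baseline Length-2 numeric, baseline window (s after onset).
#' @return An object of class `window_spec`.
#' @export
window_spec <- function(response = c(0.05, 0.25), baseline = c(2.5, 4.7)) {
  stopifnot(length(response) == 2, length(baseline) == 2,
            response[1] < response[2], baseline[1] < baseline[2])
  if (max(response[1], baseline[1]) < min(response[2], baseline[2])) {
    stop("window_spec: response and baseline windows overlap")
  }
  structure(list(response = as.numeric(response),
                 baseline = as.numeric(baseline)),
            class = "window_spec")
}

#' Remove action potentials with a running median filter
#'
#' Applies a sliding-window median (default 12.5 ms, rounded up to an odd
#' sample count) with replicated edges, the standard way to strip fast
#' spike transients from an intracellular trace while leaving the slower
#' subthreshold membrane potential intact.
#'
#' @param trial A [vm_trial()].
#' @param window_ms Filter window in ms.
#' @return A [vm_trial()] with the filtered trace.
#' @export
remove_spikes <- function(trial, window_ms = 12.5) {
  x <- trial$samples
  n <- length(x)
  w <- ceiling(window_ms * trial$sampling_rate / 1000)
  if (w %% 2 == 0) w <- w + 1L
  w <- max(w, 3L)
  if (w > n) stop("remove_spikes: window longer than trace")
  h <- (w - 1L) %/% 2L
  padded <- c(rep(x[1L], h), x, rep(x[n], h))
  med <- stats::runmed(padded, w, endrule = "keep")
  out <- trial
  out$samples <- med[(h + 1L):(h + n)]
  out
}

#' Detect action potentials by dual Hanning-window smoothing
#'
#' The trace is smoothed with a fine (default 0.5 ms) and a coarse (default
#' 500 ms) unit-sum Hanning kernel; the coarse trace tracks the slow
#' membrane potential, so their difference is a high-pass estimate in mV.
#' Each contiguous run of the difference exceeding `thresh_mV` yields one
#' spike at the run's maximum (earliest sample on ties).
#'
#' @param trial A [vm_trial()].
#' @param fine_ms,coarse_ms Kernel spans in ms.
#' @param thresh_mV Detection threshold in mV.
#' @return A [spike_train()].
#' @export
detect_spikes <- function(trial, fine_ms = 0.5, coarse_ms = 500,
                          thresh_mV = 15) {
  x <- trial$samples
  if (!all(is.finite(x))) stop("detect_spikes: non-finite samples")
  fs <- trial$sampling_rate
  if (length(x) <= round(coarse_ms * fs / 1000)) {
    stop("detect_spikes: trace shorter than coarse window")
  }
  d <- conv_same_reflect(x, hanning_kernel(fine_ms, fs)) -
    conv_same_reflect(x, hanning_kernel(coarse_ms, fs))
  above <- d > thresh_mV
  if (!any(above)) {
    return(spike_train(numeric(0), trial_duration(trial)))
  }
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  peaks <- vapply(which(r$values), function(j) {
    seg <- starts[j]:ends[j]
    seg[which.max(d[seg])]
  }, integer(1))
  spike_train((peaks - 1L) / fs, trial_duration(trial))
}

#' Peristimulus time histogram with Gaussian smoothing
#'
#' Spike counts in fixed bins (default 10 ms) across trials, expressed as a
#' rate in Hz, then smoothed with a truncated unit-sum Gaussian kernel
#' (default 200 ms span, 40 ms sigma). `normalized_rate` divides the
#' smoothed rate by its per-cell maximum (zero stays zero).
#'
#' @param trains List of [spike_train()]s from one cell.
#' @param duration Trial duration in s; taken from the trains if omitted.
#' @param bin_ms Bin width in ms.
#' @param gauss_win_ms,gauss_sigma_ms Smoothing kernel span and sigma in ms.
#' @return An object of class `psth` with `bin_edges`, `rate`,
#'   `smoothed_rate`, `normalized_rate`, `n_trials`.
#' @export
compute_psth <- function(trains, duration = NULL, bin_ms = 10,
                         gauss_win_ms = 200, gauss_sigma_ms = 40) {
  if (!length(trains)) stop("compute_psth: need at least one trial")
  duration <- duration %||% max(vapply(trains, function(tr) tr$duration,
                                       numeric(1)))
  if (!is.finite(duration)) stop("compute_psth: unknown trial duration")
  bw <- bin_ms / 1000
  edges <- seq(0, duration + bw * 1e-9, by = bw)
  if (edges[length(edges)] < duration - 1e-9) {
    edges <- c(edges, edges[length(edges)] + bw)
  }
  nb <- length(edges) - 1L
  counts <- numeric(nb)
  for (tr in trains) {
    if (length(tr$times)) {
      idx <- findInterval(tr$times, edges, rightmost.closed = FALSE,
                          left.open = FALSE)
      idx <- idx[idx >= 1L & idx <= nb]
      tb <- tabulate(idx, nbins = nb)
      counts <- counts + tb
    }
  }
  n_trials <- length(trains)
  rate <- counts / (n_trials * bw)
  # truncated Gaussian smoothing kernel, unit sum, in bin units
  half_bins <- max(1L, round(gauss_win_ms / 2 / bin_ms))
  tt <- (-half_bins:half_bins) * bin_ms
  g <- exp(-tt^2 / (2 * gauss_sigma_ms^2))
  g <- g / sum(g)
  smoothed <- conv_same_reflect(rate, g)
  mx <- max(smoothed)
  structure(
    list(bin_edges = edges, rate = rate, smoothed_rate = smoothed,
         normalized_rate = if (mx > 0) smoothed / mx else smoothed,
         n_trials = n_trials, bin_ms = bin_ms),
    class = "psth")
}

#' @export
print.psth <- function(x, ...) {
  cat(sprintf("<psth> %d bins of %g ms, %d trials, peak %.3g Hz\n",
              length(x$rate), x$bin_ms, x$n_trials, max(x$smoothed_rate)))
  invisible(x)
}

# Mean firing rate (Hz) of spike trains inside an absolute window [a, b).
#' @noRd
mean_rate_in_window <- function(trains, a, b) {
  counts <- vapply(trains, function(tr) {
    sum(tr$times >= a & tr$times < b)
  }, numeric(1))
  mean(counts) / (b - a)
}

#' Baseline-subtracted firing rate
#'
#' Mean rate in the response window minus mean rate in the baseline window,
#' both averaged across trials; windows are relative to stimulus onset.
#'
#' @param trains List of [spike_train()]s.
#' @param windows A [window_spec()].
#' @param stim_onset Stimulus onset in s from trial start.
#' @return Baseline-subtracted rate in Hz.
#' @export
baseline_subtracted_rate <- function(trains, windows = window_spec(),
                                     stim_onset = 0) {
  r <- mean_rate_in_window(trains, stim_onset + windows$response[1],
                           stim_onset + windows$response[2])
  b <- mean_rate_in_window(trains, stim_onset + windows$baseline[1],
                           stim_onset + windows$baseline[2])
  r - b
}

#' Z-score a PSTH against its baseline window
#'
#' @param psth A [compute_psth()] result.
#' @param baseline Length-2 numeric, baseline window in s (absolute trial
#'   time).
#' @param use Which rate series to z-score: smoothed (default) or raw.
#' @return Numeric vector of z-scores per bin.
#' @export
zscore_rate <- function(psth, baseline, use = c("smoothed", "raw")) {
  use <- match.arg(use)
  x <- if (use == "smoothed") psth$smoothed_rate else psth$rate
  centers <- utils::head(psth$bin_edges, -1) + diff(psth$bin_edges) / 2
  inb <- centers >= baseline[1] & centers < baseline[2]
  if (!any(inb)) stop("zscore_rate: baseline window contains no bins")
  mu <- mean(x[inb])
  sdv <- stats::sd(x[inb])
  if (sdv == 0) stop("zscore_rate: baseline SD is zero")
  (x - mu) / sdv
}

#' Peak baseline-subtracted membrane potential in successive windows
#'
#' For a spike-removed trace, computes per-window `max(Vm) - baseline mean`.
#' The default windows I--III (0.05--0.25, 0.25--0.45, 0.45--0.65 s after
#' onset) each cover one cycle of a 5-Hz oscillation; the default baseline
#' is 2.5--4.7 s after onset.
#'
#' @param trial A spike-removed [vm_trial()].
#' @param windows List of length-2 numeric windows in s after stimulus onset.
#' @param baseline Length-2 numeric baseline in s after stimulus onset.
#' @return Named numeric vector of delta-Vm peaks in mV, one per window.
#' @export
delta_vm_peaks <- function(trial,
                           windows = list(I = c(0.05, 0.25),
                                          II = c(0.25, 0.45),
                                          III = c(0.45, 0.65)),
                           baseline = c(2.5, 4.7)) {
  fs <- trial$sampling_rate
  n <- length(trial$samples)
  on <- trial$stim_onset
  bl <- mean(trial$samples[window_indices(on + baseline[1], on + baseline[2],
                                          fs, n)])
  out <- vapply(windows, function(w) {
    max(trial$samples[window_indices(on + w[1], on + w[2], fs, n)]) - bl
  }, numeric(1))
  names(out) <- names(windows) %||% paste0("w", seq_along(windows))
  out
}
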