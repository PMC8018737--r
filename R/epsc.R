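# Optogenetically evoked EPSC feature extraction and cell-level QC.

#' Construct a voltage-clamp EPSC trial
#'
#' @param current Numeric vector of membrane current in pA (inward
#'   negative).
#' @param sampling_rate Sampling rate in Hz.
#' @param ttl_time Light-pulse onset in s from trace start.
#' @param cell_id Identifier.
#' @param access_resistance Access resistance in MOhm (QC metadata).
#' @param depth Recording depth in micrometres.
#' @param group Group label.
#' @return An object of class `epsc_trial`.
#' @export
epsc_trial <- function(current, sampling_rate, ttl_time,
                       cell_id = "cell", access_resistance = NA_real_,
                       depth = NA_real_, group = NA_character_) {
  current <- as.numeric(current)
  if (sampling_rate <= 0) stop("epsc_trial: sampling_rate must be > 0")
  if (ttl_time < 0 || ttl_time > length(current) / sampling_rate) {
    stop("epsc_trial: ttl_time outside trace")
  }
  structure(
    list(current = current, sampling_rate = sampling_rate,
         ttl_time = ttl_time, cell_id = cell_id,
         access_resistance = access_resistance, depth = depth,
         group = group),
    class = "epsc_trial")
}

#' @export
print.epsc_trial <- function(x, ...) {
  cat(sprintf("<epsc_trial %s> %.3g s @ %g Hz, TTL at %g s, Ra %s MOhm\n",
              x$cell_id, length(x$current) / x$sampling_rate,
              x$sampling_rate, x$ttl_time, format(x$access_resistance)))
  invisible(x)
}

#' Extract EPSC amplitude and latency
#'
#' Baseline is the mean current over the 0.2 s preceding the TTL. The EPSC
#' peak is the largest inward (negative) baseline-subtracted deflection in
#' the 0--40 ms post-TTL window; amplitude is its magnitude in pA. Latency
#' is the first post-TTL crossing of 5% of the amplitude (same, inward,
#' polarity) at or before the peak, in ms. Deflections below the noise
#' floor (default 3 baseline SDs) are reported as non-responses: amplitude
#' 0, latency `NA`.
#'
#' @param trial An [epsc_trial()].
#' @param baseline_dur Baseline duration in s before the TTL.
#' @param peak_window_ms Peak search window in ms after the TTL.
#' @param noise_sd_mult Response criterion: peak must exceed this many
#'   baseline SDs (set 0 to disable).
#' @return An object of class `epsc_features`: `amplitude` (pA, >= 0),
#'   `latency` (ms), `peak_time` (ms after TTL), `baseline` (pA),
#'   `responsive` (logical).
#' @export
extract_epsc <- function(trial, baseline_dur = 0.2, peak_window_ms = 40,
                         noise_sd_mult = 3) {
  fs <- trial$sampling_rate
  x <- trial$current
  n <- length(x)
  t0 <- trial$ttl_time
  if (t0 < baseline_dur) stop("extract_epsc: need >= 0.2 s of pre-TTL data")
  bidx <- window_indices(t0 - baseline_dur, t0, fs, n)
  bl <- mean(x[bidx])
  bl_sd <- stats::sd(x[bidx])
  i_ttl <- floor(t0 * fs + 1e-6) + 1L
  i_end <- min(n, i_ttl + ceiling(peak_window_ms / 1000 * fs))
  seg <- x[(i_ttl + 1L):i_end] - bl
  ipk <- which.min(seg)  # inward = most negative
  peak <- seg[ipk]
  amp <- max(0, -peak)
  if (amp == 0 || (noise_sd_mult > 0 && amp < noise_sd_mult * bl_sd)) {
    return(structure(list(amplitude = 0, latency = NA_real_,
                          peak_time = NA_real_, baseline = bl,
                          responsive = FALSE),
                     class = "epsc_features"))
  }
  cross <- which(seg[seq_len(ipk)] <= -0.05 * amp)[1L]
  structure(
    list(amplitude = amp,
         latency = cross / fs * 1000,
         peak_time = ipk / fs * 1000,
         baseline = bl, responsive = TRUE),
    class = "epsc_features")
}

#' @export
print.epsc_features <- function(x, ...) {
  if (x$responsive) {
    cat(sprintf(
      "<epsc_features> amplitude %.4g pA, latency %.3g ms, peak %.3g ms\n",
      x$amplitude, x$latency, x$peak_time))
  } else {
    cat("<epsc_features> non-responsive (below noise floor)\n")
  }
  invisible(x)
}

#' EPSC features of the trial-averaged trace
#'
#' Averages the current traces of several trials of one cell (the standard
#' 10-sweep protocol) and extracts the features from the mean trace.
#'
#' @param trials List of [epsc_trial()]s with equal length, rate and TTL.
#' @param ... Passed to [extract_epsc()].
#' @return An `epsc_features` object.
#' @export
average_cell_epsc <- function(trials, ...) {
  if (!length(trials)) stop("average_cell_epsc: no trials")
  first <- trials[[1L]]
  mats <- vapply(trials, function(tr) {
    if (length(tr$current) != length(first$current) ||
        tr$sampling_rate != first$sampling_rate ||
        tr$ttl_time != first$ttl_time) {
      stop("average_cell_epsc: trials differ in length, rate or TTL")
    }
    tr$current
  }, numeric(length(first$current)))
  avg <- first
  avg$current <- rowMeans(mats)
  extract_epsc(avg, ...)
}

#' Quality-control filter for EPSC cells
#'
#' Keeps cells with mean EPSC latency below `max_latency_ms` (default
#' 3.5 ms, the monosynaptic criterion) and access resistance at or below
#' `max_ra_mohm` (default 60 MOhm).
#'
#' @param cells List of per-cell records, each a list with at least
#'   `latency` (ms) and `access_resistance` (MOhm).
#' @param max_latency_ms,max_ra_mohm QC thresholds.
#' @return List with `kept` (sub-list of `cells`), `excluded` (sub-list),
#'   and `log` (data.frame of cell, reason).
#' @export
qc_filter_cells <- function(cells, max_latency_ms = 3.5, max_ra_mohm = 60) {
  reasons <- vapply(cells, function(cl) {
    r <- character(0)
    if (!is.na(cl$latency) && cl$latency >= max_latency_ms) {
      r <- c(r, sprintf("latency %.3g ms >= %.3g ms", cl$latency,
                        max_latency_ms))
    }
    if (!is.na(cl$access_resistance) && cl$access_resistance > max_ra_mohm) {
      r <- c(r, sprintf("Ra %.3g MOhm > %.3g MOhm", cl$access_resistance,
                        max_ra_mohm))
    }
    paste(r, collapse = "; ")
  }, character(1))
  keep <- reasons == ""
  ids <- vapply(seq_along(cells), function(i) {
    as.character(cells[[i]]$cell_id %||% i)
  }, character(1))
  list(kept = cells[keep], excluded = cells[!keep],
       log = data.frame(cell_id = ids, kept = keep, reason = reasons,
                        stringsAsFactors = FALSE))
}

#' Membrane resistance from current steps
#'
#' Least-squares slope of steady-state voltage (mV) against injected
#' current (pA), converted to MOhm (1 mV/pA = 1000 MOhm).
#'
#' @param step_currents Injected currents in pA.
#' @param steady_voltages Steady-state voltage responses in mV.
#' @return Membrane resistance in MOhm.
#' @export
membrane_resistance <- function(step_currents, steady_voltages) {
  stopifnot(length(step_currents) == length(steady_voltages),
            length(step_currents) >= 2)
  fit <- stats::lm(steady_voltages ~ step_currents)
  unname(stats::coef(fit)[2L]) * 1000
}
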