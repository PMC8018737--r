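# Orientation/direction selectivity and spike-phase analysis.

#' The 12 drift directions used for tuning protocols
#' @return Numeric vector `0, 30, ..., 330` degrees.
#' @export
tuning_directions <- function() seq(0, 330, by = 30)

#' Construct a tuning dataset
#'
#' Trials of one cell grouped by the 12 drift directions (30 degree steps),
#' each entry pairing a membrane-potential trial with its spike train, plus
#' the response/baseline windows used for rate extraction. The tuning
#' defaults are the 500-ms-stimulus windows: response 0.05--0.55 s,
#' baseline 2.5--3.5 s after onset.
#'
#' @param trials_by_direction Named list (names = directions in degrees),
#'   each element a list of `list(vm = vm_trial or NULL, spikes =
#'   spike_train)`.
#' @param windows A [window_spec()].
#' @param stim_onset Stimulus onset in s from trial start.
#' @param cell_id,condition Metadata.
#' @param ground_truth Optional list with noiseless `osi`, `dsi`,
#'   `pref_direction`, `rate_map` (stored by the synthetic generator).
#' @return An object of class `tuning_dataset`.
#' @export
tuning_dataset <- function(trials_by_direction,
                           windows = window_spec(response = c(0.05, 0.55),
                                                 baseline = c(2.5, 3.5)),
                           stim_onset = 0.5, cell_id = "cell",
                           condition = NA_character_, ground_truth = NULL) {
  dirs <- suppressWarnings(as.numeric(names(trials_by_direction)))
  if (length(dirs) != 12L || anyNA(dirs) ||
      !setequal(dirs, tuning_directions())) {
    stop("tuning_dataset: need trials for all 12 directions 0, 30, ..., 330")
  }
  nt <- vapply(trials_by_direction, length, integer(1))
  if (any(nt < 2L)) {
    stop("tuning_dataset: every direction needs >= 2 trials")
  }
  ord <- order(dirs)
  structure(
    list(trials = trials_by_direction[ord],
         directions = dirs[ord], windows = windows,
         stim_onset = stim_onset, cell_id = cell_id, condition = condition,
         ground_truth = ground_truth),
    class = "tuning_dataset")
}

#' @export
print.tuning_dataset <- function(x, ...) {
  cat(sprintf("<tuning_dataset %s> 12 directions x %s trials, %s\n",
              x$cell_id,
              paste(range(vapply(x$trials, length, integer(1))),
                    collapse = "-"),
              x$condition))
  invisible(x)
}

#' Orientation selectivity index
#'
#' `OSI = (Rpref - Rorth) / (Rpref + Rorth)`.
#'
#' @param r_pref,r_orth Mean response rates (Hz) at the preferred and
#'   orthogonal directions.
#' @return OSI (unitless).
#' @export
osi <- function(r_pref, r_orth) {
  if (r_pref + r_orth == 0) stop("osi: Rpref + Rorth is zero")
  (r_pref - r_orth) / (r_pref + r_orth)
}

#' Direction selectivity index
#'
#' `DSI = (Rpref - Ropp) / (Rpref + Ropp)`.
#'
#' @param r_pref,r_opp Mean response rates (Hz) at the preferred and
#'   opposite directions.
#' @return DSI (unitless).
#' @export
dsi <- function(r_pref, r_opp) {
  if (r_pref + r_opp == 0) stop("dsi: Rpref + Ropp is zero")
  (r_pref - r_opp) / (r_pref + r_opp)
}

# Per-trial baseline-subtracted response rates, as a list of numeric
# vectors indexed like ds$directions.
#' @noRd
trial_rates_by_direction <- function(ds) {
  on <- ds$stim_onset
  rw <- on + ds$windows$response
  bw <- on + ds$windows$baseline
  lapply(ds$trials, function(trs) {
    vapply(trs, function(tr) {
      s <- tr$spikes$times
      sum(s >= rw[1] & s < rw[2]) / diff(ds$windows$response) -
        sum(s >= bw[1] & s < bw[2]) / diff(ds$windows$baseline)
    }, numeric(1))
  })
}

#' Split-half resampled OSI/DSI
#'
#' Each repetition randomly splits the trials of every direction into two
#' halves (odd counts put the extra trial in half 1). Half 1 picks the
#' preferred direction (argmax of baseline-subtracted mean rate, earliest
#' direction on ties); half 2 supplies the rates at that preferred
#' direction, its opposite, and the mean of the two orthogonals, from which
#' OSI and DSI are computed. Repetitions yielding a negative index are
#' discarded for that index (the preferred direction was unreliable); the
#' estimate is the mean over the remaining repetitions.
#'
#' @param ds A [tuning_dataset()].
#' @param n_reps Number of repetitions (default 2000).
#' @param seed Integer seed; the procedure is deterministic given it.
#' @return An object of class `selectivity_result` with `osi`, `dsi`,
#'   `pref_direction` (modal preferred direction over repetitions),
#'   `n_valid_osi`, `n_discarded_osi`, `n_valid_dsi`, `n_discarded_dsi`.
#' @export
split_half_selectivity <- function(ds, n_reps = 2000, seed = 1L) {
  rates <- trial_rates_by_direction(ds)
  nd <- length(rates)
  dirs <- ds$directions
  opp_idx <- match((dirs + 180) %% 360, dirs)
  orth_idx1 <- match((dirs + 90) %% 360, dirs)
  orth_idx2 <- match((dirs + 270) %% 360, dirs)
  nt <- vapply(rates, length, integer(1))
  h1 <- ceiling(nt / 2)
  osi_v <- rep(NA_real_, n_reps)
  dsi_v <- rep(NA_real_, n_reps)
  prefs <- integer(n_reps)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  for (rep_i in seq_len(n_reps)) {
    m1 <- numeric(nd)
    m2 <- numeric(nd)
    for (d in seq_len(nd)) {
      perm <- sample.int(nt[d])
      m1[d] <- mean(rates[[d]][perm[seq_len(h1[d])]])
      m2[d] <- mean(rates[[d]][perm[(h1[d] + 1L):nt[d]]])
    }
    p <- which.max(m1)  # earliest index on ties
    prefs[rep_i] <- p
    r_pref <- m2[p]
    r_opp <- m2[opp_idx[p]]
    r_orth <- (m2[orth_idx1[p]] + m2[orth_idx2[p]]) / 2
    if (r_pref + r_orth != 0) osi_v[rep_i] <- (r_pref - r_orth) / (r_pref + r_orth)
    if (r_pref + r_opp != 0) dsi_v[rep_i] <- (r_pref - r_opp) / (r_pref + r_opp)
  }
  osi_valid <- osi_v[!is.na(osi_v) & osi_v >= 0]
  dsi_valid <- dsi_v[!is.na(dsi_v) & dsi_v >= 0]
  if (!length(osi_valid) || !length(dsi_valid)) {
    stop("split_half_selectivity: all repetitions discarded; selectivity undefined")
  }
  structure(
    list(osi = mean(osi_valid), dsi = mean(dsi_valid),
         pref_direction = dirs[which.max(tabulate(prefs, nd))],
         n_reps = n_reps,
         n_valid_osi = length(osi_valid),
         n_discarded_osi = n_reps - length(osi_valid),
         n_valid_dsi = length(dsi_valid),
         n_discarded_dsi = n_reps - length(dsi_valid)),
    class = "selectivity_result")
}

#' @export
print.selectivity_result <- function(x, ...) {
  cat(sprintf(paste0(
    "<selectivity_result> OSI %.3f (%d/%d reps), DSI %.3f (%d/%d reps), ",
    "pref %g deg\n"),
    x$osi, x$n_valid_osi, x$n_reps, x$dsi, x$n_valid_dsi, x$n_reps,
    x$pref_direction))
  invisible(x)
}

# save/restore the global RNG state so seeded helpers do not clobber the
# caller's stream
#' @noRd
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}
#' @noRd
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Mean response rates of the preferred, opposite and orthogonal classes
#'
#' The preferred direction is the argmax of the baseline-subtracted mean
#' rate over all trials; the orthogonal rate is the mean of the two +/-90
#' degree directions.
#'
#' @param ds A [tuning_dataset()].
#' @return List with `r_pref`, `r_opp`, `r_orth` (Hz) and `pref_direction`
#'   (degrees).
#' @export
response_rates_by_class <- function(ds) {
  rates <- vapply(trial_rates_by_direction(ds), mean, numeric(1))
  dirs <- ds$directions
  p <- which.max(rates)
  opp <- match((dirs[p] + 180) %% 360, dirs)
  o1 <- match((dirs[p] + 90) %% 360, dirs)
  o2 <- match((dirs[p] + 270) %% 360, dirs)
  list(r_pref = rates[[p]], r_opp = rates[[opp]],
       r_orth = (rates[[o1]] + rates[[o2]]) / 2,
       pref_direction = dirs[p], rates = stats::setNames(rates, dirs))
}

#' Spike phases on the 4--7 Hz membrane-potential oscillation
#'
#' Bandpasses the spike-removed trace (zero-phase Butterworth), takes the
#' analytic-signal angle at each spike time inside the response window.
#' Phase 0 is the oscillation peak; negative angles are the rising phase,
#' positive the falling phase.
#'
#' @param trial A spike-removed [vm_trial()].
#' @param spikes A [spike_train()] for the same trial.
#' @param band A [band_spec()], default 4--7 Hz.
#' @param window Length-2 numeric in s after stimulus onset.
#' @param direction_class Optional label (`"preferred"`, `"opposite"`,
#'   `"orthogonal"`).
#' @return An object of class `phase_sample`: list with `phases` (radians
#'   in `(-pi, pi]`) and `direction_class`.
#' @export
spike_phases <- function(trial, spikes, band = default_bands()$theta,
                         window = c(0.05, 0.55),
                         direction_class = NA_character_) {
  bp <- band_filter_decimated(trial$samples - mean(trial$samples),
                              band$lo, band$hi, trial$sampling_rate)
  z <- analytic_signal(bp$y)
  tgrid <- (seq_along(z) - 1L) / bp$fs
  on <- trial$stim_onset
  keep <- spikes$times >= on + window[1] & spikes$times < on + window[2]
  st <- spikes$times[keep]
  # linear interpolation of the complex analytic signal at spike times
  zr <- stats::approx(tgrid, Re(z), xout = st, rule = 2)$y
  zi <- stats::approx(tgrid, Im(z), xout = st, rule = 2)$y
  ph <- Arg(complex(real = zr, imaginary = zi))
  ph[ph <= -pi] <- ph[ph <= -pi] + 2 * pi
  structure(list(phases = ph, direction_class = direction_class),
            class = "phase_sample")
}

#' Phase density histogram
#'
#' Unit-integral density over `(-pi, pi]`.
#'
#' @param sample A [spike_phases()] result, or numeric vector of phases.
#' @param n_bins Number of bins.
#' @return List with `breaks`, `mids`, `density`.
#' @export
phase_histogram <- function(sample, n_bins = 18) {
  ph <- if (inherits(sample, "phase_sample")) sample$phases else sample
  breaks <- seq(-pi, pi, length.out = n_bins + 1L)
  idx <- findInterval(ph, breaks, left.open = TRUE, all.inside = TRUE)
  counts <- tabulate(idx, nbins = n_bins)
  width <- diff(breaks)[1]
  dens <- if (sum(counts)) counts / (sum(counts) * width) else counts
  list(breaks = breaks, mids = breaks[-1] - width / 2, density = dens)
}

#' Circular mean of phase angles
#' @param phases Numeric vector of radians.
#' @return Circular mean in `(-pi, pi]`.
#' @export
circular_mean <- function(phases) Arg(mean(exp(1i * phases)))
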