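# Ground-truth-labelled synthetic recordings. The generator emulates the
# phenomenology the analysis pipeline is built for: naive cells respond to
# the stimulus with a broad depolarisation and a single strong onset burst;
# experienced cells respond with a damped ~5 Hz membrane-potential
# oscillation lasting three to four cycles, fewer onset spikes, and spikes
# phase-locked to the oscillation's rising phase.

#' Synthetic membrane-potential trial parameters
#'
#' Condition defaults: naive cells get a smooth alpha-function
#' depolarisation (8 mV) and an onset-locked burst (30 Hz peak rate,
#' no oscillation); experienced cells get a damped 5-Hz oscillation
#' (5 mV, 3.5 cycles), a smaller depolarisation (2 mV), and
#' oscillation-phase-locked firing (12 Hz during the oscillation,
#' von Mises phase density centred on the rising phase at -pi/4,
#' concentration 2).
#'
#' @param condition `"naive"` or `"experienced"`.
#' @param resting_vm Resting potential in mV.
#' @param noise_sd Membrane-potential noise SD in mV.
#' @param noise_color `"pink"` (1/f-shaped, the default -- awake Vm
#'   fluctuations are dominated by slow synaptic activity) or `"white"`.
#' @param osc_freq Oscillation frequency in Hz.
#' @param osc_amp Oscillation amplitude in mV.
#' @param osc_cycles Damping horizon in cycles (envelope time constant =
#'   `osc_cycles / osc_freq`).
#' @param depol_amp Alpha-function depolarisation amplitude in mV.
#' @param depol_tau Alpha-function time-to-peak in s.
#' @param onset_rate Peak onset-locked firing rate in Hz.
#' @param osc_locked_rate Mean oscillation-locked firing rate in Hz.
#' @param phase_lock_center,phase_lock_kappa Von Mises phase-locking
#'   centre (radians; 0 = oscillation peak, negative = rising phase) and
#'   concentration.
#' @param spike_amp,spike_width Spike template height (mV) and width (ms).
#' @param sampling_rate Sampling rate in Hz (>= 1000).
#' @param stim_onset,stim_dur,trial_dur Stimulus onset, stimulus duration
#'   and trial duration in s.
#' @param seed Integer seed; equal seeds give bitwise-equal trials.
#' @return An object of class `synth_vm_params`.
#' @export
synth_vm_params <- function(condition = c("experienced", "naive"),
                            resting_vm = -65, noise_sd = 2,
                            noise_color = c("pink", "white"),
                            osc_freq = 5,
                            osc_amp = if (condition == "experienced") 5 else 0,
                            osc_cycles = 3.5,
                            depol_amp = if (condition == "experienced") 2 else 8,
                            depol_tau = 0.1,
                            onset_rate = if (condition == "experienced") 8 else 30,
                            osc_locked_rate = if (condition == "experienced") 12 else 0,
                            phase_lock_center = -pi / 4,
                            phase_lock_kappa = 2,
                            spike_amp = 60, spike_width = 2,
                            sampling_rate = 10000,
                            stim_onset = 0.5, stim_dur = 0.2,
                            trial_dur = 6, seed = 1L) {
  condition <- match.arg(condition)
  noise_color <- match.arg(noise_color)
  force(osc_amp); force(depol_amp); force(onset_rate); force(osc_locked_rate)
  p <- list(condition = condition, resting_vm = resting_vm,
            noise_sd = noise_sd, noise_color = noise_color,
            osc_freq = osc_freq, osc_amp = osc_amp,
            osc_cycles = osc_cycles, depol_amp = depol_amp,
            depol_tau = depol_tau, onset_rate = onset_rate,
            osc_locked_rate = osc_locked_rate,
            phase_lock_center = phase_lock_center,
            phase_lock_kappa = phase_lock_kappa,
            spike_amp = spike_amp, spike_width = spike_width,
            sampling_rate = sampling_rate, stim_onset = stim_onset,
            stim_dur = stim_dur, trial_dur = trial_dur,
            seed = as.integer(seed))
  if (p$sampling_rate < 1000) stop("synth_vm_params: sampling_rate must be >= 1000 Hz")
  if (!(p$stim_onset > 0 && p$stim_onset + p$stim_dur < p$trial_dur)) {
    stop("synth_vm_params: need 0 < stim_onset < stim_onset + stim_dur < trial_dur")
  }
  if (p$osc_amp < 0 || p$noise_sd < 0) {
    stop("synth_vm_params: osc_amp and noise_sd must be >= 0")
  }
  structure(p, class = "synth_vm_params")
}

# biexponential spike template: sharp rise, slower decay, peak spike_amp
#' @noRd
spike_template <- function(spike_amp, spike_width_ms, fs) {
  tau_d <- spike_width_ms / 3 / 1000
  tau_r <- tau_d / 4
  tt <- seq(0, 3 * spike_width_ms / 1000, by = 1 / fs)
  v <- exp(-tt / tau_d) - exp(-tt / tau_r)
  spike_amp * v / max(v)
}

#' Generate one synthetic membrane-potential trial
#'
#' Builds `resting + noise + evoked component + spike waveforms`. The
#' experienced evoked component is a damped cosine
#' `osc_amp * exp(-(t - onset) / tau) * cos(2 pi f (t - onset))` with
#' `tau = osc_cycles / osc_freq`; the naive component is an alpha-function
#' depolarisation. Ground-truth spikes are drawn as an inhomogeneous
#' Poisson process: onset-locked (alpha-shaped intensity) for the naive
#' condition, oscillation-locked (envelope times a von Mises density over
#' the instantaneous oscillation phase) for the experienced one. Spike
#' times are sample-aligned; a biexponential spike template is added at
#' each.
#'
#' @param params A [synth_vm_params()].
#' @param direction Drift direction in degrees (metadata only).
#' @param cell_id,trial_id Identifiers.
#' @return List with `trial` (a [vm_trial()]) and `spikes` (the
#'   ground-truth [spike_train()]).
#' @export
generate_vm_trial <- function(params, direction = NA_real_,
                              cell_id = "synth", trial_id = 1L) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(params$seed)
  fs <- params$sampling_rate
  n <- round(params$trial_dur * fs)
  tt <- (seq_len(n) - 1L) / fs
  rel <- tt - params$stim_onset
  after <- rel >= 0

  evoked <- numeric(n)
  if (params$depol_amp != 0) {
    a <- rel[after] / params$depol_tau
    evoked[after] <- evoked[after] +
      params$depol_amp * a * exp(1 - a)
  }
  if (params$osc_amp > 0) {
    tau_env <- params$osc_cycles / params$osc_freq
    evoked[after] <- evoked[after] +
      params$osc_amp * exp(-rel[after] / tau_env) *
        cos(2 * pi * params$osc_freq * rel[after])
  }

  # ground-truth spike times via thinning of an inhomogeneous Poisson
  # process on the sample grid
  intensity <- numeric(n)
  if (params$onset_rate > 0) {
    a <- rel[after] / params$depol_tau
    intensity[after] <- intensity[after] +
      params$onset_rate * a * exp(1 - a)
  }
  if (params$osc_locked_rate > 0 && params$osc_amp > 0) {
    tau_env <- params$osc_cycles / params$osc_freq
    phase <- 2 * pi * params$osc_freq * rel[after]
    vm_dens <- exp(params$phase_lock_kappa *
                     cos(wrap_angle(phase) - params$phase_lock_center))
    vm_dens <- vm_dens / mean(vm_dens)
    intensity[after] <- intensity[after] +
      params$osc_locked_rate * exp(-rel[after] / tau_env) * vm_dens
  }
  p_spike <- pmin(intensity / fs, 1)
  fired <- which(stats::runif(n) < p_spike)
  # enforce a 2-ms refractory period so spike times stay separable
  if (length(fired) > 1L) {
    refrac <- round(0.002 * fs)
    keep <- fired[1L]
    for (i in fired[-1L]) {
      if (i - keep[length(keep)] >= refrac) keep <- c(keep, i)
    }
    fired <- keep
  }
  spike_times <- (fired - 1L) / fs

  x <- params$resting_vm + evoked
  if (params$noise_sd > 0) {
    x <- x + colored_noise(n, params$noise_sd, fs, params$noise_color)
  }
  if (length(fired)) {
    tpl <- spike_template(params$spike_amp, params$spike_width, fs)
    for (i in fired) {
      j <- i:min(n, i + length(tpl) - 1L)
      x[j] <- x[j] + tpl[seq_along(j)]
    }
  }
  trial <- vm_trial(x, fs, params$stim_onset, params$stim_dur,
                    direction = direction, cell_id = cell_id,
                    trial_id = trial_id, condition = params$condition)
  list(trial = trial, spikes = spike_train(spike_times, params$trial_dur))
}

#' Synthetic tuning-dataset parameters
#'
#' The noiseless response-window rate map over drift direction is
#' `R(theta) = base_rate + amp_rate * V(theta)` with
#' `V = O(theta) * (1 + dir_bias cos(delta)) / (1 + dir_bias)`, where
#' `delta` is the angle to the preferred direction and `O` is a von Mises
#' orientation factor `exp(kappa_ori (cos 2 delta - 1))` (`kappa_ori =
#' Inf` collapses it to an indicator of the preferred orientation).
#' Spontaneous firing outside the response window is zero, so the
#' baseline-subtracted estimator targets exactly this map; the stored
#' ground-truth OSI/DSI are the selectivity formulas applied to it.
#'
#' @param pref_direction Preferred direction in degrees.
#' @param base_rate Untuned response rate in Hz.
#' @param amp_rate Tuned rate amplitude in Hz.
#' @param kappa_ori Orientation concentration (may be `Inf`).
#' @param dir_bias Direction bias in `[0, 1]` (1 = no response opposite).
#' @param n_trials_per_dir Trials per direction.
#' @param condition Label.
#' @param seed Integer seed.
#' @return An object of class `synth_tuning_params`.
#' @export
synth_tuning_params <- function(pref_direction = 60, base_rate = 2,
                                amp_rate = 10, kappa_ori = 2,
                                dir_bias = 0.5, n_trials_per_dir = 10,
                                condition = "experienced", seed = 1L) {
  if (base_rate < 0 || amp_rate < 0) {
    stop("synth_tuning_params: rates must be >= 0")
  }
  if (dir_bias < 0 || dir_bias > 1) {
    stop("synth_tuning_params: dir_bias must be in [0, 1]")
  }
  if (n_trials_per_dir < 2) {
    stop("synth_tuning_params: need >= 2 trials per direction")
  }
  structure(list(pref_direction = pref_direction, base_rate = base_rate,
                 amp_rate = amp_rate, kappa_ori = kappa_ori,
                 dir_bias = dir_bias,
                 n_trials_per_dir = as.integer(n_trials_per_dir),
                 condition = condition, seed = as.integer(seed)),
            class = "synth_tuning_params")
}

#' Noiseless tuning rate map
#'
#' @param params A [synth_tuning_params()].
#' @param directions Directions in degrees.
#' @return Response-window rates in Hz at `directions`.
#' @export
tuning_rate_map <- function(params, directions = tuning_directions()) {
  delta <- wrap_angle((directions - params$pref_direction) * pi / 180)
  ori <- if (is.infinite(params$kappa_ori)) {
    as.numeric(abs(wrap_angle(2 * delta)) < 1e-9)
  } else {
    exp(params$kappa_ori * (cos(2 * delta) - 1))
  }
  dirf <- (1 + params$dir_bias * cos(delta)) / (1 + params$dir_bias)
  params$base_rate + params$amp_rate * ori * dirf
}

# ground-truth OSI/DSI from the noiseless map at the 12 directions
#' @noRd
ground_truth_selectivity <- function(params) {
  dirs <- tuning_directions()
  rates <- tuning_rate_map(params, dirs)
  p <- which.max(rates)
  opp <- match((dirs[p] + 180) %% 360, dirs)
  orth <- match(c((dirs[p] + 90) %% 360, (dirs[p] + 270) %% 360), dirs)
  r_orth <- mean(rates[orth])
  list(osi = osi(rates[p], r_orth), dsi = dsi(rates[p], rates[opp]),
       pref_direction = dirs[p],
       rate_map = stats::setNames(rates, dirs))
}

#' Generate a synthetic tuning dataset with ground-truth OSI/DSI
#'
#' Draws `12 x n_trials_per_dir` trials. Spike counts are Poisson with the
#' direction's map rate inside the response window and zero elsewhere;
#' spike times are uniform within the window. With `with_vm = TRUE` each
#' trial also carries a full membrane-potential trace from
#' [generate_vm_trial()] (tuned by scaling the evoked amplitudes with the
#' normalised rate map).
#'
#' @param params A [synth_tuning_params()].
#' @param vm_params A [synth_vm_params()] supplying trace properties and
#'   windows (its condition should match).
#' @param with_vm Generate full membrane-potential traces (slower).
#' @return A [tuning_dataset()] whose `ground_truth` holds the noiseless
#'   `osi`, `dsi`, `pref_direction` and `rate_map`.
#' @export
generate_tuning_dataset <- function(params,
                                    vm_params = synth_vm_params(
                                      params$condition,
                                      stim_dur = 0.5, seed = params$seed),
                                    with_vm = FALSE) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(params$seed)
  dirs <- tuning_directions()
  rates <- tuning_rate_map(params, dirs)
  gt <- ground_truth_selectivity(params)
  windows <- window_spec(response = c(0.05, 0.55), baseline = c(2.5, 3.5))
  on_s <- vm_params$stim_onset
  rw <- on_s + windows$response
  dur <- vm_params$trial_dur
  rel_amp <- rates / max(rates)
  trials <- lapply(seq_along(dirs), function(d) {
    lapply(seq_len(params$n_trials_per_dir), function(i) {
      k <- stats::rpois(1, rates[d] * diff(windows$response))
      st <- sort(stats::runif(k, rw[1], rw[2] - 1e-6))
      st <- st[!duplicated(round(st * vm_params$sampling_rate))]
      vm <- NULL
      if (with_vm) {
        vp <- vm_params
        vp$osc_amp <- vm_params$osc_amp * rel_amp[d]
        vp$depol_amp <- vm_params$depol_amp * rel_amp[d]
        vp$onset_rate <- 0
        vp$osc_locked_rate <- 0
        vp$seed <- params$seed + 7919L * d + i
        vm <- generate_vm_trial(vp, direction = dirs[d],
                                cell_id = params$condition,
                                trial_id = i)$trial
      }
      list(vm = vm, spikes = spike_train(st, dur))
    })
  })
  names(trials) <- dirs
  tuning_dataset(trials, windows = windows, stim_onset = on_s,
                 cell_id = sprintf("%s_synth", params$condition),
                 condition = params$condition, ground_truth = gt)
}

#' Synthetic EPSC parameters
#'
#' @param amplitude Peak magnitude of the inward current in pA (> 0, or 0
#'   for a flat trace).
#' @param latency Time from TTL to the 5%-of-peak crossing, in ms.
#' @param rise_tau,decay_tau Double-exponential time constants in ms
#'   (`0 < rise_tau < decay_tau`).
#' @param noise_sd Gaussian noise SD in pA.
#' @param baseline_dur Pre-TTL baseline duration in s.
#' @param sampling_rate Sampling rate in Hz.
#' @param total_dur Trace duration in s.
#' @param seed Integer seed.
#' @return An object of class `synth_epsc_params`.
#' @export
synth_epsc_params <- function(amplitude = 120, latency = 2,
                              rise_tau = 0.8, decay_tau = 6,
                              noise_sd = 3, baseline_dur = 0.25,
                              sampling_rate = 20000, total_dur = 0.5,
                              seed = 1L) {
  if (amplitude < 0) stop("synth_epsc_params: amplitude must be >= 0")
  if (!(rise_tau > 0 && rise_tau < decay_tau)) {
    stop("synth_epsc_params: need 0 < rise_tau < decay_tau")
  }
  if (latency < 0) stop("synth_epsc_params: latency must be >= 0")
  structure(list(amplitude = amplitude, latency = latency,
                 rise_tau = rise_tau, decay_tau = decay_tau,
                 noise_sd = noise_sd, baseline_dur = baseline_dur,
                 sampling_rate = sampling_rate, total_dur = total_dur,
                 seed = as.integer(seed)),
            class = "synth_epsc_params")
}

# Unit-peak difference of exponentials v(t) = (e^{-t/td} - e^{-t/tr}) / vmax
# and its analytic peak time / 5%-crossing offset (ms).
#' @noRd
epsc_waveform_shape <- function(rise_tau, decay_tau) {
  tp <- rise_tau * decay_tau / (decay_tau - rise_tau) *
    log(decay_tau / rise_tau)
  vmax <- exp(-tp / decay_tau) - exp(-tp / rise_tau)
  v <- function(t) {
    out <- numeric(length(t))
    pos <- t >= 0
    out[pos] <- (exp(-t[pos] / decay_tau) - exp(-t[pos] / rise_tau)) / vmax
    out
  }
  cross5 <- stats::uniroot(function(t) v(t) - 0.05, c(1e-9, tp),
                           tol = 1e-12)$root
  list(v = v, peak_time = tp, cross5 = cross5)
}

#' Generate a synthetic light-evoked EPSC trial
#'
#' A flat baseline followed by a negative-going double-exponential whose
#' peak magnitude equals `amplitude` and whose 5%-of-peak crossing falls
#' exactly `latency` ms after the TTL (the waveform onset is shifted
#' accordingly). Ground truth (amplitude, latency, analytic peak time) is
#' attached.
#'
#' @param params A [synth_epsc_params()].
#' @param cell_id,access_resistance,depth,group Metadata forwarded to
#'   [epsc_trial()].
#' @return List with `trial` (an [epsc_trial()]) and `ground_truth`
#'   (amplitude pA, latency ms, peak_time ms after TTL).
#' @export
generate_epsc_trial <- function(params, cell_id = "synth",
                                access_resistance = 20, depth = 300,
                                group = "naive") {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(params$seed)
  fs <- params$sampling_rate
  n <- round(params$total_dur * fs)
  tt_ms <- ((seq_len(n) - 1L) / fs - params$baseline_dur) * 1000
  x <- numeric(n)
  gt_peak <- NA_real_
  if (params$amplitude > 0) {
    sh <- epsc_waveform_shape(params$rise_tau, params$decay_tau)
    onset_ms <- params$latency - sh$cross5
    x <- -params$amplitude * sh$v(tt_ms - onset_ms)
    gt_peak <- onset_ms + sh$peak_time
  }
  if (params$noise_sd > 0) {
    x <- x + colored_noise(n, params$noise_sd, fs, params$noise_color)
  }
  trial <- epsc_trial(x, fs, ttl_time = params$baseline_dur,
                      cell_id = cell_id,
                      access_resistance = access_resistance,
                      depth = depth, group = group)
  list(trial = trial,
       ground_truth = list(amplitude = params$amplitude,
                           latency = if (params$amplitude > 0)
                             params$latency else NA_real_,
                           peak_time = gt_peak))
}

#' Generate a population of synthetic cells
#'
#' Per-cell parameters are jittered around the condition defaults
#' (oscillation amplitude, rates, resting potential), each cell receiving
#' a derived seed, so the population is deterministic under `seed`.
#'
#' @param condition `"naive"` or `"experienced"`.
#' @param n_cells Number of cells.
#' @param n_trials Trials per cell.
#' @param seed Integer seed.
#' @param ... Overrides passed to [synth_vm_params()].
#' @return List of cells; each cell is a list with `cell_id`, `condition`,
#'   `params`, and `trials` (list of `list(trial, spikes)` from
#'   [generate_vm_trial()]).
#' @export
generate_cell_population <- function(condition = c("experienced", "naive"),
                                     n_cells = 10, n_trials = 10,
                                     seed = 1L, ...) {
  condition <- match.arg(condition)
  if (n_cells == 0) return(list())
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  jit <- function(x, frac = 0.2) x * stats::runif(1, 1 - frac, 1 + frac)
  lapply(seq_len(n_cells), function(ci) {
    base <- synth_vm_params(condition, ...)
    base$osc_amp <- jit(base$osc_amp)
    base$depol_amp <- jit(base$depol_amp)
    base$onset_rate <- jit(base$onset_rate)
    base$osc_locked_rate <- jit(base$osc_locked_rate)
    base$resting_vm <- base$resting_vm + stats::rnorm(1, sd = 2)
    trials <- lapply(seq_len(n_trials), function(ti) {
      p <- base
      p$seed <- as.integer((seed + 104729 * ci + ti) %% .Machine$integer.max)
      generate_vm_trial(p, cell_id = sprintf("%s_%02d", condition, ci),
                        trial_id = ti)
    })
    list(cell_id = sprintf("%s_%02d", condition, ci), condition = condition,
         params = base, trials = trials)
  })
}
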