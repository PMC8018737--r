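test_that("generators are deterministic under seed and respect the all-off contract", {
  p <- synth_vm_params("experienced", seed = 123)
  g1 <- generate_vm_trial(p)
  g2 <- generate_vm_trial(p)
  expect_identical(g1$trial$samples, g2$trial$samples)
  expect_identical(g1$spikes$times, g2$spikes$times)

  off <- synth_vm_params("naive", noise_sd = 0, osc_amp = 0, depol_amp = 0,
                         onset_rate = 0, osc_locked_rate = 0,
                         sampling_rate = 1000, seed = 1)
  g0 <- generate_vm_trial(off)
  expect_true(all(g0$trial$samples == off$resting_vm))
  expect_length(g0$spikes$times, 0)

  e1 <- generate_epsc_trial(synth_epsc_params(seed = 9))
  e2 <- generate_epsc_trial(synth_epsc_params(seed = 9))
  expect_identical(e1$trial$current, e2$trial$current)

  t1 <- generate_tuning_dataset(synth_tuning_params(seed = 4))
  t2 <- generate_tuning_dataset(synth_tuning_params(seed = 4))
  expect_identical(lapply(t1$trials, function(d) lapply(d, `[[`, "spikes")),
                   lapply(t2$trials, function(d) lapply(d, `[[`, "spikes")))
})

test_that("generator parameter validation rejects bad windows and rates", {
  expect_error(synth_vm_params(stim_onset = 5, stim_dur = 2, trial_dur = 6),
               "trial_dur")
  expect_error(synth_vm_params(sampling_rate = 200), "1000")
  expect_error(synth_tuning_params(dir_bias = 1.5), "dir_bias")
  expect_error(synth_epsc_params(rise_tau = 5, decay_tau = 2), "rise_tau")
})

test_that("experienced traces carry >10x band power in the response window (FFT oracle)", {
  p <- synth_vm_params("experienced", noise_sd = 0, osc_amp = 5,
                       depol_amp = 0, onset_rate = 0, osc_locked_rate = 0,
                       sampling_rate = 1000, seed = 1)
  g <- generate_vm_trial(p)
  x <- g$trial$samples
  fs <- 1000
  band_power_fft <- function(seg) {
    seg <- seg - mean(seg)
    n <- length(seg)
    P <- Mod(fft(seg))^2 / n^2
    f <- (0:(n - 1)) * fs / n
    sum(P[f >= 4 & f <= 7 | f >= fs - 7 & f <= fs - 4])
  }
  resp <- x[window_indices(0.5, 1.0, fs, length(x))]
  base <- x[window_indices(5.0, 5.5, fs, length(x))]
  expect_gt(band_power_fft(resp), 10 * max(band_power_fft(base), 1e-12))
})

test_that("noiseless experienced traces have their dominant response frequency at osc_freq", {
  for (f0 in c(4, 5, 6)) {
    p <- synth_vm_params("experienced", noise_sd = 0, osc_freq = f0,
                         depol_amp = 0, onset_rate = 0,
                         osc_locked_rate = 0, sampling_rate = 1000,
                         seed = 1)
    g <- generate_vm_trial(p)
    ps <- power_spectrum(g$trial, window = c(0, 1))
    f_peak <- ps$freq[which.max(ps$power)]
    expect_lt(abs(f_peak - f0), 1.01)  # one FFT bin of the 1-s window
  }
})

test_that("experienced ground-truth spikes are phase-locked to the rising phase", {
  p <- synth_vm_params("experienced", noise_sd = 0, osc_locked_rate = 40,
                       onset_rate = 0, depol_amp = 0, seed = 6,
                       sampling_rate = 1000)
  g <- generate_vm_trial(p)
  ph <- spike_phases(remove_spikes(g$trial), g$spikes, window = c(0, 0.8))
  expect_gt(length(ph$phases), 10)
  # damping of the oscillation advances the analytic phase slightly, so
  # the concentration is near, not exactly at, the programmed centre
  expect_lt(abs(circular_mean(ph$phases) - (-pi / 4)), 0.65)
})

test_that("tuning ground truth equals the closed-form map selectivity", {
  # oracle: evaluate the von Mises rate map directly and apply the formulas
  p <- synth_tuning_params(kappa_ori = 2, dir_bias = 0.5, base_rate = 2,
                           amp_rate = 10, pref_direction = 60)
  dirs <- tuning_directions()
  delta <- (dirs - 60) * pi / 180
  delta <- atan2(sin(delta), cos(delta))
  rates <- 2 + 10 * exp(2 * (cos(2 * delta) - 1)) *
    (1 + 0.5 * cos(delta)) / 1.5
  i <- which.max(rates)
  r_orth <- mean(rates[dirs %in% c((dirs[i] + 90) %% 360,
                                   (dirs[i] + 270) %% 360)])
  r_opp <- rates[dirs == (dirs[i] + 180) %% 360]
  ds <- generate_tuning_dataset(p)
  expect_equal(ds$ground_truth$osi, (rates[i] - r_orth) / (rates[i] + r_orth))
  expect_equal(ds$ground_truth$dsi, (rates[i] - r_opp) / (rates[i] + r_opp))
  expect_equal(ds$ground_truth$pref_direction, 60)

  flat <- generate_tuning_dataset(synth_tuning_params(amp_rate = 0))
  expect_equal(flat$ground_truth$osi, 0)
  expect_equal(flat$ground_truth$dsi, 0)

  onehot <- generate_tuning_dataset(synth_tuning_params(
    base_rate = 0, dir_bias = 1, kappa_ori = Inf))
  expect_equal(onehot$ground_truth$osi, 1)
  expect_equal(onehot$ground_truth$dsi, 1)
})

test_that("synthetic EPSC waveform places the analytic peak and 5% crossing where promised", {
  for (lat in c(1, 2, 3.2)) {
    p <- synth_epsc_params(amplitude = 150, latency = lat, noise_sd = 0,
                           seed = 1)
    g <- generate_epsc_trial(p)
    feat <- extract_epsc(g$trial)
    expect_lt(abs(feat$amplitude - 150) / 150, 0.01)
    expect_lt(abs(feat$latency - lat), 0.2)
  }
  zero <- generate_epsc_trial(synth_epsc_params(amplitude = 0, noise_sd = 0))
  expect_true(all(zero$trial$current == 0))
  expect_equal(zero$ground_truth$amplitude, 0)
})

test_that("cell populations are deterministic, sized, and condition-separable", {
  expect_length(generate_cell_population("naive", n_cells = 0), 0)

  p1 <- generate_cell_population("experienced", n_cells = 3, n_trials = 2,
                                 seed = 5, sampling_rate = 1000)
  p2 <- generate_cell_population("experienced", n_cells = 3, n_trials = 2,
                                 seed = 5, sampling_rate = 1000)
  expect_identical(p1[[1]]$trials[[1]]$trial$samples,
                   p2[[1]]$trials[[1]]$trial$samples)

  osc_prob <- function(pop) {
    mean(vapply(pop, function(cell) {
      clean <- lapply(cell$trials, function(tt) remove_spikes(tt$trial))
      detect_oscillation_trials(clean)$probability
    }, numeric(1)))
  }
  pe <- generate_cell_population("experienced", n_cells = 5, n_trials = 4,
                                 seed = 2, sampling_rate = 1000)
  pn <- generate_cell_population("naive", n_cells = 5, n_trials = 4,
                                 seed = 2, sampling_rate = 1000)
  expect_gt(osc_prob(pe), osc_prob(pn))
})
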