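test_that("median-filter spike removal preserves constants, ramps, and matches a naive sliding median", {
  const <- flat_trial(-65)
  expect_equal(remove_spikes(const)$samples, const$samples)

  ramp <- vm_trial(seq(-70, -50, length.out = 6000), 1000, 0.5, 0.2)
  filtered <- remove_spikes(ramp)
  w <- ceiling(12.5 * 1000 / 1000)
  if (w %% 2 == 0) w <- w + 1
  h <- (w - 1) / 2
  interior <- (h + 1):(6000 - h)
  expect_equal(filtered$samples[interior], ramp$samples[interior])

  # oracle equivalence on random small traces
  set.seed(42)
  for (i in 1:10) {
    n <- sample(100:300, 1)
    x <- cumsum(rnorm(n))
    tr <- vm_trial(x, 1000, 0.01, 0.05)
    expect_equal(remove_spikes(tr, window_ms = 15)$samples,
                 naive_sliding_median(x, 15), tolerance = 1e-12)
  }
})

test_that("median filter strips a 2-ms spike from a flat baseline", {
  fs <- 20000
  x <- numeric(fs)  # 1 s of 0 mV
  spike_idx <- 10000:(10000 + 0.002 * fs)
  x[spike_idx] <- 50 * sin(seq(0, pi, length.out = length(spike_idx)))
  tr <- vm_trial(x, fs, 0.1, 0.2)
  expect_lt(max(abs(remove_spikes(tr)$samples)), 1)
})

test_that("remove_spikes rejects windows longer than the trace", {
  tr <- vm_trial(rnorm(50), 1000, 0.001, 0.01)
  expect_error(remove_spikes(tr, window_ms = 100), "window longer")
})

test_that("spike detection finds ground-truth spikes and nothing else", {
  expect_length(detect_spikes(flat_trial(-65, fs = 2000))$times, 0)

  p <- synth_vm_params("naive", onset_rate = 60, noise_sd = 1,
                       noise_color = "white", seed = 5)
  g <- generate_vm_trial(p)
  det <- detect_spikes(g$trial)
  expect_length(det$times, length(g$spikes$times))
  expect_lt(max(abs(det$times - g$spikes$times)), 5e-4)

  # slow 10-mV subthreshold bump never crosses the 15-mV high-pass threshold
  fs <- 10000
  x <- rep(-65, fs)
  bump <- seq_len(0.05 * fs)
  x[5000 + bump] <- -65 + 10 * sin(seq(0, pi, length.out = length(bump)))
  expect_length(detect_spikes(vm_trial(x, fs, 0.1, 0.2))$times, 0)
})

test_that("spike detection is translation-equivariant", {
  fs <- 10000
  x <- rep(0, 3 * fs)
  tpl_at <- c(8000, 15000, 22000)
  for (i in tpl_at) x[i + 0:20] <- 60 * exp(-(0:20) / 5)
  t1 <- detect_spikes(vm_trial(x, fs, 0.1, 0.2))$times
  k <- 37
  t2 <- detect_spikes(vm_trial(c(rep(0, k), x[1:(length(x) - k)]),
                               fs, 0.1, 0.2))$times
  expect_equal(t2, t1 + k / fs, tolerance = 1e-12)
})

test_that("PSTH bins, conserves counts, and recovers a constant rate", {
  empty <- compute_psth(list(spike_train(numeric(0), 6)), duration = 6)
  expect_true(all(empty$rate == 0))
  expect_true(all(empty$normalized_rate == 0))

  trains <- replicate(10, spike_train(0.105, 6), simplify = FALSE)
  ps <- compute_psth(trains, duration = 6)
  bin <- findInterval(0.105, ps$bin_edges)
  expect_equal(ps$rate[bin], 100)  # 10 spikes / (10 trials x 10 ms)

  # count conservation on random Poisson trains (pre-smoothing)
  set.seed(7)
  trains <- lapply(1:20, function(i) {
    spike_train(sort(runif(rpois(1, 30), 0, 6)), 6)
  })
  total <- sum(vapply(trains, function(tr) length(tr$times), numeric(1)))
  ps <- compute_psth(trains, duration = 6)
  expect_equal(sum(ps$rate) * 0.01 * 20, total)

  # homogeneous 20 Hz Poisson, 200 trials: smoothed interior within 10%
  set.seed(8)
  trains <- lapply(1:200, function(i) {
    spike_train(sort(runif(rpois(1, 20 * 6), 0, 6)), 6)
  })
  ps <- compute_psth(trains, duration = 6)
  interior <- 30:(length(ps$smoothed_rate) - 30)
  expect_true(all(abs(ps$smoothed_rate[interior] - 20) < 2))
})

test_that("baseline-subtracted rate is near zero for stationary trains and equals the response rate for onset-only firing", {
  set.seed(9)
  trains <- lapply(1:100, function(i) {
    spike_train(sort(runif(rpois(1, 10 * 6), 0, 6)), 6)
  })
  w <- window_spec(response = c(0.05, 0.25), baseline = c(2.5, 4.7))
  expect_lt(abs(baseline_subtracted_rate(trains, w, stim_onset = 0.5)), 2)

  trains <- replicate(10, spike_train(c(0.6, 0.62, 0.65), 6),
                      simplify = FALSE)
  r <- baseline_subtracted_rate(trains, w, stim_onset = 0.5)
  expect_equal(r, 3 / 0.2)
})

test_that("z-scoring centres on the baseline and flags degenerate baselines", {
  set.seed(10)
  trains <- lapply(1:50, function(i) {
    spike_train(sort(c(runif(rpois(1, 30), 0, 6), runif(10, 0.55, 0.65))), 6)
  })
  ps <- compute_psth(trains, duration = 6)
  z <- zscore_rate(ps, baseline = c(3, 5))
  centers <- head(ps$bin_edges, -1) + 0.005
  expect_lt(abs(mean(z[centers >= 3 & centers < 5])), 1e-10)
  expect_gt(max(z[centers > 0.5 & centers < 0.8]), max(z[centers >= 3]))

  ps0 <- compute_psth(list(spike_train(numeric(0), 6)), duration = 6)
  expect_error(zscore_rate(ps0, baseline = c(3, 5)), "SD is zero")
})

test_that("delta-Vm peaks track the oscillation envelope per cycle window", {
  expect_equal(unname(delta_vm_peaks(flat_trial(-65))), c(0, 0, 0))

  # 5-Hz cosine from onset: each 0.2-s window contains one full cycle peak
  tr <- sine_trial(freq = 5, amp = 4, fs = 1000, dur = 6, onset = 0.5)
  tr$samples[1:500] <- 0  # quiet pre-stimulus part; baseline windows are late
  pk <- delta_vm_peaks(tr)
  expect_equal(unname(pk[1]), 4, tolerance = 0.05)
  expect_equal(unname(pk[2]), 4, tolerance = 0.05)

  # naive synthetic: alpha-function depolarisation decays across windows
  p <- synth_vm_params("naive", noise_sd = 0, onset_rate = 0, seed = 1)
  g <- generate_vm_trial(p)
  pk <- delta_vm_peaks(g$trial)
  expect_gt(pk[["I"]], pk[["III"]])
})
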