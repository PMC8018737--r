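test_that("power spectrum is Parseval-consistent and peaks at the tone frequency", {
  fs <- 1000
  tr <- sine_trial(freq = 5, amp = 3, fs = fs, dur = 6, onset = 0.5)
  ps <- power_spectrum(tr, window = c(0, 2))  # integer cycles of 5 Hz
  expect_equal(ps$freq[which.max(ps$power)], 5)
  expect_equal(max(ps$power), 3^2 / 2, tolerance = 1e-6)
  x <- tr$samples[window_indices(0.5, 2.5, fs, length(tr$samples))]
  expect_equal(sum(ps$power), mean((x - mean(x))^2), tolerance = 1e-9)

  dc <- power_spectrum(flat_trial(-70))
  expect_true(all(dc$power[dc$freq > 0] == 0))
})

test_that("white-noise spectra are flat on average", {
  set.seed(3)
  fs <- 500
  agg <- 0
  for (i in 1:100) {
    tr <- vm_trial(rnorm(fs * 2), fs, 0.1, 0.2)
    agg <- agg + power_spectrum(tr)$power
  }
  agg <- agg / 100
  inner <- agg[-c(1, length(agg))]
  expect_lt(max(inner) / min(inner), 3)
  expect_equal(mean(inner) * length(agg), 1, tolerance = 0.05)
})

test_that("band magnitude recovers sinusoid amplitude in-band, rejects out-of-band, ignores DC", {
  tr <- sine_trial(freq = 5, amp = 3, fs = 10000, dur = 6)
  expect_equal(band_magnitude(tr, default_bands()$theta, window = c(0.5, 3.5)),
               3, tolerance = 0.05)
  expect_lt(band_magnitude(tr, default_bands()$beta, window = c(0.5, 3.5)),
            0.3)
  expect_equal(band_magnitude(flat_trial(0)), 0, tolerance = 1e-9)
  shifted <- tr
  shifted$samples <- shifted$samples - 65
  expect_equal(band_magnitude(shifted, window = c(0.5, 3.5)),
               band_magnitude(tr, window = c(0.5, 3.5)), tolerance = 1e-5)
})

test_that("wavelet power localises tones, scales quadratically, and reproduces its own envelope on impulses", {
  fs <- 500
  tr <- sine_trial(freq = 10, amp = 2, fs = fs, dur = 4)
  W <- wavelet_transform(tr)
  freqs <- attr(W, "freqs")
  pw <- wavelet_power(W)
  mid <- window_indices(1, 3, fs, dim(W)[3])
  prof <- rowMeans(pw[, mid])
  expect_equal(freqs[which.max(prof)],
               freqs[which.min(abs(freqs - 10))])

  tr2 <- tr
  tr2$samples <- 3 * tr2$samples
  W2 <- wavelet_transform(tr2)
  expect_equal(wavelet_power(W2)[, mid], 9 * pw[, mid], tolerance = 1e-9)

  # impulse: |W(f, t)| is the wavelet's own Gaussian envelope
  x <- numeric(2 * fs)
  x[fs] <- 1
  Wi <- wavelet_transform(vm_trial(x, fs, 0.1, 0.2),
                          freqs = 10, cycles = 5)
  prof_t <- Mod(Wi[1, 1, ])
  s <- 5 / (2 * pi * 10)
  tt <- ((seq_len(2 * fs)) - fs) / fs
  expected <- 2 / (s * sqrt(2 * pi) * fs) * exp(-tt^2 / (2 * s^2))
  expect_gt(stats::cor(prof_t, expected), 0.9999)
})

test_that("ITPC is 1 for identical trials, bounded, and vanishes for random phases", {
  fs <- 250
  base <- sine_trial(freq = 5, amp = 2, fs = fs, dur = 2, onset = 0.5)
  W <- wavelet_transform(replicate(5, base, simplify = FALSE))
  it <- itpc(W)
  expect_lt(max(abs(it - 1)), 1e-12)

  W1 <- wavelet_transform(base)
  expect_lt(max(abs(itpc(W1) - 1)), 1e-12)

  set.seed(11)
  trials <- lapply(1:300, function(i) {
    sine_trial(freq = 5, amp = 2, fs = fs, dur = 2, onset = 0.5,
               phase = runif(1, -pi, pi))
  })
  Wr <- wavelet_transform(trials, freqs = c(5, 20), cycles = c(4, 6))
  itr <- itpc(Wr)
  expect_true(all(itr >= 0 & itr <= 1))
  interior <- window_indices(0.4, 1.6, fs, dim(Wr)[3])
  expect_lt(mean(itr[1, interior]), 0.15)
})

test_that("oscillation-trial detector flags strong band ratios and passes stationary signals", {
  fs <- 1000
  # noiseless oscillation in response window, near-silent baseline
  tt <- (0:(6 * fs - 1)) / fs
  x <- ifelse(tt >= 0.5 & tt < 1.0, 5 * sin(2 * pi * 5 * (tt - 0.5)), 0)
  osc_tr <- vm_trial(x, fs, 0.5, 0.2)
  res <- detect_oscillation_trials(list(osc_tr))
  expect_true(res$flag[1])

  # stationary sinusoid: response and baseline powers match, ratio about 1
  steady <- sine_trial(freq = 5, amp = 3, fs = fs, dur = 6, onset = 0.5)
  res2 <- detect_oscillation_trials(list(steady))
  expect_equal(res2$ratio[1], 1, tolerance = 0.1)
  expect_false(res2$flag[1])

  # stationary pink noise: low false-positive rate
  trials <- lapply(1:200, function(i) {
    p <- synth_vm_params("naive", depol_amp = 0, onset_rate = 0,
                         sampling_rate = 1000, seed = 5000 + i)
    generate_vm_trial(p)$trial
  })
  res3 <- detect_oscillation_trials(trials)
  expect_lt(res3$probability, 0.05)
})

test_that("wavelet and periodogram agree on dominant frequency of single tones", {
  fs <- 500
  for (f0 in c(3, 8.5, 21, 47)) {
    tr <- sine_trial(freq = f0, amp = 1, fs = fs, dur = 4, onset = 0.5)
    ps <- power_spectrum(tr, window = c(0, 3))
    f_fft <- ps$freq[which.max(ps$power)]
    W <- wavelet_transform(tr)
    freqs <- attr(W, "freqs")
    mid <- window_indices(1, 3, fs, dim(W)[3])
    f_wav <- freqs[which.max(rowMeans(wavelet_power(W)[, mid]))]
    # both land on their grid point nearest the tone
    expect_lt(abs(f_fft - f0), 0.5)
    expect_equal(f_wav, freqs[which.min(abs(freqs - f0))])
  }
})
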