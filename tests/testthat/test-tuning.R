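test_that("selectivity index formulas and guards", {
  expect_equal(osi(10, 0), 1)
  expect_equal(osi(7, 7), 0)
  expect_equal(dsi(8, 2), 0.6)
  expect_error(osi(0, 0), "zero")
  expect_error(dsi(0, 0), "zero")
})

test_that("split-half selectivity is exact for a cell firing at one direction only", {
  counts <- rep(0, 12)
  counts[which(tuning_directions() == 90)] <- 6
  ds <- counts_dataset(counts, n_trials = 6)
  sel <- split_half_selectivity(ds, n_reps = 200, seed = 4)
  expect_equal(sel$osi, 1)
  expect_equal(sel$dsi, 1)
  expect_equal(sel$n_discarded_osi, 0)
  expect_equal(sel$n_discarded_dsi, 0)
  expect_equal(sel$pref_direction, 90)
})

test_that("split-half selectivity matches an independent Monte-Carlo oracle on a flat noisy cell", {
  set.seed(21)
  dirs <- tuning_directions()
  trials <- lapply(seq_along(dirs), function(d) {
    lapply(1:10, function(i) {
      k <- rpois(1, 4)
      st <- sort(runif(k, 0.56, 1.04))
      list(vm = NULL, spikes = spike_train(st, 6))
    })
  })
  names(trials) <- dirs
  ds <- tuning_dataset(trials, stim_onset = 0.5)
  sel <- split_half_selectivity(ds, n_reps = 2000, seed = 31)
  orc <- splithalf_oracle(ds, n_reps = 4000, seed = 32)
  # flat tuning: truncated-null expectation, small and positive
  expect_gt(sel$osi, 0)
  expect_lt(sel$osi, 0.5)
  expect_lt(abs(sel$osi - orc$osi), 0.05)
  expect_lt(abs(sel$dsi - orc$dsi), 0.05)
  # conservation of repetition counts
  expect_equal(sel$n_valid_osi + sel$n_discarded_osi, sel$n_reps)
  expect_equal(sel$n_valid_dsi + sel$n_discarded_dsi, sel$n_reps)
})

test_that("split-half recovers ground-truth selectivity of a tuned synthetic cell", {
  # configure the generator for ground truth OSI 0.6, DSI 0.4:
  # Rpref = base + amp; Ropp = base + amp (1 - b)/(1 + b); solve b, then
  # kappa_ori for the orthogonal ratio
  base <- 3
  amp <- 30
  r_opp_target <- (base + amp) * (1 - 0.4) / (1 + 0.4)
  ratio <- (r_opp_target - base) / amp
  b <- (1 - ratio) / (1 + ratio)
  kap <- solve_kappa_for_osi(0.6, dir_bias = b, base_rate = base,
                             amp_rate = amp)
  errs_o <- errs_d <- numeric(3)
  for (i in 1:3) {
    tp <- synth_tuning_params(kappa_ori = kap, dir_bias = b,
                              base_rate = base, amp_rate = amp,
                              n_trials_per_dir = 20, seed = i)
    ds <- generate_tuning_dataset(tp)
    expect_equal(ds$ground_truth$osi, 0.6, tolerance = 1e-6)
    expect_equal(ds$ground_truth$dsi, 0.4, tolerance = 1e-6)
    sel <- split_half_selectivity(ds, n_reps = 2000, seed = 100 + i)
    expect_true(sel$osi >= 0 && sel$osi <= 1)
    expect_true(sel$dsi >= 0 && sel$dsi <= 1)
    errs_o[i] <- sel$osi - ds$ground_truth$osi
    errs_d[i] <- sel$dsi - ds$ground_truth$dsi
  }
  expect_lt(abs(mean(errs_o)), 0.05)
  expect_lt(abs(mean(errs_d)), 0.05)
})

test_that("split-half estimate is deterministic under seed and stable under trial relabeling", {
  tp <- synth_tuning_params(n_trials_per_dir = 8, seed = 6)
  ds <- generate_tuning_dataset(tp)
  s1 <- split_half_selectivity(ds, n_reps = 400, seed = 9)
  s2 <- split_half_selectivity(ds, n_reps = 400, seed = 9)
  expect_identical(s1, s2)

  ds_perm <- ds
  set.seed(77)
  for (d in seq_along(ds_perm$trials)) {
    ds_perm$trials[[d]] <- ds_perm$trials[[d]][sample(length(ds_perm$trials[[d]]))]
  }
  s3 <- split_half_selectivity(ds_perm, n_reps = 2000, seed = 9)
  s4 <- split_half_selectivity(ds, n_reps = 2000, seed = 9)
  expect_lt(abs(s3$osi - s4$osi), 0.03)
  expect_lt(abs(s3$dsi - s4$dsi), 0.03)
})

test_that("response-class rates classify preferred, opposite and orthogonal correctly", {
  counts <- rep(0, 12)
  counts[which(tuning_directions() == 60)] <- 8
  ds <- counts_dataset(counts)
  cls <- response_rates_by_class(ds)
  expect_equal(cls$pref_direction, 60)
  expect_equal(cls$r_pref, 8 / 0.5)
  expect_equal(cls$r_opp, 0)
  expect_equal(cls$r_orth, 0)

  uni <- counts_dataset(rep(5, 12))
  cls2 <- response_rates_by_class(uni)
  expect_equal(cls2$r_pref, cls2$r_opp)
  expect_equal(cls2$r_pref, cls2$r_orth)
})

test_that("spike phases follow the analytic-signal convention on a pure 5-Hz tone", {
  fs <- 1000
  tr <- sine_trial(freq = 5, amp = 3, fs = fs, dur = 6, onset = 0.5)
  # working-rate phase increment of the decimated band filter
  fs_w <- fs / max(1, floor(fs / (50 * 7)))
  tol <- 2 * pi * 5 / fs_w
  peaks <- 0.5 + (3:5) / 5              # cosine peaks
  troughs <- 0.5 + (3:5) / 5 + 0.1      # half period later
  rising <- 0.5 + (3:5) / 5 - 0.05      # quarter period before a peak
  win <- c(0.05, 5)
  ph_peak <- spike_phases(tr, spike_train(peaks, 6), window = win)$phases
  expect_lt(max(abs(ph_peak)), tol)
  ph_trough <- spike_phases(tr, spike_train(troughs, 6), window = win)$phases
  expect_lt(max(abs(abs(ph_trough) - pi)), tol)
  ph_rise <- spike_phases(tr, spike_train(rising, 6), window = win)$phases
  expect_lt(max(abs(ph_rise + pi / 2)), tol)
})

test_that("phase histograms integrate to one and locate von Mises concentrations", {
  set.seed(14)
  u <- runif(4000, -pi, pi)
  h <- phase_histogram(u, n_bins = 12)
  expect_equal(sum(h$density * diff(h$breaks)), 1, tolerance = 1e-12)
  expect_lt(max(abs(h$density - 1 / (2 * pi))), 0.04)

  all_same <- phase_histogram(rep(0.7, 50), n_bins = 18)
  expect_equal(sum(all_same$density > 0), 1)

  # von Mises sample via rejection sampling, kappa 2, centre -pi/4
  kappa <- 2
  mu <- -pi / 4
  draw <- function(n) {
    out <- c()
    while (length(out) < n) {
      x <- runif(2 * n, -pi, pi)
      acc <- runif(2 * n) < exp(kappa * (cos(x - mu) - 1))
      out <- c(out, x[acc])
    }
    out[1:n]
  }
  vm <- draw(1000)
  expect_lt(abs(circular_mean(vm) - mu), 0.1)
})
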