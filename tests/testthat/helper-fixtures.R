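# Fixture builders shared across test files. Everything is generated in
# code; no stored data.

# cosine trace locked to stimulus onset: cos phase 0 at onset
sine_trial <- function(freq = 5, amp = 3, fs = 1000, dur = 6,
                       onset = 0.5, phase = 0, offset = 0) {
  tt <- (0:(fs * dur - 1)) / fs
  vm_trial(offset + amp * cos(2 * pi * freq * (tt - onset) + phase),
           sampling_rate = fs, stim_onset = onset, stim_dur = 0.2)
}

flat_trial <- function(value = 0, fs = 1000, dur = 6, onset = 0.5) {
  vm_trial(rep(value, fs * dur), sampling_rate = fs, stim_onset = onset,
           stim_dur = 0.2)
}

# naive O(n*w) sliding median with replicated edges — oracle for
# remove_spikes
naive_sliding_median <- function(x, w) {
  n <- length(x)
  h <- (w - 1) %/% 2
  padded <- c(rep(x[1], h), x, rep(x[n], h))
  vapply(seq_len(n), function(i) stats::median(padded[i:(i + w - 1)]),
         numeric(1))
}

# hand-built tuning dataset from per-direction spike counts (deterministic,
# evenly spaced spikes inside the response window; silent elsewhere)
counts_dataset <- function(counts, n_trials = 4, onset = 0.5,
                           response = c(0.05, 0.55),
                           baseline = c(2.5, 3.5), dur = 6) {
  dirs <- tuning_directions()
  stopifnot(length(counts) == 12)
  trials <- lapply(seq_along(dirs), function(d) {
    lapply(seq_len(n_trials), function(i) {
      k <- counts[d]
      st <- if (k > 0) {
        onset + response[1] + diff(response) * (seq_len(k) - 0.5) / k
      } else numeric(0)
      list(vm = NULL, spikes = spike_train(st, dur))
    })
  })
  names(trials) <- dirs
  tuning_dataset(trials,
                 windows = window_spec(response = response,
                                       baseline = baseline),
                 stim_onset = onset)
}

# independent plain-loop implementation of the split-half procedure,
# used as a Monte-Carlo oracle against split_half_selectivity
splithalf_oracle <- function(ds, n_reps, seed) {
  dirs <- ds$directions
  on <- ds$stim_onset
  rw <- on + ds$windows$response
  bw <- on + ds$windows$baseline
  rate_tab <- list()
  for (d in seq_along(dirs)) {
    rate_tab[[d]] <- sapply(ds$trials[[d]], function(tr) {
      s <- tr$spikes$times
      sum(s >= rw[1] & s < rw[2]) / diff(ds$windows$response) -
        sum(s >= bw[1] & s < bw[2]) / diff(ds$windows$baseline)
    })
  }
  set.seed(seed)
  osis <- dsis <- c()
  for (r in seq_len(n_reps)) {
    h1m <- h2m <- numeric(12)
    for (d in 1:12) {
      x <- rate_tab[[d]]
      n <- length(x)
      idx <- sample(n)
      take <- ceiling(n / 2)
      h1m[d] <- mean(x[idx[1:take]])
      h2m[d] <- mean(x[idx[(take + 1):n]])
    }
    p <- which.max(h1m)
    rp <- h2m[p]
    ro <- h2m[which(dirs == (dirs[p] + 180) %% 360)]
    rt <- mean(c(h2m[which(dirs == (dirs[p] + 90) %% 360)],
                 h2m[which(dirs == (dirs[p] + 270) %% 360)]))
    o <- (rp - rt) / (rp + rt)
    dd <- (rp - ro) / (rp + ro)
    if (is.finite(o) && o >= 0) osis <- c(osis, o)
    if (is.finite(dd) && dd >= 0) dsis <- c(dsis, dd)
  }
  list(osi = mean(osis), dsi = mean(dsis))
}

# kappa_ori giving a target ground-truth OSI at fixed other parameters
solve_kappa_for_osi <- function(target, dir_bias = 0.5, base_rate = 3,
                                amp_rate = 30) {
  gt_osi <- function(kap) {
    p <- synth_tuning_params(kappa_ori = kap, dir_bias = dir_bias,
                             base_rate = base_rate, amp_rate = amp_rate)
    dirs <- tuning_directions()
    rates <- tuning_rate_map(p, dirs)
    i <- which.max(rates)
    orth <- mean(rates[dirs %in% c((dirs[i] + 90) %% 360,
                                   (dirs[i] + 270) %% 360)])
    (rates[i] - orth) / (rates[i] + orth)
  }
  stats::uniroot(function(k) gt_osi(k) - target, c(0.005, 50),
                 tol = 1e-12)$root
}
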