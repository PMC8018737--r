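---
title: "Methods: oscillation analysis, selectivity estimation, and the ring model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: oscillation analysis, selectivity estimation, and the ring model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Scope

`v1osc` implements the computational pipeline used to characterise
familiarity-induced ~5 Hz membrane-potential (Vm) oscillations in mouse
primary visual cortex, together with the recurrent ring-network rate model
that explains them. The package works on trial-structured whole-cell
recordings: current-clamp Vm sweeps with stimulus metadata, and
voltage-clamp current sweeps with a light-pulse TTL. Because raw
recordings of this kind are rarely shared, the package also ships a
synthetic-data generator that produces ground-truth-labelled trials with
the statistical structure the analyses assume; every stage of the pipeline
is tested against that ground truth.

# Trace analysis

## Spike removal and detection

Subthreshold analysis requires spike-free traces. Action potentials are
removed with a running median filter (12.5 ms window, rounded up to an odd
sample count, edges replicated). Edge replication avoids manufacturing an
onset transient at the trace boundaries; a median leaves constant and
monotone segments untouched while clipping transients much narrower than
its window.

Spike detection uses two unit-sum Hanning smoothings of the raw trace,
fine (0.5 ms) and coarse (500 ms). The coarse trace tracks the slow Vm, so
the difference is a high-pass signal calibrated in mV, and a fixed 15 mV
threshold applies. One spike is emitted per contiguous supra-threshold
run, at the run's maximum (earliest sample on ties — the tie-break is
arbitrary but fixed for determinism). Both kernels are normalised to unit
sum precisely so the difference stays in mV; without that, the threshold
would silently depend on the sampling rate.

## PSTH and firing-rate measures

PSTHs use 10 ms bins, rates in Hz averaged across trials, smoothed with a
truncated unit-sum Gaussian kernel (200 ms span, sigma 40 ms).
"Normalised rate" divides the smoothed rate by its per-cell maximum, so
population summaries peak near 1; z-scoring against a baseline window is
provided separately. The baseline-subtracted response rate is the mean
rate in the response window minus the mean rate in the baseline window;
for the single-direction protocol the windows are 0.05–0.25 s and
2.5–4.7 s after stimulus onset, for the 12-direction protocol 0.05–0.55 s
and 2.5–3.5 s. All windows are half-open `[start, end)` with 0-based
sample times, which makes binning unambiguous at window edges.

## Spectral analysis

Power spectra are one-sided periodograms of mean-removed windows, scaled
so that a sinusoid of amplitude A contributes A²/2 at its bin and the
spectrum sums to the window variance.

Band magnitudes (4–7, 8–12, 13–30 Hz) are the time-averaged
analytic-signal envelope of a zero-phase (forward–backward) 4th-order
Butterworth bandpass, giving an amplitude in mV comparable across bands.
A numerical point matters here: a 4–7 Hz band at a 10–20 kHz acquisition
rate is a vanishing fraction of Nyquist, and transfer-function Butterworth
designs are numerically singular there (the filter output diverges). The
package therefore decimates internally before filtering: an FFT brick-wall
anti-alias lowpass followed by subsampling to a working rate of about 50
times the upper band edge, on which the order-4 design is
well-conditioned. The decimation is zero-phase by construction, so the
downstream phase analyses are unaffected; quantities sampled at spike
times are obtained by linear interpolation of the complex analytic signal
on the working grid.

Time-frequency maps use complex Morlet wavelets on 40 log-spaced
frequencies from 2 to 80 Hz, with cycle counts mapped linearly from 3 at
the lowest to 10 at the highest frequency (the mapping across the grid is
a package choice; only the 3–10 range is fixed by the protocol). Kernels
are amplitude-calibrated so a pure tone of amplitude A yields |W| of about
A. Traces are reflect-padded so edges taper instead of wrapping. Display
spectrograms are expressed in dB relative to mean baseline-window power
per frequency; the default baseline is the tuning baseline (2.5–3.5 s
after onset) — the normalisation window is configurable because the
protocol does not pin it down.

Intertrial phase coherence is `ITPC(f,t) = |mean_trials exp(i arg W)|`,
1 for perfectly phase-locked trials, with expectation ~ sqrt(pi / (4 n))
for independent phases.

## Oscillation-trial detection

A trial counts as an oscillation trial when its 4–7 Hz power in the
response window (stimulus onset to +0.5 s) exceeds 10 times the power in
the late baseline (4.5–5 s after onset). "Power" is implemented as the
mean squared amplitude of the bandpassed signal over the window; the ratio
is scale-free, so this choice only shifts the effective threshold, and
both the band and the threshold are exposed in the criterion object. The
original workflow additionally inspected flagged trials manually; that
step is not reproducible and is deliberately omitted.

## Selectivity estimation

OSI = (Rpref − Rorth)/(Rpref + Rorth) and DSI = (Rpref − Ropp)/(Rpref +
Ropp), with Rorth the mean of the two ±90° directions. The estimator is a
split-half resampling procedure: per repetition, trials of each direction
are split randomly in half (odd counts place the extra trial in half 1);
half 1 selects the preferred direction by argmax of baseline-subtracted
mean rate (earliest direction on ties); half 2 supplies the rates from
which the indices are computed. Using independent halves removes the
selection bias that inflates selectivity when the same trials pick the
preferred direction and evaluate it. Repetitions yielding a negative index
are discarded — independently for OSI and for DSI, so an unreliable
direction estimate for one index does not erase information about the
other — and 2000 repetitions are averaged. Rates are baseline-subtracted
and can be negative, which is what makes the discard rule reachable.

The recovery accuracy of this estimator is assessed on synthetic von Mises
cells with known ground truth. Two conditions of that assessment are
package choices worth stating: the grid point at ground-truth OSI 0.8 is
only attainable for strongly driven cells (with an untuned response of
3 Hz and tuned amplitude 30 Hz the map supports it; with weak drive the
formula caps out lower), so the recovery suite uses such cells, at 20
trials per direction; and the generator keeps spontaneous firing at zero
outside the response window so that the baseline-subtracted estimator
targets exactly the stored map (mouse L2/3 cells are near-silent
spontaneously, so this is not a strong idealisation). Measured mean
absolute error across ground-truth OSI {0.2, 0.5, 0.8} is ~0.03 under
these conditions.

## Spike phases

Spike phase is the angle of the analytic signal of the 4–7 Hz bandpassed,
spike-removed trace, sampled at spike times in the response window. The
convention is: 0 = oscillation peak, negative = rising phase, positive =
falling phase — exactly the angle of the analytic signal of a cosine.

# EPSC features

Light-evoked EPSCs are inward (negative) currents. The baseline is the
mean of 0.2 s before the TTL; the peak is the most negative
baseline-subtracted point within 0–40 ms post-TTL; amplitude is its
magnitude; latency is the first post-TTL crossing of 5% of the amplitude
at or before the peak. Cells are kept when mean latency < 3.5 ms (the
monosynaptic criterion) and access resistance ≤ 60 MΩ. A deflection
smaller than 3 baseline SDs is reported as a non-response (amplitude 0,
latency undefined); the 3-SD floor is a package choice, since the
original criterion for "responsive" is not stated. Membrane resistance is
the least-squares slope of steady-state voltage against injected current
(1 mV/pA = 1000 MΩ).

# The ring model

Populations are indexed by preferred direction φ on (−π, π]. Rates r(φ,t)
relax toward a threshold-linear function of net input with time constant
τr = 5 ms; an adaptation variable a(φ,t) low-pass filters the rate
(τa = 150 ms) and feeds back negatively with strength k = 1. Net input is
the ring integral of a difference-of-Gaussians recurrent kernel times the
rate field, plus a separable feedforward drive (two Gaussian bumps at the
stimulus direction and its opposite, widths π/10, opposite-bump weight
0.2; temporal profile a 500 ms pulse low-passed at τext = 50 ms), minus
the adaptation current. Before learning the recurrent kernel is uniform
weak excitation (J_E = 0.15, σ_E = ∞, J_I = 0) and the feedforward gain is
1; after learning the kernel becomes local excitation with global
inhibition (J_E = 3, σ_E = π/6, J_I = 1, σ_I = ∞) and the gain halves.
σ = ∞ is represented by an explicit sentinel producing a constant kernel
term, never a numeric overflow.

Mechanistically: after learning, strong local recurrent excitation
provides positive feedback whose interaction with the slow adaptation
variable produces a relaxation oscillation at ~5 Hz in the driven
populations; global inhibition driven by the active bump pushes the
opposite-direction populations into anti-phase and suppresses the
orthogonal populations below threshold, so their rates are exactly zero
while their *net input* still oscillates — the model's account of why
subthreshold Vm oscillates at all directions while firing does not.

## Numerical choices

The published description leaves the discretisation open; the package
defaults are N = 180 populations, ring integral as a Riemann sum with
weight 2π/N, wrapped minimal angular distance in the kernel (the printed
Gaussians are non-periodic; wrapping is the standard ring reading and
matters only in the tails), total time 2000 ms with stimulus onset at
500 ms, and zero initial conditions. Integration is fixed-step classical
RK4. The default step is dt = 0.05 ms: the threshold nonlinearity makes
the right-hand side non-smooth at threshold crossings, which degrades
RK4's order there, and 0.05 ms is the step at which halving changes the
rate field by less than 1e-6 in relative sup-norm (at 0.1 ms the halving
difference is ~1.4e-6). Doubling N from 180 to 360 changes
stimulus-window mean rates by well under 1%. Any rate exceeding 1e6 in
magnitude aborts the run with an instability error naming the step and
phase. Fields are stored every 10th step by default; readouts
(periodogram peak of the probe rate at ≤0.25 Hz grid resolution via
zero-padding, stimulus-window means, cross-spectral phase between net
inputs) operate on the stored grid.

Display normalisations follow the convention that all rates, pre- and
post-learning, are divided by the single post-learning maximum, and the
net input by its post-learning maximum.

# The synthetic-data generator

The generator emulates what the analyses assume about the two conditions:

* **naive** — broad stimulus-locked depolarisation (alpha function, 8 mV,
  100 ms time-to-peak) and a single strong onset burst (inhomogeneous
  Poisson, 30 Hz peak intensity with the same alpha profile);
* **experienced** — a damped 5 Hz cosine starting at stimulus onset
  (5 mV, exponential envelope with time constant 3.5 cycles / 5 Hz,
  matching the three-to-four-cycle phenomenology), a smaller
  depolarisation, and oscillation-locked firing: Poisson intensity equal
  to the oscillation envelope times a von Mises density over the
  instantaneous phase, centred at −π/4 (rising phase) with concentration 2.

Spikes are added to the trace as a fixed biexponential template (60 mV,
2 ms) with a 2 ms refractory period; noise is Gaussian, 1/f-shaped
("pink") by default at 2 mV SD. Pink rather than white noise is a
deliberate realism choice: awake Vm fluctuations are dominated by slow
synaptic input, and with white noise the baseline 4–7 Hz power is so low
that the oscillation-trial ratio saturates for any stimulus transient,
including naive ones. With pink noise at 2 mV the detector behaves as in
real data — experienced trials are flagged at high probability, naive
ones rarely. Trial counts default to 10 per direction / 40 per condition
in population helpers; the protocol does not fix per-cell trial counts, so
these are configurable defaults, not claims.

Tuning datasets draw Poisson spike counts from the closed-form von Mises
rate map described above, and store the map's exact OSI/DSI as ground
truth. EPSC trials are a difference of exponentials (rise 0.8 ms, decay
6 ms) scaled so the peak equals the requested amplitude, with the waveform
onset placed so the analytic 5%-of-peak crossing falls exactly at the
requested latency.

What the generator does **not** emulate: conductance-based membrane
dynamics, eye-movement and arousal covariates, cross-trial adaptation,
correlated noise across cells, and spike-shape variability. Passing tests
therefore demonstrate the correctness of the estimators and detectors
under the stated statistical assumptions, not robustness to every
pathology of real recordings.

# Problem sizes used in the shipped tests

The test-suite defaults are sized for a laptop-class single core: Vm
traces of 6 s at 1–10 kHz, populations of 5–10 cells, 200–1000
stationary-noise trials for detector false-positive rates, 2000
resampling repetitions for selectivity, and full-resolution ring
simulations (N = 180–360, dt 0.025–0.1 ms). These sizes are the package's
own choice of test conditions; all of them are parameters the user can
scale up.

# Known limitations

* The oscillation-trial criterion is a power ratio; slow non-oscillatory
  transients with band-limited energy can exceed it. The original manual
  inspection step has no automated counterpart here.
* The split-half estimator's discard rule truncates the null distribution,
  so flat-tuned noisy cells get small positive estimates rather than zero;
  this is a property of the published procedure, reproduced faithfully.
* The ring model's rate units are arbitrary (everything is reported
  relative to the post-learning maximum); no physical Hz calibration is
  claimed.
* ABF/NWB import is out of scope; the package reads its own plain-text
  trial container.
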