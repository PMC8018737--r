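# Recurrent ring network with threshold-linear rate dynamics and slow
# adaptation. Units live on a ring of preferred directions phi in
# (-pi, pi]; learning reshapes the recurrent kernel and scales the
# feedforward drive, which turns the stimulus response from a steady bump
# into a ~5 Hz relaxation oscillation.

#' Ring-model parameter set
#'
#' Dynamics (time in ms):
#' \deqn{\tau_r \dot r = -r + f(\int J(\phi - \phi') r(\phi') d\phi' +
#'   i(\phi, t) - k a)}
#' \deqn{\tau_a \dot a = -a + r}
#' with threshold-linear `f(x) = max(x, 0)`. The recurrent kernel is a
#' difference of Gaussians in wrapped angular distance,
#' `J_E exp(-d^2/sigma_E^2) - J_I exp(-d^2/sigma_I^2)`; `sigma = Inf`
#' denotes a constant (untuned) profile. The feedforward drive is separable:
#' a two-bump spatial profile centred on the stimulus direction `phi0` and
#' its opposite (relative weight `gamma1`), times a `t_stim`-long pulse
#' low-pass filtered with `tau_ext`.
#'
#' `phase = "pre"` gives the naive network (uniform weak excitation,
#' gamma0 = 1, J_E = 0.15, sigma_E = Inf, J_I = 0); `phase = "post"` the
#' experienced one (gamma0 = 0.5, J_E = 3, sigma_E = pi/6, J_I = 1,
#' sigma_I = Inf).
#'
#' @param phase `"pre"` or `"post"` (learning), setting `gamma0`, `J_E`,
#'   `sigma_E`, `J_I`, `sigma_I` to their published values; any of those
#'   can still be overridden explicitly.
#' @param tau_r,tau_a,tau_ext Time constants in ms.
#' @param t_stim Stimulus pulse duration in ms.
#' @param k Adaptation strength.
#' @param sigma_stim Stimulus bump width in radians.
#' @param gamma0,gamma1 Feedforward gain and opposite-bump weight.
#' @param J_E,sigma_E,J_I,sigma_I Recurrent kernel parameters; `Inf` sigma
#'   = constant profile.
#' @param phi0 Stimulus direction in radians.
#' @param N Number of ring populations.
#' @param dt Integration step in ms (must be <= tau_r / 5).
#' @param t_total Simulated time in ms.
#' @param stim_onset Stimulus onset in ms.
#' @return An object of class `ring_params`.
#' @export
ring_params <- function(phase = c("post", "pre"),
                        tau_r = 5, tau_a = 150, tau_ext = 50,
                        t_stim = 500, k = 1, sigma_stim = pi / 10,
                        gamma0 = NULL, gamma1 = 0.2,
                        J_E = NULL, sigma_E = NULL, J_I = NULL,
                        sigma_I = NULL, phi0 = 0,
                        N = 180L, dt = 0.05, t_total = 2000,
                        stim_onset = 500) {
  phase <- match.arg(phase)
  defaults <- if (phase == "post") {
    list(gamma0 = 0.5, J_E = 3, sigma_E = pi / 6, J_I = 1, sigma_I = Inf)
  } else {
    list(gamma0 = 1, J_E = 0.15, sigma_E = Inf, J_I = 0, sigma_I = Inf)
  }
  p <- list(phase = phase, tau_r = tau_r, tau_a = tau_a, tau_ext = tau_ext,
            t_stim = t_stim, k = k, sigma_stim = sigma_stim,
            gamma0 = gamma0 %||% defaults$gamma0, gamma1 = gamma1,
            J_E = J_E %||% defaults$J_E, sigma_E = sigma_E %||% defaults$sigma_E,
            J_I = J_I %||% defaults$J_I, sigma_I = sigma_I %||% defaults$sigma_I,
            phi0 = phi0, N = as.integer(N), dt = dt, t_total = t_total,
            stim_onset = stim_onset)
  if (any(c(p$tau_r, p$tau_a, p$tau_ext) <= 0)) {
    stop("ring_params: time constants must be positive")
  }
  if (p$N < 8L) stop("ring_params: N must be >= 8")
  if (p$dt > p$tau_r / 5) stop("ring_params: dt must be <= tau_r / 5")
  if (any(c(p$sigma_E, p$sigma_I, p$sigma_stim) <= 0)) {
    stop("ring_params: sigma values must be positive (or Inf)")
  }
  structure(p, class = "ring_params")
}

#' @export
print.ring_params <- function(x, ...) {
  cat(sprintf(paste0(
    "<ring_params %s-learning> gamma0=%g J_E=%g sigma_E=%s J_I=%g ",
    "sigma_I=%s | N=%d dt=%g ms, %g ms total\n"),
    x$phase, x$gamma0, x$J_E, format(x$sigma_E), x$J_I, format(x$sigma_I),
    x$N, x$dt, x$t_total))
  invisible(x)
}

#' The ring's direction grid
#' @param params A [ring_params()].
#' @return `N` equally spaced angles in `(-pi, pi]`.
#' @export
ring_phis <- function(params) {
  seq(-pi, pi, length.out = params$N + 1L)[-1L]
}

# One difference-of-Gaussians term; sigma = Inf is the constant profile.
#' @noRd
gauss_term <- function(J, sigma, d) {
  if (is.infinite(sigma)) rep(J, length(d)) else J * exp(-d^2 / sigma^2)
}

#' Recurrent connectivity kernel matrix
#'
#' `J[i, j] = J_E exp(-d_ij^2 / sigma_E^2) - J_I exp(-d_ij^2 / sigma_I^2)`
#' with `d_ij` the wrapped angular distance between ring positions. The
#' `2 pi / N` integration weight is applied at use, not here.
#'
#' @param params A [ring_params()].
#' @param phis Optional angle grid (defaults to [ring_phis()]).
#' @return `N x N` numeric matrix.
#' @export
build_connectivity <- function(params, phis = ring_phis(params)) {
  D <- wrap_angle(outer(phis, phis, "-"))
  matrix(gauss_term(params$J_E, params$sigma_E, D) -
           gauss_term(params$J_I, params$sigma_I, D),
         nrow = length(phis))
}

#' Feedforward input field
#'
#' Separable input `i(phi, t) = i_s(phi) i_t(t)`: spatial part
#' `gamma0 (exp(-d0^2/sigma_stim^2) + gamma1 exp(-dpi^2/sigma_stim^2))`
#' with wrapped distances to the stimulus direction and its opposite;
#' temporal part the first-order low-pass response (time constant
#' `tau_ext`) to a unit boxcar of length `t_stim` starting at
#' `stim_onset`.
#'
#' @param params A [ring_params()].
#' @param phis Angle grid.
#' @param t Time (ms), scalar or vector.
#' @return If `t` is scalar, a vector over `phis`; else a
#'   `length(phis) x length(t)` matrix.
#' @export
feedforward_input <- function(params, phis = ring_phis(params), t) {
  sp <- stimulus_profile(params, phis)
  tp <- stimulus_timecourse(params, t)
  if (length(t) == 1L) sp * tp else outer(sp, tp)
}

#' @rdname feedforward_input
#' @export
stimulus_profile <- function(params, phis = ring_phis(params)) {
  d0 <- wrap_angle(phis - params$phi0)
  dpi <- wrap_angle(phis - params$phi0 + pi)
  params$gamma0 * (exp(-d0^2 / params$sigma_stim^2) +
                     params$gamma1 * exp(-dpi^2 / params$sigma_stim^2))
}

#' @rdname feedforward_input
#' @export
stimulus_timecourse <- function(params, t) {
  on <- params$stim_onset
  off <- on + params$t_stim
  v_off <- 1 - exp(-params$t_stim / params$tau_ext)
  out <- numeric(length(t))
  rising <- t >= on & t < off
  decaying <- t >= off
  out[rising] <- 1 - exp(-(t[rising] - on) / params$tau_ext)
  out[decaying] <- v_off * exp(-(t[decaying] - off) / params$tau_ext)
  out
}

#' Simulate the ring network
#'
#' Fixed-step fourth-order Runge-Kutta from `r = a = 0`, with the ring
#' integral discretised as a Riemann sum (weight `2 pi / N`). The stored
#' net input `x(phi, t)` is the argument of the threshold nonlinearity, so
#' it shows subthreshold oscillations even where `r` is clipped to zero.
#'
#' @param params A [ring_params()].
#' @param store_every Store every k-th step (default 10, i.e. 1 ms at the
#'   default `dt`); the integration step itself is unaffected.
#' @return An object of class `ring_result`: `phis`, `times` (ms), and
#'   `N x T` matrices `r`, `a`, `x`.
#' @export
simulate_ring <- function(params = ring_params(), store_every = 10L) {
  phis <- ring_phis(params)
  W <- build_connectivity(params, phis) * (2 * pi / params$N)
  sp <- stimulus_profile(params, phis)
  dt <- params$dt
  nt <- round(params$t_total / dt)
  store_every <- max(1L, as.integer(store_every))
  keep <- seq(0L, nt, by = store_every)
  times_all <- (0:nt) * dt
  tau_r <- params$tau_r
  tau_a <- params$tau_a
  k <- params$k
  itc <- stimulus_timecourse(params, times_all)
  itc_half <- stimulus_timecourse(params, times_all[-length(times_all)] + dt / 2)
  N <- params$N
  R <- matrix(0, N, length(keep))
  A <- matrix(0, N, length(keep))
  X <- matrix(0, N, length(keep))
  r <- numeric(N)
  a <- numeric(N)
  net_input <- function(r, a, it) as.vector(W %*% r) + sp * it - k * a
  X[, 1L] <- net_input(r, a, itc[1L])
  col <- 1L
  for (i in seq_len(nt)) {
    it0 <- itc[i]
    ith <- itc_half[i]
    it1 <- itc[i + 1L]
    x1 <- net_input(r, a, it0)
    dr1 <- (-r + pmax(x1, 0)) / tau_r
    da1 <- (-a + r) / tau_a
    r2 <- r + dt / 2 * dr1; a2 <- a + dt / 2 * da1
    x2 <- net_input(r2, a2, ith)
    dr2 <- (-r2 + pmax(x2, 0)) / tau_r
    da2 <- (-a2 + r2) / tau_a
    r3 <- r + dt / 2 * dr2; a3 <- a + dt / 2 * da2
    x3 <- net_input(r3, a3, ith)
    dr3 <- (-r3 + pmax(x3, 0)) / tau_r
    da3 <- (-a3 + r3) / tau_a
    r4 <- r + dt * dr3; a4 <- a + dt * da3
    x4 <- net_input(r4, a4, it1)
    dr4 <- (-r4 + pmax(x4, 0)) / tau_r
    da4 <- (-a4 + r4) / tau_a
    r <- r + dt / 6 * (dr1 + 2 * dr2 + 2 * dr3 + dr4)
    a <- a + dt / 6 * (da1 + 2 * da2 + 2 * da3 + da4)
    if (any(!is.finite(r)) || any(abs(r) > 1e6)) {
      stop(sprintf(
        "simulate_ring: divergence at t = %g ms (dt = %g, phase = %s)",
        i * dt, dt, params$phase))
    }
    if (i %% store_every == 0L) {
      col <- col + 1L
      R[, col] <- r
      A[, col] <- a
      X[, col] <- net_input(r, a, it1)
    }
  }
  structure(
    list(phis = phis, times = times_all[keep + 1L], r = R, a = A, x = X,
         params = params),
    class = "ring_result")
}

#' @export
print.ring_result <- function(x, ...) {
  cat(sprintf(
    "<ring_result %s-learning> %d populations x %d stored times, max rate %.3g\n",
    x$params$phase, nrow(x$r), ncol(x$r), max(x$r)))
  invisible(x)
}

# index of the grid angle closest to phi (wrapped)
#' @noRd
phi_index <- function(result, phi) {
  which.min(abs(wrap_angle(result$phis - phi)))
}

#' Dominant oscillation frequency of a population rate
#'
#' Mean-removed, zero-padded periodogram of `r(phi_probe, .)` (or of the
#' net input `x`) over a time window; returns the peak frequency. Constant
#' series have no peak and yield `NA` with a warning.
#'
#' @param result A [simulate_ring()] result.
#' @param phi_probe Probe angle in radians (default the stimulus
#'   direction).
#' @param window Length-2 numeric window in ms (default stimulus onset to
#'   1000 ms past it).
#' @param field `"r"` (rate) or `"x"` (net input).
#' @param resolution_hz Frequency-grid resolution ceiling via zero-padding.
#' @param max_hz Restrict the peak search to below this frequency.
#' @return Peak frequency in Hz (`NA` if the series is flat).
#' @export
dominant_frequency <- function(result, phi_probe = result$params$phi0,
                               window = result$params$stim_onset + c(0, 1000),
                               field = c("r", "x"),
                               resolution_hz = 0.25, max_hz = 50) {
  field <- match.arg(field)
  y <- result[[field]][phi_index(result, phi_probe), ]
  sel <- result$times >= window[1] & result$times <= window[2]
  y <- y[sel]
  if (max(y) - min(y) < 1e-12) {
    warning("dominant_frequency: series is constant; no spectral peak")
    return(NA_real_)
  }
  fs <- 1000 / diff(result$times[1:2])  # Hz
  pad <- 2^ceiling(log2(fs / resolution_hz))
  pg <- periodogram_onesided(y, fs, pad_to = pad)
  keep <- pg$freq > 0 & pg$freq <= max_hz
  pg$freq[keep][which.max(pg$power[keep])]
}

#' Stimulus-window selectivity readouts of a simulation
#'
#' Time-averaged rates at the stimulus direction and its opposite over the
#' stimulus window, their ratio, and the mean rate over all populations.
#'
#' @param result A [simulate_ring()] result.
#' @param window Length-2 numeric in ms (default the stimulus period).
#' @return List with `r_pref`, `r_opp`, `ratio` (`NA` if `r_opp` is 0),
#'   `population_mean`.
#' @export
model_selectivity <- function(result,
                              window = result$params$stim_onset +
                                c(0, result$params$t_stim)) {
  sel <- result$times >= window[1] & result$times <= window[2]
  p <- result$params
  rp <- mean(result$r[phi_index(result, p$phi0), sel])
  ro <- mean(result$r[phi_index(result, p$phi0 + pi), sel])
  list(r_pref = rp, r_opp = ro,
       ratio = if (ro > 0) rp / ro else NA_real_,
       population_mean = mean(result$r[, sel]))
}

#' Net input field normalised by its post-learning maximum
#'
#' Divides the stored net input `x(phi, t)` by `max(x)` of a reference
#' (post-learning) result, exposing the subthreshold oscillation at
#' directions where the rate is clipped to zero.
#'
#' @param result A [simulate_ring()] result.
#' @param reference Result whose maximum sets the normalisation (default
#'   `result` itself).
#' @return Matrix `N x T` of normalised net input.
#' @export
net_input_field <- function(result, reference = result) {
  mx <- max(reference$x)
  if (mx <= 0) stop("net_input_field: reference maximum is not positive")
  result$x / mx
}

#' Normalised rate field
#'
#' All rates divided by the maximum rate of a reference (post-learning)
#' simulation, the display normalisation used for pre/post comparisons.
#'
#' @param result A [simulate_ring()] result.
#' @param reference Result supplying the maximum (default `result`).
#' @return Matrix `N x T`.
#' @export
normalized_rate_field <- function(result, reference = result) {
  mx <- max(reference$r)
  if (mx <= 0) stop("normalized_rate_field: reference maximum is not positive")
  result$r / mx
}

#' Cross-spectral phase between net inputs at two ring positions
#'
#' Phase of the cross-spectrum at the dominant frequency of the first
#' probe; a value near pi means anti-phase oscillation.
#'
#' @param result A [simulate_ring()] result.
#' @param phi_a,phi_b Probe angles in radians.
#' @param window Length-2 numeric window in ms.
#' @param field `"x"` or `"r"`.
#' @return List with `freq` (Hz) and `phase` (radians in `(-pi, pi]`).
#' @export
cross_phase <- function(result, phi_a = result$params$phi0,
                        phi_b = result$params$phi0 + pi,
                        window = result$params$stim_onset + c(0, 1000),
                        field = c("x", "r")) {
  field <- match.arg(field)
  sel <- result$times >= window[1] & result$times <= window[2]
  ya <- result[[field]][phi_index(result, phi_a), sel]
  yb <- result[[field]][phi_index(result, phi_b), sel]
  ya <- ya - mean(ya)
  yb <- yb - mean(yb)
  fs <- 1000 / diff(result$times[1:2])
  n <- length(ya)
  pad <- 2^ceiling(log2(max(n, fs / 0.25)))
  A <- stats::fft(c(ya, numeric(pad - n)))
  B <- stats::fft(c(yb, numeric(pad - n)))
  freqs <- (0:(pad - 1)) * fs / pad
  keep <- freqs > 0 & freqs <= 50
  i_dom <- which(keep)[which.max(Mod(A[keep])^2)]
  list(freq = freqs[i_dom], phase = Arg(A[i_dom] * Conj(B[i_dom])))
}
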