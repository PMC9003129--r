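#' Default PQRST wave parameters
#'
#' The canonical parameter set of the Gaussian-wave dynamical ECG model: each
#' of the five characteristic waves (P, Q, R, S, T) is a Gaussian bump in
#' phase with amplitude `alpha` (signal units), width `b` (radians) and
#' center `theta` (radians, stored in `[0, 2*pi)`, R at 0).
#'
#' @return A tibble with columns `wave`, `alpha`, `b`, `theta`.
#' @export
#' @examples
#' mcsharry_waves()
mcsharry_waves <- function() {
  tibble::tibble(
    wave  = c("P", "Q", "R", "S", "T"),
    alpha = c(1.2, -5.0, 30.0, -7.5, 0.75),
    b     = c(0.25, 0.1, 0.1, 0.1, 0.4),
    theta = wrap_2pi(c(-pi / 3, -pi / 12, 0, pi / 12, pi / 2))
  )
}

#' Parameters of the dynamic ECG model
#'
#' Bundles everything the polar-coordinate ECG model needs: the five Gaussian
#' wave parameters, the angular velocity of the limit-cycle trajectory, the
#' sampling period, the state-noise variance on the amplitude equation, and
#' the two observation-noise variances (phase, amplitude).
#'
#' @param waves Tibble with columns `wave` (`P`,`Q`,`R`,`S`,`T`), `alpha`,
#'   `b` (> 0, radians), `theta` (radians).
#' @param omega Angular velocity in rad/s (`2*pi / RR`); must be > 0.
#' @param delta Sampling period in seconds; must be > 0.
#' @param eta_var Variance of the per-sample state noise on the amplitude
#'   `z` (signal units squared); >= 0.
#' @param obs_noise Named numeric `c(phi = ..., s = ...)`: variances of the
#'   phase observation noise (rad^2) and amplitude observation noise
#'   (signal units squared); >= 0.
#' @return A list of class `ecg_model_params`.
#' @export
ecg_model_params <- function(waves = mcsharry_waves(),
                             omega = 2 * pi,
                             delta = 0.001,
                             eta_var = 4e-4,
                             obs_noise = c(phi = 0.01, s = 0.01)) {
  stopifnot(is.data.frame(waves),
            all(c("wave", "alpha", "b", "theta") %in% names(waves)))
  if (!setequal(waves$wave, c("P", "Q", "R", "S", "T")) || nrow(waves) != 5L) {
    stop("ecg_model_params: waves must contain exactly P, Q, R, S, T")
  }
  if (any(waves$b <= 0)) stop("ecg_model_params: wave widths b must be > 0")
  if (!is.numeric(omega) || omega <= 0) stop("ecg_model_params: omega must be > 0")
  if (!is.numeric(delta) || delta <= 0) stop("ecg_model_params: delta must be > 0")
  if (eta_var < 0) stop("ecg_model_params: eta_var must be >= 0")
  if (!all(c("phi", "s") %in% names(obs_noise)) || any(obs_noise < 0)) {
    stop("ecg_model_params: obs_noise needs non-negative entries named phi, s")
  }
  waves <- waves[match(c("P", "Q", "R", "S", "T"), waves$wave), ]
  waves$theta <- wrap_2pi(waves$theta)
  structure(list(waves = waves, omega = omega, delta = delta,
                 eta_var = eta_var, obs_noise = obs_noise),
            class = "ecg_model_params")
}

#' Gaussian-sum beat waveform and its phase derivatives
#'
#' `gaussian_sum()` evaluates the closed-form beat shape
#' `G(theta) = sum_i alpha_i exp(-dtheta_i^2 / (2 b_i^2))`, with
#' `dtheta_i = wrap_pi(theta - theta_i)`; `gaussian_sum_d1()` and
#' `gaussian_sum_d2()` are its first and second derivatives in phase. The
#' amplitude recursion of the dynamic model integrates `G'` along the phase
#' trajectory, so the noise-free trace equals `G` up to a constant.
#'
#' @param theta Phase values (radians).
#' @param waves Wave-parameter tibble (see [mcsharry_waves()]).
#' @return Numeric vector the length of `theta`.
#' @export
gaussian_sum <- function(theta, waves = mcsharry_waves()) {
  out <- numeric(length(theta))
  for (i in seq_len(nrow(waves))) {
    d <- wrap_pi(theta - waves$theta[i])
    out <- out + waves$alpha[i] * exp(-d^2 / (2 * waves$b[i]^2))
  }
  out
}

#' @rdname gaussian_sum
#' @export
gaussian_sum_d1 <- function(theta, waves = mcsharry_waves()) {
  out <- numeric(length(theta))
  for (i in seq_len(nrow(waves))) {
    d <- wrap_pi(theta - waves$theta[i])
    out <- out - waves$alpha[i] * d / waves$b[i]^2 * exp(-d^2 / (2 * waves$b[i]^2))
  }
  out
}

#' @rdname gaussian_sum
#' @export
gaussian_sum_d2 <- function(theta, waves = mcsharry_waves()) {
  out <- numeric(length(theta))
  for (i in seq_len(nrow(waves))) {
    d <- wrap_pi(theta - waves$theta[i])
    out <- out - waves$alpha[i] / waves$b[i]^2 * (1 - d^2 / waves$b[i]^2) *
      exp(-d^2 / (2 * waves$b[i]^2))
  }
  out
}

#' One step of the dynamic ECG state equation
#'
#' Advances the state `x = (theta, z)` one sampling period: the phase moves
#' uniformly around the limit cycle (noise-free), and the amplitude
#' accumulates the Gaussian-sum increment plus state noise `eta`:
#' `theta_k = (theta_{k-1} + omega * delta) mod 2*pi`,
#' `z_k = z_{k-1} - sum_i alpha_i (omega * delta / b_i^2) dtheta_i
#'   exp(-dtheta_i^2 / (2 b_i^2)) + eta`, with
#' `dtheta_i = wrap_pi(theta_k - theta_i)`.
#'
#' @param state List or named numeric with `theta` (in `[0, 2*pi)`) and `z`.
#' @param params An [ecg_model_params()].
#' @param eta Scalar state-noise draw added to `z`.
#' @return List with elements `theta`, `z`.
#' @export
ecg_transition <- function(state, params, eta = 0) {
  theta <- state$theta; z <- state$z
  if (!is.finite(theta) || !is.finite(z) || !is.finite(eta)) {
    stop("ecg_transition: non-finite state or noise input")
  }
  theta_k <- wrap_2pi(theta + params$omega * params$delta)
  z_k <- z + params$omega * params$delta * gaussian_sum_d1(theta_k, params$waves) + eta
  list(theta = theta_k, z = z_k)
}

#' Jacobian of the ECG state transition
#'
#' Derivatives of the one-step transition map with respect to the previous
#' state, used by the extended Kalman filter. The phase row is the identity;
#' the amplitude row carries the phase-sensitivity of the Gaussian-sum
#' increment.
#'
#' @inheritParams ecg_transition
#' @return A 2x2 matrix, rows/cols ordered (theta, z).
#' @export
ecg_jacobian <- function(state, params) {
  theta_k <- wrap_2pi(state$theta + params$omega * params$delta)
  dz_dtheta <- params$omega * params$delta * gaussian_sum_d2(theta_k, params$waves)
  matrix(c(1, 0, dz_dtheta, 1), 2, 2, byrow = TRUE,
         dimnames = list(c("theta", "z"), c("theta", "z")))
}

#' ECG observation equation
#'
#' The observed phase is the state phase plus noise, wrapped; the observed
#' amplitude is the state amplitude plus noise:
#' `phi = (theta + u) mod 2*pi`, `s = z + v`.
#'
#' @inheritParams ecg_transition
#' @param u Phase-noise draw (radians).
#' @param v Amplitude-noise draw (signal units).
#' @return List with elements `phi`, `s`.
#' @export
ecg_observe <- function(state, u = 0, v = 0) {
  if (!is.finite(state$theta) || !is.finite(state$z) ||
      !is.finite(u) || !is.finite(v)) {
    stop("ecg_observe: non-finite input")
  }
  list(phi = wrap_2pi(state$theta + u), s = state$z + v)
}

# Build the per-sample wrapped phase trace anchored at peak times: phase is 0
# (the R center offset is added by callers) at each peak and advances by
# 2*pi/RR_j within interval j; edges extrapolate with the nearest RR.
phase_from_peak_times <- function(peak_times, n, fs, theta_r = 0) {
  stopifnot(length(peak_times) >= 1L)
  t <- (seq_len(n) - 1) / fs
  if (length(peak_times) == 1L) {
    rr <- 1
    phi <- 2 * pi * (t - peak_times[1]) / rr
    return(wrap_2pi(phi + theta_r))
  }
  rr <- diff(peak_times)
  # interval index for each sample (0 = before first peak)
  j <- findInterval(t, peak_times)
  rr_of <- c(rr[1], rr, rr[length(rr)])   # edge extrapolation uses nearest RR
  anchor <- c(peak_times[1], peak_times)  # anchor peak for each interval id
  phi <- 2 * pi * (t - anchor[j + 1]) / rr_of[j + 1]
  wrap_2pi(phi + theta_r)
}

#' Generate a synthetic beat train
#'
#' Integrates the dynamic ECG model sample-by-sample along a phase trajectory
#' defined by the beat (R-peak) times, and applies the observation equation.
#' When `rr_series` is supplied, the angular velocity is set per beat to
#' `2*pi/RR`; otherwise a constant rate is used (from `hr` if given, else
#' from `params$omega`). Ground-truth R-peak sample indices are returned in
#' the signal's `peaks` attribute.
#'
#' @param params An [ecg_model_params()]. `params$delta` sets the sampling
#'   period.
#' @param duration Signal length in seconds (> one sample).
#' @param hr Optional constant heart rate in bpm (overrides `params$omega`).
#' @param rr_series Optional vector of per-beat RR intervals in seconds; the
#'   first peak falls at `first_peak` seconds and subsequent peaks at its
#'   cumulative sums.
#' @param first_peak Time of the first R peak (seconds, default 0).
#' @param seed Optional integer seed: fixes the state/observation noise draws.
#' @param noise If `FALSE`, suppress both state and observation noise
#'   regardless of the variances in `params`.
#' @return An [annotated_signal()] whose `peaks` attribute holds the
#'   ground-truth R-peak indices.
#' @export
#' @examples
#' p <- ecg_model_params(eta_var = 0, obs_noise = c(phi = 0, s = 0))
#' s <- generate_beat_train(p, duration = 5, hr = 60)
#' length(signal_peaks(s))  # 5 beats
generate_beat_train <- function(params = ecg_model_params(), duration,
                                hr = NULL, rr_series = NULL, first_peak = 0,
                                seed = NULL, noise = TRUE) {
  fs <- 1 / params$delta
  n <- round(duration * fs)
  if (!is.numeric(duration) || duration <= 0 || n < 1L) {
    stop("generate_beat_train: duration must cover at least one sample")
  }
  if (!is.null(seed)) withr::local_seed(seed)
  if (is.null(rr_series)) {
    rr0 <- if (!is.null(hr)) 60 / hr else 2 * pi / params$omega
    n_beats <- ceiling((duration - first_peak) / rr0) + 1L
    rr_series <- rep(rr0, n_beats)
  } else if (any(rr_series <= 0)) {
    stop("generate_beat_train: rr_series entries must be > 0")
  }
  peak_times <- first_peak + c(0, cumsum(rr_series))
  theta_r <- params$waves$theta[params$waves$wave == "R"]
  phi <- phase_from_peak_times(peak_times, n, fs, theta_r = theta_r)
  # unwrapped phase increments (monotone forward motion)
  dphi <- wrap_2pi(diff(phi))
  incr <- gaussian_sum_d1(phi[-1], params$waves) * dphi
  if (noise && params$eta_var > 0) {
    incr <- incr + stats::rnorm(length(incr), 0, sqrt(params$eta_var))
  }
  z0 <- gaussian_sum(phi[1], params$waves)
  z <- c(z0, z0 + cumsum(incr))
  s <- z
  if (noise && params$obs_noise[["s"]] > 0) {
    s <- s + stats::rnorm(n, 0, sqrt(params$obs_noise[["s"]]))
  }
  pk_t <- peak_times[peak_times >= -1e-9 & peak_times <= (n - 1) / fs + 1e-9]
  pk <- unique(pmin(pmax(round(pk_t * fs) + 1L, 1L), n))
  annotated_signal(s, fs = fs, peaks = pk)
}

#' Phase-average a signal into a mean beat
#'
#' Folds a signal onto the unit circle using its per-sample phase and takes
#' the median amplitude (and median phase) within each of `bins` equal phase
#' bins. The median is robust to contamination of individual beats (e.g. by
#' fetal complexes riding on maternal beats).
#'
#' @param x An [annotated_signal()] (or numeric amplitude vector).
#' @param phase Per-sample phase in `[0, 2*pi)` (numeric vector or the tibble
#'   returned by [assign_phase()]).
#' @param bins Number of phase bins (default 250).
#' @return A tibble with columns `phase`, `amplitude`, one row per non-empty
#'   bin.
#' @export
phase_average <- function(x, phase, bins = 250) {
  amp <- if (is.data.frame(x)) x$amplitude else as.numeric(x)
  phi <- if (is.data.frame(phase)) phase$phi else as.numeric(phase)
  stopifnot(length(amp) == length(phi))
  bin <- pmin(floor(phi / (2 * pi) * bins), bins - 1L)
  out <- tibble::tibble(phase = phi, amplitude = amp, .bin = bin) |>
    dplyr::group_by(.data$.bin) |>
    dplyr::summarise(phase = stats::median(.data$phase),
                     amplitude = stats::median(.data$amplitude),
                     .groups = "drop") |>
    dplyr::arrange(.data$phase) |>
    dplyr::select("phase", "amplitude")
  out
}

#' Fit Gaussian wave parameters to a mean beat
#'
#' Nonlinear least squares for the 15 Gaussian parameters (five amplitudes,
#' widths and centers) plus a baseline offset, minimizing the squared error
#' between the Gaussian-sum beat shape and a phase-indexed mean beat.
#' Initialized at `init`; widths are kept positive by bound constraints.
#'
#' @param mean_beat Tibble with columns `phase`, `amplitude` covering
#'   `[0, 2*pi)` (output of [phase_average()]).
#' @param init An [ecg_model_params()] used as starting point (its `omega`,
#'   `delta` and noise fields are carried into the result).
#' @return A list of class `ecg_beat_fit` with elements `params` (the fitted
#'   [ecg_model_params()]), `offset`, `fitted`, `residual_var`, `converged`.
#' @export
fit_beat_params <- function(mean_beat, init = ecg_model_params()) {
  stopifnot(is.data.frame(mean_beat),
            all(c("phase", "amplitude") %in% names(mean_beat)))
  phi <- mean_beat$phase
  y <- mean_beat$amplitude
  if (diff(range(phi)) < pi) {
    stop("fit_beat_params: mean beat must cover the full phase circle")
  }
  if (stats::sd(y) < 1e-12 * (1 + max(abs(y)))) {
    stop("fit_beat_params: degenerate flat beat, nothing to fit")
  }
  w0 <- init$waves
  start <- c(w0$alpha, w0$b, w0$theta, mean(y))
  lower <- c(rep(-Inf, 5), rep(1e-3, 5), w0$theta - pi / 2, -Inf)
  upper <- c(rep(Inf, 5), rep(pi, 5), w0$theta + pi / 2, Inf)
  model_fun <- function(p) {
    waves <- tibble::tibble(wave = w0$wave, alpha = p[1:5], b = p[6:10],
                            theta = p[11:15])
    gaussian_sum(phi, waves) + p[16]
  }
  fit <- tryCatch(
    suppressWarnings(
      minpack.lm::nls.lm(par = start, lower = lower, upper = upper,
                         fn = function(p) y - model_fun(p),
                         control = minpack.lm::nls.lm.control(maxiter = 500,
                                                              maxfev = 20000))),
    error = function(e) NULL)
  # iteration-capped fits are kept when the beat is already well explained
  # (the LM step can crawl along a flat valley when a low-amplitude wave is
  # barely identifiable); genuine non-convergence still errors
  ok <- !is.null(fit) &&
    (fit$info %in% 1:4 ||
       (is.finite(fit$deviance) &&
          fit$deviance <= 0.1 * sum((y - mean(y))^2)))
  if (!ok) {
    res <- if (is.null(fit)) NA_real_ else fit$deviance
    stop(sprintf("fit_beat_params: failed to converge (residual %s)",
                 format(res)))
  }
  p <- fit$par
  waves <- tibble::tibble(wave = w0$wave, alpha = p[1:5], b = p[6:10],
                          theta = wrap_2pi(p[11:15]))
  # wave centers must keep the physiological order P < Q < R < S < T
  # (measured relative to R, up to rotation of the circle)
  rel <- wrap_pi(p[11:15] - p[13])
  if (is.unsorted(rel)) {
    warning("fit_beat_params: fitted wave centers are out of P-Q-R-S-T order")
  }
  params <- ecg_model_params(waves = waves, omega = init$omega,
                             delta = init$delta, eta_var = init$eta_var,
                             obs_noise = init$obs_noise)
  structure(list(params = params, offset = p[16], fitted = model_fun(p),
                 residual_var = mean((y - model_fun(p))^2),
                 converged = TRUE, n_points = length(y)),
            class = "ecg_beat_fit")
}

#' @export
print.ecg_beat_fit <- function(x, ...) {
  cat("<ecg_beat_fit> Gaussian-sum beat fit on", x$n_points, "phase bins\n")
  cat("  residual variance:", format(x$residual_var, digits = 4),
      " offset:", format(x$offset, digits = 4), "\n")
  print(x$params$waves)
  invisible(x)
}
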