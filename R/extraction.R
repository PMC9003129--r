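#' Extraction pipeline configuration
#'
#' Collects the tunables of the two-pass extraction: preprocessing stages,
#' maternal and fetal QRS detector settings, whether per-record wave
#' parameters are fitted (the default) or the canonical defaults are used,
#' and the filter noise settings.
#'
#' @param preprocess A [preprocess_config()].
#' @param maternal,fetal Lists with `band` (Hz) and `refractory` (s) for the
#'   two Pan-Tompkins passes.
#' @param fit_params Fit per-record Gaussian wave parameters from the
#'   phase-averaged beat (`TRUE`, default) or use scaled defaults.
#' @param bins Phase bins for the beat average (default 250).
#' @param eps_theta Tiny phase process-noise variance (rad^2) kept only for
#'   filter conditioning: the model's phase equation itself is noise-free.
#' @param phase_obs_var Variance of the observed-phase noise (rad^2).
#' @param eta_var_scale The amplitude process-noise variance is set to this
#'   multiple of the beat-fit residual variance (default 10).
#' @param refine_fetal Re-detect fetal peaks once on the denoised fetal
#'   trace and repeat the fetal pass (off by default).
#' @param perturbation_mean Passed to the ensemble update (see
#'   [enkf_step()]).
#' @return A list of class `extraction_config`.
#' @export
extraction_config <- function(preprocess = preprocess_config(),
                              maternal = list(band = c(5, 15), refractory = 0.25),
                              fetal = list(band = c(10, 30), refractory = 0.2),
                              fit_params = TRUE, bins = 250,
                              eps_theta = 1e-6, phase_obs_var = 0.01,
                              eta_var_scale = 10, refine_fetal = FALSE,
                              perturbation_mean = "zero") {
  structure(list(preprocess = preprocess, maternal = maternal, fetal = fetal,
                 fit_params = fit_params, bins = bins, eps_theta = eps_theta,
                 phase_obs_var = phase_obs_var, eta_var_scale = eta_var_scale,
                 refine_fetal = refine_fetal,
                 perturbation_mean = perturbation_mean),
            class = "extraction_config")
}

# Per-sample angular velocity (rad/s) from the peak train: 2*pi / RR of the
# interval each sample falls in, edges using the nearest RR.
omega_from_peaks <- function(peaks, n_samples, fs) {
  pk <- peak_samples(peaks)
  if (length(pk) < 2L) stop("omega_from_peaks: need at least 2 peaks")
  k <- seq_len(n_samples)
  j <- findInterval(k, pk)
  rr <- diff(pk) / fs
  rr_of <- c(rr[1], rr, rr[length(rr)])
  2 * pi / rr_of[j + 1]
}

# Estimate observation amplitude-noise variance from the isoelectric phase
# segment (between the end of the T wave and the start of the P wave).
isoelectric_var <- function(amp, phi, waves) {
  th_t <- waves$theta[waves$wave == "T"]
  th_p <- waves$theta[waves$wave == "P"]
  lo <- wrap_2pi(th_t + 0.6)
  hi <- wrap_2pi(th_p - 0.3)
  span <- wrap_2pi(hi - lo)
  rel <- wrap_2pi(phi - lo)
  sel <- rel < span
  if (sum(sel) < 10L) sel <- rep(TRUE, length(amp))
  v <- stats::var(amp[sel])
  max(v, 1e-12)
}

# Fit per-record wave parameters (or scale the defaults) for one pass.
beat_model_for <- function(amp, phi, fs, fit_params, bins,
                           init_waves = mcsharry_waves(),
                           allow_fallback = FALSE) {
  mean_beat <- phase_average(amp, phi, bins = bins)
  beat_amp <- max(mean_beat$amplitude) - min(mean_beat$amplitude)
  init <- init_waves
  r_peak <- gaussian_sum(init$theta[init$wave == "R"], init) -
    stats::median(gaussian_sum(seq(2, 4, by = 0.05), init))
  init$alpha <- init$alpha * beat_amp / max(abs(r_peak), 1e-9)
  init_params <- ecg_model_params(waves = init, delta = 1 / fs)
  if (!fit_params) {
    off <- stats::median(mean_beat$amplitude -
                           gaussian_sum(mean_beat$phase, init))
    resid_var <- stats::var(mean_beat$amplitude -
                              gaussian_sum(mean_beat$phase, init))
    return(list(params = init_params, residual_var = max(resid_var, 1e-12),
                offset = off, fitted = FALSE))
  }
  fit <- tryCatch(fit_beat_params(mean_beat, init_params), error = function(e) e)
  if (inherits(fit, "error")) {
    if (!allow_fallback) stop(fit)
    warning("beat fit failed (", conditionMessage(fit),
            "); using scaled default wave parameters")
    off <- stats::median(mean_beat$amplitude -
                           gaussian_sum(mean_beat$phase, init))
    resid_var <- stats::var(mean_beat$amplitude)
    return(list(params = init_params, residual_var = max(resid_var, 1e-12),
                offset = off, fitted = FALSE))
  }
  list(params = fit$params, residual_var = max(fit$residual_var, 1e-12),
       offset = fit$offset, fitted = TRUE)
}

# One model-based filtering pass over (phi, s) observations.
filter_pass <- function(amp, phi, omega, params, cfg, method, n_ensemble,
                        r_z, q_z) {
  w <- params$waves
  if (method == "enkf") {
    res <- ecg_enkf_cpp(phi, amp, omega, params$delta, w$alpha, w$b, w$theta,
                        q_theta = cfg$eps_theta, q_z = q_z,
                        r_phi = cfg$phase_obs_var, r_z = r_z,
                        n_ens = n_ensemble, theta0 = phi[1], z0 = amp[1],
                        perturb_literal =
                          identical(cfg$perturbation_mean, "ensemble_obs_mean"))
  } else {
    res <- ecg_ekf_cpp(phi, amp, omega, params$delta, w$alpha, w$b, w$theta,
                       q_theta = cfg$eps_theta, q_z = q_z,
                       r_phi = cfg$phase_obs_var, r_z = r_z,
                       theta0 = phi[1], z0 = amp[1], p0 = max(r_z, 1))
  }
  res
}

#' Estimate the maternal ECG from a preprocessed abdominal signal
#'
#' Maternal R-peaks are detected with the Pan-Tompkins stage, the R-R
#' intervals are wrapped into a per-sample phase, per-record Gaussian wave
#' parameters are fitted to the phase-averaged (median) beat, and the
#' chosen filter tracks the maternal waveform through the dynamic ECG
#' model. The filtered amplitude trace is the maternal estimate; the
#' measurement-noise variance is taken from the isoelectric phase segment
#' and the process-noise variance from the beat-fit residual.
#'
#' @param aecg A preprocessed [annotated_signal()].
#' @param cfg An [extraction_config()].
#' @param method `"enkf"` (default) or `"ekf"`.
#' @param n_ensemble Ensemble size for the EnKF.
#' @return A list with `mecg` (the [annotated_signal()] estimate), `params`
#'   (maternal [ecg_model_params()]), `phase` (phase series tibble),
#'   `peaks` (maternal [peak_train()]) and `diagnostics`.
#' @export
estimate_mecg <- function(aecg, cfg = extraction_config(), method = "enkf",
                          n_ensemble = 70) {
  if (nrow(aecg) == 0L) stop("estimate_mecg: empty input signal")
  fs <- signal_fs(aecg)
  peaks <- pan_tompkins(aecg, band = cfg$maternal$band,
                        refractory = cfg$maternal$refractory)
  if (nrow(peaks) < 10L) {
    stop("estimate_mecg: fewer than 10 maternal beats detected; ",
         "cannot fit the beat morphology")
  }
  phase <- assign_phase(peaks, nrow(aecg))
  bm <- beat_model_for(aecg$amplitude, phase$phi, fs, cfg$fit_params,
                       cfg$bins, allow_fallback = FALSE)
  r_z <- isoelectric_var(aecg$amplitude, phase$phi, bm$params$waves)
  q_z <- cfg$eta_var_scale * bm$residual_var
  omega <- omega_from_peaks(peaks, nrow(aecg), fs)
  res <- filter_pass(aecg$amplitude, phase$phi, omega, bm$params, cfg,
                     method, n_ensemble, r_z = r_z, q_z = q_z)
  list(mecg = set_amplitude(aecg, res$z_hat),
       params = bm$params, phase = phase, peaks = peaks,
       diagnostics = list(n_maternal_beats = nrow(peaks),
                          fit_residual_var = bm$residual_var,
                          params_fitted = bm$fitted,
                          obs_noise_var = r_z, process_noise_var = q_z))
}

#' Denoise the fetal residual
#'
#' Runs the same model-based filter on the maternal-cancelled residual:
#' preliminary fetal R-peaks are detected with fetal Pan-Tompkins settings,
#' a fetal phase and fetal wave parameters are derived, and the filter's
#' amplitude trace is the denoised fetal waveform. The residual is assumed
#' to be fetal ECG plus approximately Gaussian noise. If no preliminary
#' fetal rhythm is detectable the residual is passed through unchanged,
#' with a warning and a diagnostics flag.
#'
#' @param residual An [annotated_signal()] (abdominal minus maternal
#'   estimate).
#' @inheritParams estimate_mecg
#' @return A list with `fecg` (the [annotated_signal()]), `params`,
#'   `peaks` (preliminary fetal peaks) and `diagnostics` (`skipped = TRUE`
#'   when denoising was not possible).
#' @export
denoise_fecg <- function(residual, cfg = extraction_config(),
                         method = "enkf", n_ensemble = 70) {
  fs <- signal_fs(residual)
  peaks <- tryCatch(
    suppressWarnings(pan_tompkins(residual, band = cfg$fetal$band,
                                  refractory = cfg$fetal$refractory)),
    error = function(e) peak_train(integer(), fs))
  if (nrow(peaks) < max(10L, 2L)) {
    warning("denoise_fecg: no reliable preliminary fetal rhythm; ",
            "denoising skipped, residual passed through")
    return(list(fecg = residual, params = NULL, peaks = peaks,
                diagnostics = list(skipped = TRUE, n_fetal_beats = nrow(peaks))))
  }
  fetal_init <- mcsharry_waves()
  fetal_init$b <- fetal_init$b * 0.5
  phase <- assign_phase(peaks, nrow(residual))
  bm <- beat_model_for(residual$amplitude, phase$phi, fs, cfg$fit_params,
                       cfg$bins, init_waves = fetal_init,
                       allow_fallback = TRUE)
  r_z <- isoelectric_var(residual$amplitude, phase$phi, bm$params$waves)
  q_z <- cfg$eta_var_scale * bm$residual_var
  omega <- omega_from_peaks(peaks, nrow(residual), fs)
  res <- filter_pass(residual$amplitude, phase$phi, omega, bm$params, cfg,
                     method, n_ensemble, r_z = r_z, q_z = q_z)
  list(fecg = set_amplitude(residual, res$z_hat),
       params = bm$params, peaks = peaks,
       diagnostics = list(skipped = FALSE, n_fetal_beats = nrow(peaks),
                          fit_residual_var = bm$residual_var,
                          params_fitted = bm$fitted))
}

#' Extract the fetal ECG from a single-channel abdominal signal
#'
#' The full two-pass procedure: preprocess, estimate the maternal ECG with
#' a model-based filter and subtract it, denoise the fetal residual with a
#' second filter pass, then detect fetal QRS complexes on the denoised
#' trace. The residual plus the maternal estimate reconstructs the
#' preprocessed input exactly, sample for sample. With a fixed `seed` every
#' field of the result is reproducible.
#'
#' @param aecg A raw single-channel [annotated_signal()].
#' @param method `"enkf"` (default) or `"ekf"`; the same filter is used in
#'   both passes.
#' @param cfg An [extraction_config()].
#' @param n_ensemble Ensemble size (EnKF only; default 70).
#' @param seed Optional integer seed controlling all noise draws.
#' @return A list of class `fecg_extraction` with fields `input`,
#'   `preprocessed`, `mecg_hat`, `residual`, `fecg_hat` (all
#'   [annotated_signal()]s of the input length), `fqrs` and
#'   `maternal_peaks` ([peak_train()]s), `method`, and `diagnostics`.
#' @export
#' @examples
#' \donttest{
#' rec <- make_mixture(mixture_spec(duration = 20, seed = 1))
#' ex <- extract_fecg(rec$aecg, method = "enkf", seed = 1)
#' glance(ex)
#' }
extract_fecg <- function(aecg, method = c("enkf", "ekf"),
                         cfg = extraction_config(), n_ensemble = 70,
                         seed = NULL) {
  method <- match.arg(method)
  if (nrow(aecg) == 0L) stop("extract_fecg: empty input signal")
  if (!is.null(seed)) withr::local_seed(seed)
  pre <- with_stage("preprocess", preprocess_ecg(aecg, cfg$preprocess))
  m <- with_stage("estimate_mecg",
                  estimate_mecg(pre, cfg, method = method,
                                n_ensemble = n_ensemble))
  residual <- set_amplitude(pre, pre$amplitude - m$mecg$amplitude)
  f <- with_stage("denoise_fecg",
                  denoise_fecg(residual, cfg, method = method,
                               n_ensemble = n_ensemble))
  fqrs <- with_stage("fqrs_detection", suppressWarnings(
    pan_tompkins(f$fecg, band = cfg$fetal$band,
                 refractory = cfg$fetal$refractory)))
  if (isTRUE(cfg$refine_fetal) && nrow(fqrs) >= 10L &&
      !isTRUE(f$diagnostics$skipped)) {
    f <- with_stage("denoise_fecg_refined",
                    denoise_fecg(residual, cfg, method = method,
                                 n_ensemble = n_ensemble))
    fqrs <- suppressWarnings(pan_tompkins(f$fecg, band = cfg$fetal$band,
                                          refractory = cfg$fetal$refractory))
  }
  structure(list(
    input = aecg, preprocessed = pre, mecg_hat = m$mecg,
    residual = residual, fecg_hat = f$fecg, fqrs = fqrs,
    maternal_peaks = m$peaks, maternal_params = m$params,
    fetal_params = f$params, method = method, n_ensemble = n_ensemble,
    diagnostics = c(m$diagnostics, f$diagnostics,
                    list(n_fqrs = nrow(fqrs)))),
    class = "fecg_extraction")
}

with_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("[%s] %s", stage, conditionMessage(e)), call. = FALSE)
  })
}

#' @export
print.fecg_extraction <- function(x, ...) {
  cat("<fecg_extraction> method:", x$method,
      if (x$method == "enkf") paste0("(N = ", x$n_ensemble, ")"), "\n")
  cat("  samples:", nrow(x$input),
      " maternal beats:", x$diagnostics$n_maternal_beats,
      " fetal QRS detected:", x$diagnostics$n_fqrs, "\n")
  invisible(x)
}
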