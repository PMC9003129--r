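#' Synthesize a motion-artifact template
#'
#' Builds a realistic motion-noise waveform from three ingredients typical
#' of ambulatory electrode recordings: slow large excursions (body
#' movement), short broadband bursts (muscle activity), and step-like
#' electrode-pop transients with exponential recovery. The template is
#' scaled to unit peak amplitude, matching signals normalized to
#' \[-1, 1\].
#'
#' @param duration Template length in seconds.
#' @param fs Sampling rate in Hz.
#' @param seed Optional integer seed.
#' @param n_bursts,n_pops Expected event counts over the template.
#' @return An [annotated_signal()] of class `noise_template` with a
#'   `provenance` attribute.
#' @export
synth_motion_template <- function(duration = 30, fs = 1000, seed = NULL,
                                  n_bursts = 4, n_pops = 2) {
  if (!is.null(seed)) withr::local_seed(seed)
  n <- round(duration * fs)
  # slow lobes: lowpassed white noise below ~1.5 Hz
  bf <- signal::butter(2, 1.5 / (fs / 2), type = "low")
  slow <- signal::filtfilt(bf, stats::rnorm(n))
  slow <- slow / max(abs(slow))
  # broadband bursts with smooth envelopes
  burst <- numeric(n)
  for (i in seq_len(stats::rpois(1, n_bursts) + 1L)) {
    center <- stats::runif(1, 0.05, 0.95) * n
    width <- stats::runif(1, 0.1, 0.5) * fs
    env <- exp(-((seq_len(n) - center)^2) / (2 * width^2))
    burst <- burst + env * stats::rnorm(n, sd = 0.6)
  }
  # electrode pops: steps decaying exponentially
  pop <- numeric(n)
  for (i in seq_len(stats::rpois(1, n_pops) + 1L)) {
    at <- ceiling(stats::runif(1, 0.05, 0.95) * n)
    tau <- stats::runif(1, 0.2, 1.5) * fs
    amp <- sample(c(-1, 1), 1) * stats::runif(1, 0.5, 1.5)
    idx <- at:n
    pop[idx] <- pop[idx] + amp * exp(-(idx - at) / tau)
  }
  w <- 0.8 * slow + 0.5 * burst + 0.7 * pop
  w <- w / max(abs(w))
  out <- annotated_signal(w, fs = fs)
  attr(out, "provenance") <- "synthetic motion library (lobes+bursts+pops)"
  class(out) <- c("noise_template", class(out))
  out
}

#' Extract a motion-noise template from a recorded ECG
#'
#' Implements the template-construction recipe: normalize the recording
#' into \[-1, 1\], track its ECG content with the model-based extended
#' Kalman filter, and keep the difference (recording minus filtered ECG) as
#' the motion-noise template. The filter needs a detectable rhythm.
#'
#' @param recorded_ecg An [annotated_signal()] containing a single-channel
#'   ECG with motion contamination.
#' @param cfg An [extraction_config()] (detector and fit settings).
#' @return An [annotated_signal()] of class `noise_template`.
#' @export
extract_motion_noise <- function(recorded_ecg, cfg = extraction_config()) {
  norm <- normalize_unit(recorded_ecg)
  # rhythm is detected on a baseline-cleaned copy (slow motion lobes are
  # exactly baseline wander); the template itself is built from the plain
  # normalized signal
  det_in <- remove_baseline(norm, cutoff = 1)
  peaks <- tryCatch(
    suppressWarnings(pan_tompkins(det_in, band = cfg$maternal$band,
                                  refractory = cfg$maternal$refractory)),
    error = function(e) peak_train(integer(), signal_fs(norm)))
  if (nrow(peaks) < 10L) {
    stop("extract_motion_noise: rhythm undetectable in the recording")
  }
  fs <- signal_fs(norm)
  phase <- assign_phase(peaks, nrow(norm))
  bm <- beat_model_for(norm$amplitude, phase$phi, fs, cfg$fit_params,
                       cfg$bins, allow_fallback = TRUE)
  r_z <- isoelectric_var(norm$amplitude, phase$phi, bm$params$waves)
  q_z <- cfg$eta_var_scale * bm$residual_var
  omega <- omega_from_peaks(peaks, nrow(norm), fs)
  res <- filter_pass(norm$amplitude, phase$phi, omega, bm$params, cfg,
                     method = "ekf", n_ensemble = 2, r_z = r_z, q_z = q_z)
  # the ECG content is reconstructed from the fitted beat morphology
  # evaluated along the EKF-filtered phase trace: unlike the integrated
  # amplitude state, this reconstruction cannot drift, so slow motion
  # components stay in the template rather than being absorbed
  ecg_hat <- gaussian_sum(res$theta_hat, bm$params$waves) + bm$offset
  tpl <- set_amplitude(norm, norm$amplitude - ecg_hat)
  if (max(abs(tpl$amplitude)) > 2) {
    stop("extract_motion_noise: template amplitude outside [-2, 2]")
  }
  attr(tpl, "provenance") <- "extracted from recorded ECG (EKF residual)"
  class(tpl) <- c("noise_template", class(tpl))
  tpl
}

#' Add motion noise to an abdominal recording
#'
#' Normalizes the abdominal signal into \[-1, 1\] (the same convention the
#' template was built with), tiles the template over the record length with
#' a random circular offset, and adds it scaled by `gain`. Ground-truth
#' peak annotations are carried through unchanged: corruption may change
#' what a detector finds, never where the true beats are.
#'
#' @param aecg An [annotated_signal()].
#' @param template A `noise_template` at the same sampling rate.
#' @param gain Noise gain (0 returns the normalized input exactly).
#' @param seed Optional integer seed for the circular offset.
#' @return A normalized, corrupted [annotated_signal()].
#' @export
add_motion_noise <- function(aecg, template, gain = 1, seed = NULL) {
  fs <- signal_fs(aecg)
  if (abs(signal_fs(template) - fs) > 1e-9) {
    stop("add_motion_noise: template sampling rate does not match the record")
  }
  if (!is.null(seed)) withr::local_seed(seed)
  norm <- normalize_unit(aecg)
  n <- nrow(norm)
  tpl <- template$amplitude
  offset <- sample.int(length(tpl), 1) - 1L
  tiled <- rep(c(tpl[(offset + 1):length(tpl)], tpl[seq_len(offset)]),
               length.out = n)
  out <- set_amplitude(norm, norm$amplitude + gain * tiled)
  attr(out, "norm_center") <- attr(norm, "norm_center")
  attr(out, "norm_scale") <- attr(norm, "norm_scale")
  out
}

#' Write or read a noise template as CSV
#'
#' Plain-text serialization with a small commented header carrying the
#' sampling rate and provenance.
#'
#' @param template A `noise_template`.
#' @param path File path.
#' @return `read_noise_template()` returns a `noise_template`.
#' @export
write_noise_template <- function(template, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# fs=%g", signal_fs(template)),
               sprintf("# provenance=%s", attr(template, "provenance"))), con)
  utils::write.csv(data.frame(sample_index = seq_len(nrow(template)) - 1L,
                              amplitude = template$amplitude),
                   con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_noise_template
#' @export
read_noise_template <- function(path) {
  hdr <- readLines(path, n = 2)
  fs <- as.numeric(sub("# fs=", "", hdr[1], fixed = TRUE))
  if (is.na(fs)) stop("read_noise_template: missing fs header")
  prov <- sub("# provenance=", "", hdr[2], fixed = TRUE)
  df <- utils::read.csv(path, comment.char = "#")
  out <- annotated_signal(df$amplitude, fs = fs)
  attr(out, "provenance") <- prov
  class(out) <- c("noise_template", class(out))
  out
}
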