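#' Specification of a synthetic abdominal mixture
#'
#' Describes a fully annotated maternal+fetal abdominal ECG mixture: two
#' independent beat trains generated from the dynamic ECG model (the fetal
#' one smaller, narrower and faster, possibly with reversed polarity),
#' additive white noise referenced to the fetal component power, plus
#' baseline-wander and powerline terms.
#'
#' @param maternal_hr,fetal_hr Heart rates in bpm (fetal typically faster:
#'   defaults 80 and 140).
#' @param hrv_sd Per-beat R-R jitter standard deviation in seconds.
#' @param fetal_gain Fetal-to-maternal R-amplitude ratio, in (0, 1).
#' @param fetal_polarity +1 or -1 (electrode placement can reverse the
#'   fetal complexes).
#' @param noise_snr Additive white-noise SNR in dB relative to the fetal
#'   component (the harder signal); `Inf` disables it.
#' @param baseline,powerline Numeric `c(amplitude, freq)` pairs for the
#'   sinusoidal baseline-wander and powerline terms (amplitude 0 disables).
#' @param duration Record length in seconds.
#' @param fs Sampling rate in Hz.
#' @param seed Integer seed making the record reproducible.
#' @param eta_sd Per-sample amplitude process-noise s.d. of both generators.
#' @return A list of class `mixture_spec`.
#' @export
mixture_spec <- function(maternal_hr = 80, fetal_hr = 140, hrv_sd = 0.02,
                         fetal_gain = 0.25, fetal_polarity = 1,
                         noise_snr = 12, baseline = c(3, 0.3),
                         powerline = c(1.5, 50), duration = 60, fs = 1000,
                         seed = 1, eta_sd = 0.02) {
  spec <- list(maternal_hr = maternal_hr, fetal_hr = fetal_hr,
               hrv_sd = hrv_sd, fetal_gain = fetal_gain,
               fetal_polarity = fetal_polarity, noise_snr = noise_snr,
               baseline = baseline, powerline = powerline,
               duration = duration, fs = fs, seed = seed, eta_sd = eta_sd)
  checks <- c(
    maternal_hr = maternal_hr > 0,
    fetal_hr = fetal_hr > 0,
    hrv_sd = hrv_sd >= 0,
    fetal_gain = fetal_gain >= 0 && fetal_gain < 1,
    fetal_polarity = fetal_polarity %in% c(-1, 1),
    noise_snr = is.numeric(noise_snr),
    baseline = length(baseline) == 2 && baseline[1] >= 0,
    powerline = length(powerline) == 2 && powerline[1] >= 0,
    duration = duration * fs >= 2 * fs,  # at least 2 s of samples
    fs = fs > 0,
    seed = is.numeric(seed),
    eta_sd = eta_sd >= 0)
  if (!all(checks)) {
    stop("mixture_spec: invalid fields: ",
         paste(names(checks)[!checks], collapse = ", "))
  }
  structure(spec, class = "mixture_spec")
}

# Jittered beat times covering [0, duration], first beat at `first`.
beat_times <- function(hr, hrv_sd, duration, first = 0, min_rr = 0.25) {
  rr0 <- 60 / hr
  n <- ceiling((duration - first) / rr0) + 3L
  rr <- pmax(rr0 + stats::rnorm(n, 0, hrv_sd), min_rr)
  t <- first + c(0, cumsum(rr))
  t[t <= duration + rr0]
}

fetal_waves_for <- function(spec) {
  w <- mcsharry_waves()
  w$alpha <- w$alpha * spec$fetal_gain * spec$fetal_polarity
  w$b <- w$b * 0.5
  w
}

build_mixture <- function(spec, m_times, f_times) {
  fs <- spec$fs
  n <- round(spec$duration * fs)
  m_params <- ecg_model_params(delta = 1 / fs, eta_var = spec$eta_sd^2,
                               obs_noise = c(phi = 0, s = 0))
  f_params <- ecg_model_params(waves = fetal_waves_for(spec), delta = 1 / fs,
                               eta_var = (spec$eta_sd * spec$fetal_gain)^2,
                               obs_noise = c(phi = 0, s = 0))
  m_rr <- diff(m_times)
  f_rr <- diff(f_times)
  maternal <- generate_beat_train(m_params, spec$duration,
                                  rr_series = m_rr, first_peak = m_times[1])
  fetal <- generate_beat_train(f_params, spec$duration,
                               rr_series = f_rr, first_peak = f_times[1])
  t <- (seq_len(n) - 1) / fs
  noise <- numeric(n)
  if (is.finite(spec$noise_snr)) {
    p_fetal <- mean(fetal$amplitude^2)
    noise <- stats::rnorm(n, 0, sqrt(p_fetal / 10^(spec$noise_snr / 10)))
  }
  if (spec$baseline[1] > 0) {
    noise <- noise + spec$baseline[1] *
      sin(2 * pi * spec$baseline[2] * t + stats::runif(1, 0, 2 * pi))
  }
  if (spec$powerline[1] > 0) {
    noise <- noise + spec$powerline[1] *
      sin(2 * pi * spec$powerline[2] * t + stats::runif(1, 0, 2 * pi))
  }
  mix <- maternal$amplitude + fetal$amplitude + noise
  aecg <- annotated_signal(mix, fs = fs, peaks = signal_peaks(fetal))
  structure(list(
    aecg = aecg,
    maternal_clean = maternal, fetal_clean = fetal,
    noise = annotated_signal(noise + 0, fs = fs),
    maternal_peaks = peak_train(signal_peaks(maternal), fs),
    fetal_peaks = peak_train(signal_peaks(fetal), fs,
                             polarity = spec$fetal_polarity),
    spec = spec), class = "mixture_record")
}

#' Simulate an annotated abdominal mixture
#'
#' Generates maternal and fetal beat trains from the dynamic ECG model
#' (fetal waves narrower by half and scaled by `fetal_gain * polarity`),
#' sums them with white noise at the requested SNR plus baseline and
#' powerline terms, and keeps every component and both ground-truth peak
#' trains. The stored components always sum to the mixture exactly.
#'
#' @param spec A [mixture_spec()].
#' @return A list of class `mixture_record` with fields `aecg`,
#'   `maternal_clean`, `fetal_clean`, `noise` ([annotated_signal()]s),
#'   `maternal_peaks`, `fetal_peaks` ([peak_train()]s) and `spec`.
#' @export
#' @examples
#' rec <- make_mixture(mixture_spec(duration = 10, seed = 42))
#' nrow(rec$fetal_peaks)
make_mixture <- function(spec = mixture_spec()) {
  stopifnot(inherits(spec, "mixture_spec"))
  withr::local_seed(spec$seed)
  m_times <- beat_times(spec$maternal_hr, spec$hrv_sd, spec$duration)
  f0 <- stats::runif(1, 0, 60 / spec$fetal_hr)
  f_times <- beat_times(spec$fetal_hr, spec$hrv_sd, spec$duration, first = f0)
  build_mixture(spec, m_times, f_times)
}

#' Simulate a mixture with forced QRS overlaps
#'
#' Phase-adjusts the fetal beat times so that at least `overlap_fraction`
#' of the fetal R-peaks fall within 30 ms of a maternal R-peak — the
#' regime where subtraction-based extraction is hardest. With
#' `overlap_fraction = 0` fetal peaks are instead pushed at least 30 ms
#' away from every maternal peak. Which fetal beats ended up overlapped is
#' recorded in the result's `overlap` field.
#'
#' @param spec A [mixture_spec()].
#' @param overlap_fraction Requested fraction in \[0, 1\].
#' @param window Overlap window in seconds (default 0.03).
#' @return A `mixture_record` with an extra logical field `overlap` (one
#'   entry per fetal peak) and `achieved_overlap`.
#' @export
make_overlap_stressor <- function(spec = mixture_spec(), overlap_fraction,
                                  window = 0.03) {
  stopifnot(inherits(spec, "mixture_spec"),
            overlap_fraction >= 0, overlap_fraction <= 1)
  withr::local_seed(spec$seed)
  m_times <- beat_times(spec$maternal_hr, spec$hrv_sd, spec$duration)
  rr_f <- 60 / spec$fetal_hr
  min_rr <- 0.25
  # build the fetal beat times sequentially; designated beats are re-anchored
  # onto the nearest admissible maternal peak and later beats follow from
  # there, so RR statistics are preserved while overlap pressure is forced
  nf_nominal <- ceiling(spec$duration / rr_f) + 1L
  k <- ceiling(overlap_fraction * nf_nominal)
  targets <- if (k > 0) unique(round(seq(1, nf_nominal, length.out = k))) else integer()
  f_times <- numeric(0)
  t <- stats::runif(1, 0, rr_f)
  i <- 1L
  while (t <= spec$duration) {
    if (overlap_fraction > 0 && i %in% targets) {
      # admissible maternal peaks keep the fetal RR above the refractory
      # floor; the nearest one is at most half a maternal interval away,
      # so the shift bound is set from the maternal rate
      ok <- m_times[m_times - dplyr::last(f_times, default = -Inf) >= min_rr &
                      m_times <= spec$duration]
      if (length(ok)) {
        m <- ok[which.min(abs(ok - t))]
        if (abs(m - t) <= 0.6 * 60 / spec$maternal_hr) t <- m
      }
    } else if (overlap_fraction == 0) {
      m <- m_times[which.min(abs(m_times - t))]
      d <- t - m
      if (abs(d) < 2 * window) t <- m + sign(d + 1e-12) * 2 * window
    }
    prev <- dplyr::last(f_times, default = -Inf)
    if (t - prev >= min_rr && t <= spec$duration) f_times <- c(f_times, t)
    t <- t + max(rr_f + stats::rnorm(1, 0, spec$hrv_sd), min_rr)
    i <- i + 1L
  }
  overlap <- vapply(f_times, function(t) min(abs(m_times - t)) <= window,
                    logical(1))
  achieved <- mean(overlap)
  if (overlap_fraction > 0 && achieved < overlap_fraction - 0.05) {
    stop("make_overlap_stressor: requested overlap fraction infeasible ",
         "at these heart rates (achieved ", round(achieved, 3), ")")
  }
  rec <- build_mixture(spec, m_times, f_times)
  keep <- rec$fetal_peaks$time
  rec$overlap <- vapply(keep, function(t) min(abs(m_times - t)) <= window,
                        logical(1))
  rec$achieved_overlap <- achieved
  rec
}
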