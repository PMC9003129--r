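#' Preprocessing configuration
#'
#' Settings for the raw-signal cleanup chain applied before extraction:
#' baseline-wander removal, powerline notch, and stationary-wavelet
#' denoising. Stages run in the order given by `stages`; an empty `stages`
#' yields the identity.
#'
#' @param baseline_cutoff Baseline-estimator lowpass cutoff in Hz (> 0).
#' @param notch_freq Powerline frequency in Hz (50 or 60 typically).
#' @param notch_q Notch quality factor (bandwidth = freq / q).
#' @param swt_levels Stationary-wavelet decomposition depth (>= 1).
#' @param wavelet Wavelet family name (only the embedded `"coif5"` filters
#'   are shipped).
#' @param threshold_rule `"soft"` or `"hard"` detail thresholding.
#' @param stages Character vector, ordered subset of
#'   `c("baseline", "notch", "wavelet")`. Wavelet denoising is off by
#'   default: over-aggressive thresholding can erase the low-amplitude fetal
#'   complexes it is meant to expose.
#' @return A list of class `preprocess_config`.
#' @export
preprocess_config <- function(baseline_cutoff = 1, notch_freq = 50,
                              notch_q = 30, swt_levels = 10,
                              wavelet = "coif5",
                              threshold_rule = c("soft", "hard"),
                              stages = c("baseline", "notch")) {
  stopifnot(baseline_cutoff > 0, notch_freq > 0, notch_q > 0, swt_levels >= 1,
            all(stages %in% c("baseline", "notch", "wavelet")))
  structure(list(baseline_cutoff = baseline_cutoff, notch_freq = notch_freq,
                 notch_q = notch_q, swt_levels = swt_levels,
                 wavelet = wavelet,
                 threshold_rule = match.arg(threshold_rule),
                 stages = stages),
            class = "preprocess_config")
}

#' Remove baseline wander
#'
#' Estimates the slow baseline with a zero-phase (forward-backward)
#' Butterworth lowpass at `cutoff` and subtracts it, leaving the QRS
#' morphology untouched. Functionally a highpass, but realized as
#' estimate-then-subtract so the cutoff parameter names the baseline
#' estimator.
#'
#' @param x An [annotated_signal()].
#' @param cutoff Baseline-estimator cutoff in Hz (default 1, must be below
#'   Nyquist).
#' @return An [annotated_signal()].
#' @export
remove_baseline <- function(x, cutoff = 1) {
  fs <- signal_fs(x)
  if (cutoff >= fs / 2) stop("remove_baseline: cutoff must be below Nyquist")
  bf <- signal::butter(2, cutoff / (fs / 2), type = "low")
  baseline <- signal::filtfilt(bf, x$amplitude)
  set_amplitude(x, x$amplitude - baseline)
}

#' Notch out powerline interference
#'
#' Zero-phase second-order IIR notch at `freq` with quality factor `q`
#' (bandwidth `freq/q`). Forward-backward filtering doubles the stopband
#' attenuation and cancels phase distortion, preserving peak timing.
#'
#' @param x An [annotated_signal()].
#' @param freq Notch center frequency in Hz (below Nyquist).
#' @param q Quality factor.
#' @return An [annotated_signal()].
#' @export
notch_filter <- function(x, freq = 50, q = 30) {
  fs <- signal_fs(x)
  if (freq >= fs / 2) stop("notch_filter: freq must be below Nyquist")
  w0 <- 2 * pi * freq / fs
  a0 <- sin(w0) / (2 * q)
  b <- c(1, -2 * cos(w0), 1) / (1 + a0)
  a <- c(1, -2 * cos(w0) / (1 + a0), (1 - a0) / (1 + a0))
  out <- signal::filtfilt(b, a, x$amplitude)
  set_amplitude(x, out)
}

# Orthonormal Coiflet-5 scaling (lowpass) decomposition filter.
coif5_dec_lo <- c(
  -9.604010112767894e-08, -1.6237995172048338e-07, 2.0612203985788783e-06,
  3.7007277113394796e-06, -2.1270221672515614e-05, -4.12198619242655e-05,
  0.00014035632812373243, 0.0003018579416682448, -0.0006375589261258812,
  -0.0016616273039298788, 0.0024315754425382886, 0.006761520220620417,
  -0.009159507338676163, -0.019758391600965465, 0.032674799467057355,
  0.041287530472117834, -0.10556315130733723, -0.06203775157498196,
  0.4379823066591634, 0.7742936228603274, 0.42157126673075435,
  -0.052046670253554764, -0.09192158806008609, 0.028169744270532353,
  0.023408322118927783, -0.010131584846900276, -0.00415931262757864,
  0.0021782943778456947, 0.0003585777411617577, -0.000212081862067494)

swt_filters <- function(wavelet) {
  if (!identical(wavelet, "coif5")) {
    stop("wavelet_denoise: only the embedded 'coif5' filters are available")
  }
  h <- coif5_dec_lo
  nh <- length(h)
  g <- rev(h) * (-1)^(seq_len(nh) - 1)  # quadrature mirror highpass
  list(h = h, g = g)
}

# FFT of a filter upsampled by `up` (a-trous), zero-padded to length L.
filter_fft <- function(f, up, L) {
  idx <- (seq_along(f) - 1) * up
  v <- numeric(L)
  v[(idx %% L) + 1] <- v[(idx %% L) + 1] + f
  stats::fft(v)
}

#' Stationary-wavelet denoising
#'
#' Undecimated (shift-invariant) wavelet decomposition with Coiflet-5
#' filters, per-level detail thresholding with the universal threshold
#' `sigma * sqrt(2 * log(L))` where `sigma = MAD(level-1 detail) / 0.6745`,
#' and exact inverse transform. All convolutions are circular and computed
#' in the frequency domain; the signal is reflection-padded to a multiple of
#' `2^levels` and the padding removed afterwards.
#'
#' @param x An [annotated_signal()].
#' @param cfg A [preprocess_config()] (fields `swt_levels`, `wavelet`,
#'   `threshold_rule` are used).
#' @param threshold Optional fixed threshold overriding the universal rule
#'   (0 disables thresholding, giving perfect reconstruction).
#' @return An [annotated_signal()].
#' @export
wavelet_denoise <- function(x, cfg = preprocess_config(), threshold = NULL) {
  flt <- swt_filters(cfg$wavelet)
  n <- nrow(x)
  if (n < length(flt$h)) {
    stop("wavelet_denoise: signal shorter than the wavelet filter support")
  }
  J <- cfg$swt_levels
  block <- 2^J
  L <- as.integer(block * ceiling(n / block))
  pad <- L - n
  amp <- x$amplitude
  padded <- if (pad > 0) {
    refl <- rev(amp)[seq_len(min(pad, n))]
    c(amp, rep(refl, length.out = pad))
  } else amp
  A <- stats::fft(padded)
  Hs <- vector("list", J); Gs <- vector("list", J)
  details <- vector("list", J)
  for (j in seq_len(J)) {
    up <- 2^(j - 1)
    Hs[[j]] <- filter_fft(flt$h, up, L)
    Gs[[j]] <- filter_fft(flt$g, up, L)
    details[[j]] <- Re(stats::fft(A * Gs[[j]], inverse = TRUE)) / L
    A <- A * Hs[[j]]
  }
  thr <- threshold
  if (is.null(thr)) {
    sigma <- stats::mad(details[[1]])  # MAD / 0.6745
    thr <- sigma * sqrt(2 * log(L))
  }
  shrink <- switch(cfg$threshold_rule,
    soft = function(d) sign(d) * pmax(abs(d) - thr, 0),
    hard = function(d) d * (abs(d) > thr))
  for (j in seq_len(J)) details[[j]] <- shrink(details[[j]])
  for (j in rev(seq_len(J))) {
    A <- (A * Conj(Hs[[j]]) + stats::fft(details[[j]]) * Conj(Gs[[j]])) / 2
  }
  out <- Re(stats::fft(A, inverse = TRUE)) / L
  set_amplitude(x, out[seq_len(n)])
}

#' Normalize a signal into \[-1, 1\]
#'
#' Affine map putting the minimum at -1 and the maximum at +1. The center
#' and scale are stored as attributes (`norm_center`, `norm_scale`) so the
#' map is invertible with [denormalize_unit()].
#'
#' @param x An [annotated_signal()].
#' @return A normalized [annotated_signal()] carrying `norm_center` and
#'   `norm_scale` attributes.
#' @export
normalize_unit <- function(x) {
  r <- range(x$amplitude)
  if (diff(r) <= 0) stop("normalize_unit: constant signal cannot be normalized")
  center <- mean(r)
  scale <- 2 / diff(r)
  out <- set_amplitude(x, (x$amplitude - center) * scale)
  attr(out, "norm_center") <- center
  attr(out, "norm_scale") <- scale
  out
}

#' @rdname normalize_unit
#' @param center,scale Override the stored normalization record.
#' @export
denormalize_unit <- function(x, center = attr(x, "norm_center"),
                             scale = attr(x, "norm_scale")) {
  if (is.null(center) || is.null(scale)) {
    stop("denormalize_unit: no normalization record found")
  }
  set_amplitude(x, x$amplitude / scale + center)
}

#' Run the preprocessing chain
#'
#' Applies the stages named in `cfg$stages`, in order. With no stages the
#' input is returned unchanged.
#'
#' @param x An [annotated_signal()].
#' @param cfg A [preprocess_config()].
#' @return An [annotated_signal()].
#' @export
preprocess_ecg <- function(x, cfg = preprocess_config()) {
  for (stage in cfg$stages) {
    x <- switch(stage,
      baseline = remove_baseline(x, cfg$baseline_cutoff),
      notch = notch_filter(x, cfg$notch_freq, cfg$notch_q),
      wavelet = wavelet_denoise(x, cfg),
      stop("preprocess_ecg: unknown stage ", stage))
  }
  x
}
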