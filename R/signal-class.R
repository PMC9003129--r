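#' Annotated ECG signal
#'
#' The basic container for a sampled waveform: a tibble with columns `time`
#' (seconds) and `amplitude` (signal units), carrying the sampling rate and
#' optional ground-truth R-peak sample indices as attributes. All processing
#' functions in the package take and return this container, so calls chain
#' with the pipe.
#'
#' @param amplitude Numeric vector of samples.
#' @param fs Sampling rate in Hz.
#' @param peaks Optional integer vector of 1-based R-peak sample indices.
#' @param t0 Time of the first sample in seconds.
#' @return A tibble of class `annotated_signal` with columns `time`,
#'   `amplitude`.
#' @export
#' @examples
#' s <- annotated_signal(sin(2 * pi * 5 * seq(0, 1, by = 1 / 250)), fs = 250)
#' signal_fs(s)
annotated_signal <- function(amplitude, fs, peaks = integer(), t0 = 0) {
  stopifnot(is.numeric(amplitude), length(amplitude) >= 1L,
            is.numeric(fs), fs > 0)
  if (anyNA(amplitude) || any(!is.finite(amplitude))) {
    stop("annotated_signal: amplitude contains non-finite values")
  }
  peaks <- as.integer(peaks)
  if (length(peaks) && (any(peaks < 1L) || any(peaks > length(amplitude)))) {
    stop("annotated_signal: peak indices outside the signal")
  }
  out <- tibble::tibble(
    time = t0 + (seq_along(amplitude) - 1) / fs,
    amplitude = as.numeric(amplitude)
  )
  attr(out, "fs") <- fs
  attr(out, "peaks") <- peaks
  class(out) <- c("annotated_signal", class(out))
  out
}

#' @rdname annotated_signal
#' @param x An `annotated_signal`.
#' @export
signal_fs <- function(x) {
  fs <- attr(x, "fs")
  if (is.null(fs)) {
    if (!is.data.frame(x) || !"time" %in% names(x) || nrow(x) < 2L) {
      stop("cannot determine sampling rate: no fs attribute and no time column")
    }
    fs <- 1 / stats::median(diff(x$time))
  }
  fs
}

#' @rdname annotated_signal
#' @export
signal_peaks <- function(x) {
  p <- attr(x, "peaks")
  if (is.null(p)) integer() else p
}

#' Replace the samples of a signal, keeping rate and annotations
#'
#' @param x An `annotated_signal`.
#' @param amplitude New sample vector (same length as `x`).
#' @return An `annotated_signal`.
#' @keywords internal
set_amplitude <- function(x, amplitude) {
  stopifnot(length(amplitude) == nrow(x))
  annotated_signal(amplitude, fs = signal_fs(x), peaks = signal_peaks(x),
                   t0 = x$time[1])
}

#' Peak train
#'
#' Detected or ground-truth R-peak locations: a tibble with columns `sample`
#' (1-based index) and `time` (seconds), with the sampling rate and dominant
#' QRS polarity as attributes.
#'
#' @param sample Integer vector of strictly increasing 1-based sample indices.
#' @param fs Sampling rate in Hz.
#' @param polarity +1 or -1, dominant QRS polarity.
#' @return A tibble of class `peak_train`.
#' @export
peak_train <- function(sample, fs, polarity = 1) {
  sample <- as.integer(sample)
  if (length(sample) > 1L && any(diff(sample) <= 0L)) {
    stop("peak_train: sample indices must be strictly increasing")
  }
  out <- tibble::tibble(sample = sample, time = (sample - 1L) / fs)
  attr(out, "fs") <- fs
  attr(out, "polarity") <- polarity
  class(out) <- c("peak_train", class(out))
  out
}

#' @rdname peak_train
#' @param x A `peak_train`.
#' @export
peak_samples <- function(x) {
  if (inherits(x, "peak_train") || is.data.frame(x)) as.integer(x$sample)
  else as.integer(x)
}

# ---- small angular helpers used throughout ---------------------------------

#' Wrap angles
#'
#' `wrap_2pi()` maps into `[0, 2*pi)`; `wrap_pi()` maps into `[-pi, pi)`.
#' The latter is the convention used for the per-wave phase increments of the
#' dynamic ECG model, so each Gaussian wave acts locally around its center.
#'
#' @param x Numeric vector of angles (radians).
#' @return Wrapped angles.
#' @export
wrap_2pi <- function(x) x %% (2 * pi)

#' @rdname wrap_2pi
#' @export
wrap_pi <- function(x) ((x + pi) %% (2 * pi)) - pi
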