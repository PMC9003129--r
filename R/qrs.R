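#' Pan-Tompkins R-peak detection
#'
#' Classic stage chain: zero-phase bandpass, five-point derivative,
#' squaring, 150 ms moving-window integration, then adaptive dual
#' thresholds with search-back over the integrator peaks. Each accepted
#' integrator peak is refined to the local absolute-amplitude extremum of
#' the bandpassed signal within +/- 40 ms, so the squaring stage makes the
#' detector insensitive to QRS polarity (fetal complexes are often
#' reversed by electrode placement).
#'
#' Maternal defaults are `band = c(5, 15)` Hz and a 250 ms refractory
#' period; for fetal detection use `band = c(10, 30)` and
#' `refractory = 0.2` (fetal rates reach ~200 bpm).
#'
#' @param x An [annotated_signal()] at least 2 s long.
#' @param band Bandpass corner frequencies in Hz; `fs >= 2 * band[2]`.
#' @param refractory Minimum peak spacing in seconds.
#' @return A [peak_train()] (empty, with a warning, when nothing is found).
#' @export
pan_tompkins <- function(x, band = c(5, 15), refractory = 0.25) {
  fs <- signal_fs(x)
  n <- nrow(x)
  if (fs < 2 * band[2]) stop("pan_tompkins: sampling rate below 2x band top")
  if (n < 2 * fs) stop("pan_tompkins: need at least 2 s of signal")
  amp <- x$amplitude
  if (all(abs(amp - amp[1]) < .Machine$double.eps)) {
    warning("pan_tompkins: flat signal, no peaks found")
    return(peak_train(integer(), fs))
  }
  bf <- signal::butter(3, band / (fs / 2), type = "pass")
  bp <- signal::filtfilt(bf, amp)
  # five-point derivative, centred (zero-phase)
  kern <- c(1, 2, 0, -2, -1) * fs / 8
  der <- stats::filter(bp, kern, sides = 2)
  der[is.na(der)] <- 0
  sq <- as.numeric(der)^2
  w <- max(3L, round(0.15 * fs))
  mwi <- as.numeric(stats::filter(sq, rep(1 / w, w), sides = 2))
  mwi[is.na(mwi)] <- 0
  mwi[c(seq_len(w), (n - w + 1L):n)] <- 0  # drop filter warm-up transients

  ref_n <- max(1L, round(refractory * fs))
  cand <- local_maxima(mwi, min_sep = ref_n)
  if (!length(cand)) {
    warning("pan_tompkins: no peaks found")
    return(peak_train(integer(), fs))
  }

  # adaptive dual thresholds over the integrator peaks; initialized from
  # candidate quantiles (robust to isolated large artifacts), with the
  # signal-level update clamped so one outlier cannot lock the detector out
  spki <- as.numeric(stats::quantile(mwi[cand], 0.75))
  npki <- as.numeric(stats::quantile(mwi[cand], 0.25))
  accepted <- integer()
  rr_avg <- NA_real_
  last <- -Inf
  i <- 1L
  while (i <= length(cand)) {
    p <- cand[i]
    thr1 <- npki + 0.25 * (spki - npki)
    if (mwi[p] > thr1 && (p - last) >= ref_n) {
      accepted <- c(accepted, p)
      spki <- 0.125 * min(mwi[p], 4 * spki) + 0.875 * spki
      if (length(accepted) >= 2L) {
        rrs <- diff(utils::tail(accepted, 8))
        rr_avg <- mean(rrs)
      }
      last <- p
    } else {
      npki <- 0.125 * mwi[p] + 0.875 * npki
      # search-back: long gap since the last beat -> retry at half threshold
      if (!is.na(rr_avg) && length(accepted) && (p - last) > 1.66 * rr_avg &&
          mwi[p] > 0.5 * thr1 && (p - last) >= ref_n) {
        accepted <- c(accepted, p)
        spki <- 0.25 * mwi[p] + 0.75 * spki
        last <- p
      }
    }
    i <- i + 1L
  }
  if (!length(accepted)) {
    warning("pan_tompkins: no peaks found")
    return(peak_train(integer(), fs))
  }
  # refine to the absolute extremum of the bandpassed signal within 40 ms
  w40 <- as.integer(round(0.04 * fs))
  refined <- vapply(accepted, function(p) {
    lo <- max(1L, as.integer(p) - w40); hi <- min(n, as.integer(p) + w40)
    lo + which.max(abs(bp[lo:hi])) - 1L
  }, integer(1))
  refined <- sort(unique(refined))
  if (length(refined) > 1L) {
    keep <- c(TRUE, diff(refined) >= ref_n)
    while (!all(keep)) {
      refined <- refined[keep]
      keep <- c(TRUE, diff(refined) >= ref_n)
    }
  }
  polarity <- if (stats::median(bp[refined]) >= 0) 1 else -1
  peak_train(refined, fs, polarity = polarity)
}

local_maxima <- function(v, min_sep = 1L) {
  n <- length(v)
  if (n < 3L) return(integer())
  idx <- which(v[2:(n - 1)] > v[1:(n - 2)] & v[2:(n - 1)] >= v[3:n]) + 1L
  idx <- idx[v[idx] > 0]
  if (!length(idx) || min_sep <= 1L) return(idx)
  # greedy suppression: keep the larger of any pair closer than min_sep
  ord <- idx[order(v[idx], decreasing = TRUE)]
  keep <- logical(n)
  blocked <- logical(n)
  for (p in ord) {
    if (!blocked[p]) {
      keep[p] <- TRUE
      lo <- max(1L, p - min_sep + 1L); hi <- min(n, p + min_sep - 1L)
      blocked[lo:hi] <- TRUE
    }
  }
  sort(which(keep))
}

#' Linear phase wrapping of R-R intervals
#'
#' Converts an R-peak train into the per-sample observed phase: within each
#' R-R interval the phase grows linearly from 0 to `2*pi` and wraps at the
#' next peak, so phase 0 coincides exactly with every peak. Samples before
#' the first peak and after the last are extrapolated with the nearest
#' observed R-R interval.
#'
#' @param peaks A [peak_train()] (or integer vector of sample indices) with
#'   at least two peaks.
#' @param n_samples Length of the signal the phase is for.
#' @return A tibble of class `phase_series` with columns `sample`, `phi`;
#'   the source peaks are kept in the `source_peaks` attribute.
#' @export
#' @examples
#' assign_phase(c(1, 5), n_samples = 5)
assign_phase <- function(peaks, n_samples) {
  pk <- peak_samples(peaks)
  if (length(pk) < 2L) stop("assign_phase: need at least 2 peaks")
  k <- seq_len(n_samples)
  j <- findInterval(k, pk)
  rr <- diff(pk)
  rr_of <- c(rr[1], rr, rr[length(rr)])
  anchor <- c(pk[1], pk)
  phi <- wrap_2pi(2 * pi * (k - anchor[j + 1]) / rr_of[j + 1])
  out <- tibble::tibble(sample = k, phi = phi)
  attr(out, "source_peaks") <- peaks
  class(out) <- c("phase_series", class(out))
  out
}
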