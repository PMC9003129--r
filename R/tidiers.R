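#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy an extraction result
#'
#' Returns the component waveforms in long format: one row per sample and
#' component (`aecg`, `preprocessed`, `mecg_hat`, `residual`, `fecg_hat`).
#'
#' @param x An `fecg_extraction`.
#' @param ... Unused.
#' @return A tibble with columns `time`, `component`, `amplitude`.
#' @export
tidy.fecg_extraction <- function(x, ...) {
  comps <- list(aecg = x$input, preprocessed = x$preprocessed,
                mecg_hat = x$mecg_hat, residual = x$residual,
                fecg_hat = x$fecg_hat)
  purrr::imap(comps, function(s, nm) {
    tibble::tibble(time = s$time, component = nm, amplitude = s$amplitude)
  }) |>
    purrr::list_rbind() |>
    dplyr::mutate(component = factor(.data$component, levels = names(comps)))
}

#' One-row summary of an extraction
#'
#' @param x An `fecg_extraction`.
#' @param ... Unused.
#' @return A one-row tibble of per-stage diagnostics.
#' @export
glance.fecg_extraction <- function(x, ...) {
  d <- x$diagnostics
  tibble::tibble(
    method = x$method,
    n_ensemble = if (x$method == "enkf") x$n_ensemble else NA_integer_,
    n_samples = nrow(x$input),
    n_maternal_beats = d$n_maternal_beats,
    n_fqrs = d$n_fqrs,
    maternal_fit_residual = d$fit_residual_var,
    fetal_denoise_skipped = isTRUE(d$skipped))
}

#' Tidy a beat-parameter fit
#'
#' @param x An `ecg_beat_fit`.
#' @param ... Unused.
#' @return A tibble with one row per wave (`wave`, `alpha`, `b`, `theta`).
#' @export
tidy.ecg_beat_fit <- function(x, ...) x$params$waves

#' @rdname tidy.ecg_beat_fit
#' @export
glance.ecg_beat_fit <- function(x, ...) {
  tibble::tibble(residual_var = x$residual_var, offset = x$offset,
                 converged = x$converged, n_points = x$n_points)
}

#' Summary table of a benchmark
#'
#' @param x An `fecg_benchmark` (output of [evaluate_batch()]).
#' @param ... Unused.
#' @return The mean +/- s.d. summary tibble, one row per method.
#' @export
glance.fecg_benchmark <- function(x, ...) attr(x, "summary")
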