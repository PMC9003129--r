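#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot an annotated signal
#'
#' Line plot of the waveform with ground-truth peaks marked.
#'
#' @param object An [annotated_signal()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.annotated_signal <- function(object, ...) {
  p <- ggplot2::ggplot(object, ggplot2::aes(x = .data$time, y = .data$amplitude)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::labs(x = "time (s)", y = "amplitude")
  pk <- signal_peaks(object)
  if (length(pk)) {
    p <- p + ggplot2::geom_point(
      data = object[pk, , drop = FALSE],
      colour = "orange", shape = 8, size = 2)
  }
  p
}

#' Plot the stages of an extraction
#'
#' Facets the abdominal input, maternal estimate, residual and denoised
#' fetal trace; detected fetal QRS marks are overlaid on the fetal panel.
#'
#' @param object An `fecg_extraction`.
#' @param reference Optional [peak_train()] of true fetal peaks to overlay.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.fecg_extraction <- function(object, reference = NULL, ...) {
  df <- tidy(object) |>
    dplyr::filter(.data$component != "preprocessed")
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$amplitude)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_wrap(~component, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "time (s)", y = "amplitude")
  if (nrow(object$fqrs)) {
    marks <- object$fecg_hat[object$fqrs$sample, , drop = FALSE] |>
      dplyr::mutate(component = factor("fecg_hat", levels = levels(df$component)))
    p <- p + ggplot2::geom_point(data = marks, colour = "red", shape = 4)
  }
  if (!is.null(reference) && nrow(reference)) {
    refm <- object$fecg_hat[reference$sample, , drop = FALSE] |>
      dplyr::mutate(component = factor("fecg_hat", levels = levels(df$component)))
    p <- p + ggplot2::geom_point(data = refm, colour = "orange", shape = 8)
  }
  p
}

#' Plot a simulated mixture
#'
#' Facets the mixture and its stored clean components.
#'
#' @param object A `mixture_record`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.mixture_record <- function(object, ...) {
  comps <- list(aecg = object$aecg, maternal = object$maternal_clean,
                fetal = object$fetal_clean)
  df <- purrr::imap(comps, function(s, nm) {
    tibble::tibble(time = s$time, component = nm, amplitude = s$amplitude)
  }) |>
    purrr::list_rbind() |>
    dplyr::mutate(component = factor(.data$component, levels = names(comps)))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$amplitude)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_wrap(~component, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "time (s)", y = "amplitude")
}
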