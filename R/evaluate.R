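#' Match detected peaks against reference annotations
#'
#' One-to-one greedy matching in increasing time order: each detected peak
#' is matched to the nearest unmatched reference peak within `+/- window`
#' seconds (ties broken toward the earlier reference peak). Matched
#' detections count as true positives, unmatched detections as false
#' positives, unmatched references as false negatives.
#'
#' @param detected,reference [peak_train()]s (or tibbles with a `time`
#'   column).
#' @param window Matching half-window in seconds (default 0.05, the common
#'   scoring convention; 0.15 is sometimes used).
#' @return A one-row tibble of class `detection_counts` with columns `tp`,
#'   `fp`, `fn`, `window`.
#' @export
match_peaks <- function(detected, reference, window = 0.05) {
  if (window < 0) stop("match_peaks: window must be non-negative")
  dt <- sort(detected$time)
  rt <- sort(reference$time)
  used <- logical(length(rt))
  tp <- 0L
  for (d in dt) {
    if (!length(rt)) break
    dist <- abs(rt - d)
    dist[used] <- Inf
    j <- which(dist == min(dist))[1]  # tie -> earlier reference
    if (is.finite(dist[j]) && dist[j] <= window) {
      used[j] <- TRUE
      tp <- tp + 1L
    }
  }
  out <- tibble::tibble(tp = tp, fp = length(dt) - tp,
                        fn = length(rt) - tp, window = window)
  class(out) <- c("detection_counts", class(out))
  out
}

#' Beat-detection accuracy metrics
#'
#' Sensitivity `SE = TP/(TP+FN)`, positive predictive value
#' `PPV = TP/(TP+FP)` and their harmonic mean
#' `F1 = 2 TP/(2 TP + FN + FP)`, all reported in percent.
#'
#' @param counts A `detection_counts` row (or anything with `tp`, `fp`,
#'   `fn`).
#' @return A one-row tibble with columns `se`, `ppv`, `f1`, `degenerate`.
#'   When a denominator is zero the affected metric is `NA` and
#'   `degenerate` is `TRUE` (no error is thrown).
#' @export
#' @examples
#' compute_metrics(tibble::tibble(tp = 95, fp = 2, fn = 3))
compute_metrics <- function(counts) {
  tp <- counts$tp; fp <- counts$fp; fn <- counts$fn
  se <- if (tp + fn > 0) 100 * tp / (tp + fn) else NA_real_
  ppv <- if (tp + fp > 0) 100 * tp / (tp + fp) else NA_real_
  f1 <- if (2 * tp + fn + fp > 0) 100 * 2 * tp / (2 * tp + fn + fp) else NA_real_
  tibble::tibble(se = se, ppv = ppv, f1 = f1,
                 degenerate = is.na(se) || is.na(ppv) || is.na(f1))
}

#' Score an extraction against reference fetal annotations
#'
#' Convenience wrapper: match the extraction's detected fetal QRS train
#' against a reference and compute SE/PPV/F1.
#'
#' @param extraction An `fecg_extraction`.
#' @param reference A [peak_train()] of true fetal R-peaks.
#' @param window Matching half-window in seconds.
#' @return A one-row metrics tibble (with the counts columns prepended).
#' @export
score_extraction <- function(extraction, reference, window = 0.05) {
  counts <- match_peaks(extraction$fqrs, reference, window)
  dplyr::bind_cols(counts[, c("tp", "fp", "fn")], compute_metrics(counts))
}

#' Run and score a batch of records
#'
#' Extracts the fetal ECG from every record and scores it against the
#' record's reference fetal annotations, returning per-record metrics plus
#' a mean/s.d. summary per method. Records without annotations are skipped
#' with a message.
#'
#' @param records A list of `mixture_record`s, or of lists with fields
#'   `aecg` ([annotated_signal()]) and `fetal_peaks` ([peak_train()]).
#' @param methods Character vector of filter methods to compare.
#' @param cfg An [extraction_config()].
#' @param n_ensemble Ensemble size for the EnKF.
#' @param window Matching half-window in seconds.
#' @param seed Integer seed; record `i`, method `m` runs with
#'   `seed + i` so the batch is reproducible.
#' @return A tibble of class `fecg_benchmark` with one row per record and
#'   method (`record`, `method`, `tp`, `fp`, `fn`, `se`, `ppv`, `f1`); the
#'   mean +/- s.d. summary table is available via [glance()] or the
#'   `summary` attribute.
#' @export
evaluate_batch <- function(records, methods = "enkf",
                           cfg = extraction_config(), n_ensemble = 70,
                           window = 0.05, seed = 1) {
  rows <- list()
  for (i in seq_along(records)) {
    rec <- records[[i]]
    if (is.null(rec$fetal_peaks) || nrow(rec$fetal_peaks) == 0L) {
      message("evaluate_batch: record ", i, " has no reference annotations; skipped")
      next
    }
    for (m in methods) {
      ex <- extract_fecg(rec$aecg, method = m, cfg = cfg,
                         n_ensemble = n_ensemble, seed = seed + i)
      sc <- score_extraction(ex, rec$fetal_peaks, window)
      rows[[length(rows) + 1L]] <-
        dplyr::bind_cols(tibble::tibble(record = i, method = m), sc)
    }
  }
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0L) {
    out <- tibble::tibble(record = integer(), method = character(),
                          tp = integer(), fp = integer(), fn = integer(),
                          se = numeric(), ppv = numeric(), f1 = numeric(),
                          degenerate = logical())
  }
  summary <- out |>
    dplyr::group_by(.data$method) |>
    dplyr::summarise(dplyr::across(c("se", "ppv", "f1"),
                                   list(mean = ~mean(.x, na.rm = TRUE),
                                        sd = ~stats::sd(.x, na.rm = TRUE))),
                     n_records = dplyr::n(), .groups = "drop")
  attr(out, "summary") <- summary
  class(out) <- c("fecg_benchmark", class(out))
  out
}
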