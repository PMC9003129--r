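#' Write and read signals as CSV
#'
#' Waveforms serialize to a CSV with columns `sample_index` (0-based) and
#' `amplitude`, preceded by a commented header carrying the sampling rate.
#' Peak annotations go to a one-column sidecar CSV (`<path>.peaks.csv` by
#' default).
#'
#' @param x An [annotated_signal()].
#' @param path Output CSV path.
#' @param peaks_path Sidecar path for peak indices (`NULL` to skip).
#' @return The path, invisibly.
#' @export
write_signal_csv <- function(x, path,
                             peaks_path = paste0(path, ".peaks.csv")) {
  con <- file(path, "w")
  writeLines(sprintf("# fs=%g", signal_fs(x)), con)
  # full-precision text so the round-trip is sample-exact
  utils::write.csv(data.frame(sample_index = seq_len(nrow(x)) - 1L,
                              amplitude = sprintf("%.17g", x$amplitude)),
                   con, row.names = FALSE, quote = FALSE)
  close(con)
  pk <- signal_peaks(x)
  if (!is.null(peaks_path) && length(pk)) {
    utils::write.csv(data.frame(sample_index = pk - 1L), peaks_path,
                     row.names = FALSE)
  }
  invisible(path)
}

#' @rdname write_signal_csv
#' @export
read_signal_csv <- function(path, peaks_path = paste0(path, ".peaks.csv")) {
  hdr <- readLines(path, n = 1)
  if (!grepl("^# fs=", hdr)) {
    stop("read_signal_csv: missing '# fs=' header in ", path)
  }
  fs <- as.numeric(sub("# fs=", "", hdr, fixed = TRUE))
  df <- utils::read.csv(path, comment.char = "#")
  if (!all(c("sample_index", "amplitude") %in% names(df))) {
    stop("read_signal_csv: expected columns sample_index, amplitude")
  }
  peaks <- integer()
  if (!is.null(peaks_path) && file.exists(peaks_path)) {
    peaks <- utils::read.csv(peaks_path)$sample_index + 1L
  }
  annotated_signal(df$amplitude, fs = fs, peaks = peaks)
}

#' Read a record in CSV or WFDB layout
#'
#' CSV records are those written by [write_signal_csv()]. WFDB records are
#' a `<record>.hea` header plus format-16 `.dat` signal file, optionally
#' with a fetal-QRS annotation file (`.fqrs`); multi-channel records
#' require picking exactly one channel.
#'
#' @param path Record path: the CSV file, or the WFDB record name (with or
#'   without `.hea`).
#' @param format `"csv"` or `"wfdb"`.
#' @param channel Channel to read from a multi-channel WFDB record.
#' @param annotator Annotation extension holding reference fetal QRS marks
#'   (default `"fqrs"`).
#' @return A list with `signal` ([annotated_signal()]) and `reference`
#'   (a [peak_train()] or `NULL`).
#' @export
read_record <- function(path, format = c("csv", "wfdb"), channel = 1,
                        annotator = "fqrs") {
  format <- match.arg(format)
  if (format == "csv") {
    sig <- read_signal_csv(path)
    pk <- signal_peaks(sig)
    ref <- if (length(pk)) peak_train(pk, signal_fs(sig)) else NULL
    return(list(signal = sig, reference = ref))
  }
  rec <- sub("\\.hea$", "", path)
  hea <- paste0(rec, ".hea")
  if (!file.exists(hea)) stop("read_record: header not found: ", hea)
  h <- read_wfdb_header(hea)
  if (channel < 1 || channel > h$n_sig) {
    stop("read_record: channel ", channel, " not in record (",
         h$n_sig, " signals)")
  }
  dat <- file.path(dirname(hea), h$file[channel])
  raw_n <- file.info(dat)$size / 2
  if (raw_n < h$n_samp * h$n_sig) {
    stop("read_record: truncated .dat file at byte ",
         file.info(dat)$size, " (expected ", 2 * h$n_samp * h$n_sig, ")")
  }
  v <- readBin(dat, "integer", n = h$n_samp * h$n_sig, size = 2,
               signed = TRUE, endian = "little")
  ch <- v[seq(channel, length(v), by = h$n_sig)]
  amp <- (ch - h$baseline[channel]) / h$gain[channel]
  sig <- annotated_signal(amp, fs = h$fs)
  ann_path <- paste0(rec, ".", annotator)
  ref <- NULL
  if (file.exists(ann_path)) {
    idx <- read_wfdb_annotation(ann_path)
    if (any(idx > h$n_samp)) {
      stop("read_record: annotation/record length mismatch")
    }
    ref <- peak_train(idx, h$fs)
  }
  list(signal = sig, reference = ref)
}

#' Write a record in WFDB layout
#'
#' Writes a format-16 `.dat`/`.hea` pair (single channel) and, if the
#' signal carries peak annotations, a QRS annotation file readable by
#' standard WFDB tooling.
#'
#' @param x An [annotated_signal()].
#' @param record Record name (path prefix).
#' @param annotator Annotation extension (default `"fqrs"`).
#' @return The record name, invisibly.
#' @export
write_record_wfdb <- function(x, record, annotator = "fqrs") {
  amp <- x$amplitude
  gain <- floor(32000 / max(abs(amp), 1e-12))
  adc <- as.integer(round(amp * gain))
  base <- basename(record)
  dat_name <- paste0(base, ".dat")
  writeBin(adc, paste0(record, ".dat"), size = 2, endian = "little")
  cks <- sum(adc) %% 65536
  if (cks > 32767) cks <- cks - 65536
  hdr <- c(sprintf("%s 1 %g %d", base, signal_fs(x), length(amp)),
           sprintf("%s 16 %d(0)/mV 16 0 %d %d 0 sig", dat_name, gain,
                   adc[1], cks))
  writeLines(hdr, paste0(record, ".hea"))
  pk <- signal_peaks(x)
  if (length(pk)) {
    write_wfdb_annotation(pk, paste0(record, ".", annotator))
  }
  invisible(record)
}

read_wfdb_header <- function(hea) {
  ln <- readLines(hea)
  ln <- ln[!grepl("^#", ln) & nzchar(trimws(ln))]
  top <- strsplit(trimws(ln[1]), "\\s+")[[1]]
  n_sig <- as.integer(top[2])
  fs <- if (length(top) >= 3) as.numeric(sub("/.*", "", top[3])) else 250
  n_samp <- if (length(top) >= 4) as.integer(top[4]) else NA_integer_
  if (is.na(fs)) stop("read_wfdb_header: sampling rate missing")
  sig <- lapply(ln[1 + seq_len(n_sig)], function(s) {
    f <- strsplit(trimws(s), "\\s+")[[1]]
    gain_field <- sub("\\(.*\\)", "", sub("/.*", "", f[3]))
    baseline <- if (grepl("\\(", f[3])) {
      as.numeric(sub(".*\\((-?[0-9]+)\\).*", "\\1", f[3]))
    } else 0
    list(file = f[1], fmt = f[2],
         gain = as.numeric(gain_field), baseline = baseline)
  })
  fmt <- vapply(sig, `[[`, "", "fmt")
  if (!all(fmt == "16")) stop("read_wfdb_header: only format 16 is supported")
  list(n_sig = n_sig, fs = fs, n_samp = n_samp,
       file = vapply(sig, `[[`, "", "file"),
       gain = vapply(sig, function(s) if (is.na(s$gain) || s$gain == 0) 200 else s$gain, 0),
       baseline = vapply(sig, `[[`, 0, "baseline"))
}

# MIT annotation format: 16-bit little-endian words, type in the top 6 bits,
# inter-annotation interval in the bottom 10; larger jumps use a SKIP word
# followed by the 4-byte interval (high word first). NORMAL beats only.
write_wfdb_annotation <- function(samples, path) {
  samples <- as.integer(sort(samples))
  words <- integer(0)
  prev <- 0L
  for (s in samples) {
    d <- s - prev
    if (d > 1023L) {
      words <- c(words, bitwShiftL(59L, 10L),          # SKIP
                 bitwAnd(bitwShiftR(d, 16L), 65535L),  # high word
                 bitwAnd(d, 65535L),                   # low word
                 bitwShiftL(1L, 10L))                  # NORMAL, interval 0
    } else {
      words <- c(words, bitwOr(bitwShiftL(1L, 10L), d))
    }
    prev <- s
  }
  words <- c(words, 0L)  # terminator
  con <- file(path, "wb")
  writeBin(as.integer(words), con, size = 2, endian = "little")
  close(con)
  invisible(path)
}

read_wfdb_annotation <- function(path) {
  n <- file.info(path)$size / 2
  w <- readBin(path, "integer", n = n, size = 2, signed = FALSE,
               endian = "little")
  out <- integer(0)
  t <- 0L
  i <- 1L
  skip <- 0L
  while (i <= length(w)) {
    word <- w[i]
    if (word == 0L) break
    typ <- bitwShiftR(word, 10L)
    dt <- bitwAnd(word, 1023L)
    if (typ == 59L) {
      hi <- w[i + 1L]; lo <- w[i + 2L]
      skip <- bitwShiftL(hi, 16L) + lo
      i <- i + 3L
      next
    }
    t <- t + dt + skip
    skip <- 0L
    if (typ >= 1L && typ <= 49L) out <- c(out, t)
    i <- i + 1L
  }
  out
}
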