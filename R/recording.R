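# The continuous multichannel recording container and its on-disk formats:
# a full-precision delimited-text format with a JSON sidecar (default
# interchange) and a minimal EDF (European Data Format) writer/reader whose
# round-trip precision is the 16-bit quantization step.

#' Construct a recording
#'
#' @param data numeric matrix, samples x channels (uV).
#' @param sampling_rate Hz.
#' @param channel_labels character vector, one per column.
#' @return object of class `lep_recording` with fields `data`,
#'   `sampling_rate`, `channel_labels`, `duration` (s).
#' @export
new_recording <- function(data, sampling_rate, channel_labels) {
  data <- as.matrix(data)
  if (!all(is.finite(data))) stop_painlep("recording contains non-finite values")
  if (length(channel_labels) != ncol(data))
    stop_painlep("channel_labels length (%d) != number of columns (%d)",
                 length(channel_labels), ncol(data))
  colnames(data) <- channel_labels
  structure(list(data = data, sampling_rate = sampling_rate,
                 channel_labels = channel_labels,
                 duration = nrow(data) / sampling_rate),
            class = "lep_recording")
}

#' @export
print.lep_recording <- function(x, ...) {
  cat(sprintf("lep_recording: %d samples x %d channels @ %g Hz (%.1f s)\n",
              nrow(x$data), ncol(x$data), x$sampling_rate, x$duration))
  invisible(x)
}

recording_channel <- function(recording, channel) {
  j <- match(channel, recording$channel_labels)
  if (is.na(j)) stop_painlep("channel '%s' not found (have: %s)", channel,
                             paste(recording$channel_labels, collapse = ", "))
  recording$data[, j]
}

#' Write / read a recording as delimited text with a JSON sidecar
#'
#' One column per channel with a header row of labels; the sampling rate and
#' labels are stored in `<path>.json`. Values round-trip at full double
#' precision.
#'
#' @param recording an `lep_recording`.
#' @param path file path for the data table (e.g. `rec.tsv`).
#' @return `write_recording_text` returns `path` invisibly;
#'   `read_recording_text` returns an `lep_recording`.
#' @export
write_recording_text <- function(recording, path) {
  data.table::fwrite(data.table::as.data.table(recording$data), path,
                     sep = "\t")
  jsonlite::write_json(list(sampling_rate = recording$sampling_rate,
                            channel_labels = recording$channel_labels),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_recording_text
#' @export
read_recording_text <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  dt <- data.table::fread(path, sep = "\t")
  new_recording(as.matrix(dt), meta$sampling_rate, meta$channel_labels)
}

#' Write / read a recording in EDF (European Data Format)
#'
#' Minimal EDF implementation: ASCII header, one-second data records, 16-bit
#' little-endian samples scaled between the per-channel physical extrema.
#' Round-trip precision is the quantization step
#' `(physical max - physical min) / (2^16 - 1)`.
#'
#' @param recording an `lep_recording` whose sampling rate is an integer.
#' @param path output file path.
#' @return `write_recording_edf` returns `path` invisibly;
#'   `read_recording_edf` returns an `lep_recording`.
#' @export
write_recording_edf <- function(recording, path) {
  fs <- recording$sampling_rate
  if (fs != round(fs)) stop_painlep("EDF writer requires an integer sampling rate")
  ns <- ncol(recording$data)
  nrec <- floor(nrow(recording$data) / fs)   # whole 1-s records
  data <- recording$data[seq_len(nrec * fs), , drop = FALSE]
  pmin_ <- apply(data, 2, min); pmax_ <- apply(data, 2, max)
  flat <- pmax_ - pmin_ < 1e-12
  pmax_[flat] <- pmin_[flat] + 1
  # physical extrema must fit the 8-char ASCII header fields; digitize with
  # the values as written so the declared quantization precision holds
  num8 <- function(x) vapply(x, function(v) {
    for (d in 7:1) {
      s <- formatC(v, digits = d, format = "g")
      if (nchar(s) <= 8) return(s)
    }
    stop_painlep("cannot format %g into 8 characters", v)
  }, "")
  pmin_s <- num8(pmin_ - abs(pmin_) * 1e-3 - 1e-9)  # nudge outward before rounding
  pmax_s <- num8(pmax_ + abs(pmax_) * 1e-3 + 1e-9)
  pmin_ <- as.numeric(pmin_s); pmax_ <- as.numeric(pmax_s)
  dmin <- -32768; dmax <- 32767
  pad <- function(x, w) formatC(substr(as.character(x), 1, w), width = w, flag = "-")
  header <- paste0(
    pad("0", 8), pad("painlep synthetic", 80), pad("synthetic recording", 80),
    pad("01.01.00", 8), pad("00.00.00", 8),
    pad(256 + 256 * ns, 8), pad("", 44), pad(nrec, 8), pad(1, 8), pad(ns, 4),
    paste0(vapply(recording$channel_labels, pad, "", w = 16), collapse = ""),
    paste0(rep(pad("AgAgCl electrode", 80), ns), collapse = ""),
    paste0(rep(pad("uV", 8), ns), collapse = ""),
    paste0(vapply(pmin_s, pad, "", w = 8), collapse = ""),
    paste0(vapply(pmax_s, pad, "", w = 8), collapse = ""),
    paste0(rep(pad(dmin, 8), ns), collapse = ""),
    paste0(rep(pad(dmax, 8), ns), collapse = ""),
    paste0(rep(pad("", 80), ns), collapse = ""),
    paste0(rep(pad(fs, 8), ns), collapse = ""),
    paste0(rep(pad("", 32), ns), collapse = "")
  )
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw(header), con)
  scale <- (dmax - dmin) / (pmax_ - pmin_)
  for (r in seq_len(nrec)) {
    idx <- ((r - 1) * fs + 1):(r * fs)
    for (j in seq_len(ns)) {
      dig <- as.integer(round((data[idx, j] - pmin_[j]) * scale[j]) + dmin)
      writeBin(dig, con, size = 2, endian = "little")
    }
  }
  invisible(path)
}

#' @rdname write_recording_edf
#' @export
read_recording_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  fixed <- rawToChar(readBin(con, "raw", 256))
  fld <- function(s, from, len) trimws(substr(s, from, from + len - 1))
  nrec <- as.integer(fld(fixed, 237, 8))
  ns <- as.integer(fld(fixed, 253, 4))
  var <- rawToChar(readBin(con, "raw", 256 * ns))
  grab <- function(offset, w) {
    vapply(seq_len(ns), function(j)
      trimws(substr(var, offset + (j - 1) * w + 1, offset + j * w)), "")
  }
  o <- 0
  labels <- grab(o, 16); o <- o + ns * (16 + 80 + 8)
  pmin_ <- as.numeric(grab(o, 8)); o <- o + ns * 8
  pmax_ <- as.numeric(grab(o, 8)); o <- o + ns * 8
  dmin <- as.numeric(grab(o, 8)); o <- o + ns * 8
  dmax <- as.numeric(grab(o, 8)); o <- o + ns * (8 + 80)
  nsamp <- as.integer(grab(o, 8))
  fs <- nsamp[1]
  data <- matrix(0, nrec * fs, ns)
  for (r in seq_len(nrec)) {
    for (j in seq_len(ns)) {
      dig <- readBin(con, "integer", fs, size = 2, endian = "little")
      data[((r - 1) * fs + 1):(r * fs), j] <-
        pmin_[j] + (dig - dmin[j]) * (pmax_[j] - pmin_[j]) / (dmax[j] - dmin[j])
    }
  }
  new_recording(data, fs, labels)
}

#' Write / read an event table as CSV
#'
#' Columns: `trial_index`, `onset_s`, `energy_J`, `rating`.
#'
#' @param events event table data.frame.
#' @param path CSV path.
#' @export
write_events <- function(events, path) {
  data.table::fwrite(events, path)
  invisible(path)
}

#' @rdname write_events
#' @export
read_events <- function(path) {
  as.data.frame(data.table::fread(path))
}
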