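# Recording I/O: a minimal European Data Format (EDF) writer/reader and a
# plain columnar text dialect. EDF stores 16-bit samples, so round trips are
# exact only up to the per-channel quantization step; the text dialect is
# lossless to its printed precision. Events are not embedded in either
# format: they travel in CSV sidecars (one row per trial).

.edfPad <- function(x, width) {
  x <- as.character(x)
  if (nchar(x) > width) x <- substr(x, 1, width)
  formatC(x, width = width, flag = "-")
}

#' Write a recording to EDF
#'
#' Minimal EDF writer: one-second data records, 16-bit samples scaled to the
#' per-channel physical range, physical dimension microvolts. The number of
#' samples must be a whole number of seconds (pad or trim first if needed);
#' events are written separately (see [writeEventsCSV()]).
#'
#' @param recording a [ContinuousRecording].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeEDF <- function(recording, path) {
  stopifnot(is(recording, "ContinuousRecording"))
  x <- recording@data
  fs <- recording@fs
  ns <- nrow(x)
  if (ns < 1L) stop("format error: recording has no channels")
  if (fs != round(fs)) stop("EDF writer requires an integer sampling rate")
  if (ncol(x) %% fs != 0)
    stop("EDF writer requires a whole number of seconds of data")
  nRec <- ncol(x) %/% fs

  # limits are serialized with two decimals; round them up first so the
  # writer's scale matches what a reader parses back
  physMax <- ceiling(pmax(apply(abs(x), 1, max), 0.01) * 100) / 100
  physMin <- -physMax
  digMax <- 32767L; digMin <- -32768L

  con <- file(path, "wb")
  on.exit(close(con))
  wr <- function(s, w) writeChar(.edfPad(s, w), con, nchars = w, eos = NULL)
  wr("0", 8)                                   # version
  wr("X X X X", 80)                            # patient id (anonymous)
  wr("Startdate X X X X", 80)                  # recording id
  wr("01.01.00", 8); wr("00.00.00", 8)         # date, time
  wr(as.character(256L * (1L + ns)), 8)        # header bytes
  wr("", 44)                                   # reserved
  wr(as.character(nRec), 8)                    # number of data records
  wr("1", 8)                                   # record duration (s)
  wr(as.character(ns), 4)                      # number of signals
  for (lab in recording@channelNames) wr(lab, 16)
  for (i in seq_len(ns)) wr("", 80)            # transducer
  for (i in seq_len(ns)) wr("uV", 8)           # physical dimension
  for (i in seq_len(ns)) wr(sprintf("%.2f", physMin[i]), 8)
  for (i in seq_len(ns)) wr(sprintf("%.2f", physMax[i]), 8)
  for (i in seq_len(ns)) wr(as.character(digMin), 8)
  for (i in seq_len(ns)) wr(as.character(digMax), 8)
  for (i in seq_len(ns)) wr("", 80)            # prefiltering
  for (i in seq_len(ns)) wr(as.character(fs), 8)
  for (i in seq_len(ns)) wr("", 32)            # reserved

  scale <- (digMax - digMin) / (physMax - physMin)
  for (r in seq_len(nRec)) {
    idx <- ((r - 1L) * fs + 1L):(r * fs)
    for (i in seq_len(ns)) {
      dig <- as.integer(round((x[i, idx] - physMin[i]) * scale[i]) + digMin)
      writeBin(dig, con, size = 2L, endian = "little")
    }
  }
  invisible(path)
}

#' Read an EDF recording
#'
#' Counterpart of [writeEDF()]. Amplitudes are returned in the file's
#' physical units (microvolts for files this package writes); the event
#' table is empty (events live in CSV sidecars).
#'
#' @param path EDF file path.
#' @return a [ContinuousRecording].
#' @export
readEDF <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(w) trimws(readChar(con, w, useBytes = TRUE))
  rd(8); rd(80); rd(80); rd(8); rd(8)
  rd(8)                                        # header bytes
  rd(44)
  nRec <- as.integer(rd(8))
  recDur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  if (is.na(ns) || ns < 1L) stop("format error: no signals in EDF header")
  labels <- vapply(seq_len(ns), function(i) rd(16), character(1))
  if (any(!nzchar(labels)))
    stop("format error: missing channel labels in EDF header (", ns,
         " signals, ", nRec, " records)")
  for (i in seq_len(ns)) rd(80)
  dims <- vapply(seq_len(ns), function(i) rd(8), character(1))
  physMin <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), numeric(1))
  physMax <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), numeric(1))
  digMin <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), numeric(1))
  digMax <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), numeric(1))
  for (i in seq_len(ns)) rd(80)
  sampPerRec <- vapply(seq_len(ns), function(i) as.integer(rd(8)), integer(1))
  for (i in seq_len(ns)) rd(32)

  if (length(unique(sampPerRec)) != 1L)
    stop("mixed per-signal sampling rates are not supported")
  fs <- sampPerRec[1] / recDur
  n <- nRec * sampPerRec[1]
  data <- matrix(0, nrow = ns, ncol = n, dimnames = list(labels, NULL))
  scale <- (physMax - physMin) / (digMax - digMin)
  for (r in seq_len(nRec)) {
    idx <- ((r - 1L) * sampPerRec[1] + 1L):(r * sampPerRec[1])
    for (i in seq_len(ns)) {
      dig <- readBin(con, "integer", n = sampPerRec[i], size = 2L,
                     endian = "little")
      data[i, idx] <- (dig - digMin[i]) * scale[i] + physMin[i]
    }
  }
  new("ContinuousRecording", data = data, fs = fs, channelNames = labels)
}

#' Write a recording as columnar text
#'
#' The fallback interchange dialect: comment header lines `# fs:`,
#' `# reference:` and `# channels:` (tab-separated labels) followed by one
#' tab-separated row per sample, amplitudes in microvolts.
#'
#' @param recording a [ContinuousRecording].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeRecordingText <- function(recording, path) {
  stopifnot(is(recording, "ContinuousRecording"))
  if (nrow(recording@data) < 1L) stop("format error: recording has no channels")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# thermoEEG columnar recording v1",
               paste0("# fs: ", .fmtNum(recording@fs)),
               paste0("# reference: ", recording@reference),
               paste0("# channels: ",
                      paste(recording@channelNames, collapse = "\t"))), con)
  utils::write.table(
    matrix(.fmtNum(t(recording@data)), ncol = nrow(recording@data)),
    con, sep = "\t", row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a columnar text recording
#'
#' @param path path written by [writeRecordingText()].
#' @return a [ContinuousRecording].
#' @export
readRecordingText <- function(path) {
  hdr <- readLines(path, n = 4L)
  if (!grepl("^# thermoEEG columnar recording", hdr[1]))
    stop("format error: not a thermoEEG columnar recording: ", path)
  fs <- as.numeric(sub("^# fs:\\s*", "", hdr[2]))
  ref <- sub("^# reference:\\s*", "", hdr[3])
  channels <- strsplit(sub("^# channels:\\s*", "", hdr[4]), "\t")[[1]]
  if (!length(channels) || any(!nzchar(channels)))
    stop("format error: missing channel labels in ", path)
  mat <- as.matrix(utils::read.table(path, sep = "\t", skip = 4L))
  if (ncol(mat) != length(channels))
    stop("format error: column count does not match channel header")
  data <- t(mat)
  dimnames(data) <- list(channels, NULL)
  new("ContinuousRecording", data = data, fs = fs, channelNames = channels,
      reference = ref)
}

#' Load a recording from disk
#'
#' Dispatches on the file extension: `.edf` via [readEDF()], `.txt`/`.tsv`
#' via [readRecordingText()]. An optional events CSV (columns
#' `onset_sample`, `condition`, `session`) is attached to the recording.
#'
#' @param path recording file path.
#' @param eventsPath optional events CSV path.
#' @return a [ContinuousRecording].
#' @export
loadRecording <- function(path, eventsPath = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  rec <- switch(ext,
    edf = readEDF(path),
    txt = ,
    tsv = readRecordingText(path),
    stop("format error: unknown recording extension '.", ext,
         "' (expected .edf, .txt or .tsv)"))
  if (!is.null(eventsPath)) {
    ev <- utils::read.csv(eventsPath, stringsAsFactors = FALSE)
    if (!"session" %in% names(ev)) ev$session <- "1"
    rec@events <- ev[, c("onset_sample", "condition", "session")]
    validObject(rec)
  }
  rec
}

#' Write trial events/ratings to CSV
#'
#' One row per trial: stimulation onset in seconds and samples, condition,
#' session, and (if present) the behavioral rating rounded to the integer
#' scale.
#'
#' @param trials data.frame as returned in `generateEEGSession()$trials`,
#'   or an event table with `onset_sample` and `condition`.
#' @param path output CSV path.
#' @param fs sampling rate used to fill whichever of `onset_s` /
#'   `onset_sample` is absent.
#' @return `path`, invisibly.
#' @export
writeEventsCSV <- function(trials, path, fs = 512) {
  out <- trials
  if (!"onset_sample" %in% names(out) && "onset_s" %in% names(out))
    out$onset_sample <- round(out$onset_s * fs) + 1L
  if (!"onset_s" %in% names(out) && "onset_sample" %in% names(out))
    out$onset_s <- (out$onset_sample - 1L) / fs
  if ("rating" %in% names(out)) out$rating <- round(out$rating)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}
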