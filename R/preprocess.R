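# Preprocessing: band-pass + notch filtering, epoch extraction, baseline
# correction, and threshold/EMG artifact rejection.

#' Normalized Butterworth cutoff frequencies
#'
#' Expresses band-pass corner frequencies as fractions of the Nyquist
#' frequency (fs/2). The reporting convention truncates the low fraction to
#' 4 decimal places and the high fraction to 3 (0.5 and 70 Hz at 512 Hz
#' report as 0.0019 and 0.273).
#'
#' @param lowHz,highHz corner frequencies in Hz, `0 < lowHz < highHz < fs/2`.
#' @param fs sampling rate in Hz.
#' @return list with `low`, `high` (exact fractions) and `lowReported`,
#'   `highReported` (truncated).
#' @examples
#' normalizedCutoffs(0.5, 70, 512)
#' @export
normalizedCutoffs <- function(lowHz, highHz, fs) {
  if (!(lowHz > 0 && lowHz < highHz)) stop("need 0 < lowHz < highHz")
  if (highHz >= fs / 2) stop("highHz must be below the Nyquist frequency")
  nyq <- fs / 2
  lo <- lowHz / nyq
  hi <- highHz / nyq
  trunc10 <- function(x, k) floor(x * 10^k) / 10^k
  list(low = lo, high = hi,
       lowReported = trunc10(lo, 4), highReported = trunc10(hi, 3))
}

# Second-order IIR notch (RBJ biquad), quality factor q.
.notchCoefficients <- function(notchHz, fs, q = 30) {
  w0 <- 2 * pi * notchHz / fs
  alpha <- sin(w0) / (2 * q)
  b <- c(1, -2 * cos(w0), 1)
  a <- c(1 + alpha, -2 * cos(w0), 1 - alpha)
  list(b = b / a[1], a = a / a[1])
}

# Apply one IIR filter to a channels x samples matrix, zero-phase
# (forward-backward) or causal (single forward pass).
.filterMatrix <- function(x, b, a, zeroPhase = TRUE) {
  if (zeroPhase) {
    t(.filtfiltMat(as.numeric(b), as.numeric(a), t(x)))
  } else {
    out <- x
    for (i in seq_len(nrow(x)))
      out[i, ] <- as.numeric(signal::filter(b, a, x[i, ]))
    out
  }
}

#' Band-pass and notch filter a recording
#'
#' Fourth-order Butterworth band-pass (default 0.5-70 Hz) followed by a
#' second-order IIR notch (default 50 Hz, Q = 30). Both are applied
#' forward-backward by default (zero phase), so evoked-peak latencies are
#' not biased; `zeroPhase = FALSE` gives the causal single-pass variant.
#'
#' @param recording a [ContinuousRecording].
#' @param lowHz,highHz band-pass corners in Hz.
#' @param order Butterworth order (default 4).
#' @param notchHz notch frequency in Hz; `NA` disables the notch.
#' @param notchQ notch quality factor (default 30).
#' @param zeroPhase apply filters forward-backward (default TRUE).
#' @return the filtered [ContinuousRecording] (same shape and events).
#' @export
applyFilters <- function(recording, lowHz = 0.5, highHz = 70, order = 4,
                         notchHz = 50, notchQ = 30, zeroPhase = TRUE) {
  stopifnot(is(recording, "ContinuousRecording"))
  bad <- which(!apply(is.finite(recording@data), 1, all))
  if (length(bad))
    stop("non-finite samples in channel(s) ",
         paste(recording@channelNames[bad], collapse = ", "))
  fs <- recording@fs
  nc <- normalizedCutoffs(lowHz, highHz, fs)  # validates the band
  bp <- signal::butter(order, c(nc$low, nc$high), type = "pass")
  out <- .filterMatrix(recording@data, bp$b, bp$a, zeroPhase)
  if (!is.na(notchHz)) {
    nf <- .notchCoefficients(notchHz, fs, notchQ)
    out <- .filterMatrix(out, nf$b, nf$a, zeroPhase)
  }
  dimnames(out) <- dimnames(recording@data)
  initialize(recording, data = out)
}

#' Extract fixed-length epochs around stimulation events
#'
#' Cuts one epoch per event using a half-open window `[startS, endS)` in
#' seconds relative to the event onset; `c(0, 3)` gives the 3000 ms
#' stimulation epochs and `c(-3, 0)` the 3 s pre-stimulus epochs.
#'
#' @param recording a [ContinuousRecording] with events.
#' @param window numeric `(startS, endS)` relative to onset.
#' @param events optional event table overriding the recording's.
#' @return an [EpochSet]; labels come from the event conditions and
#'   `parentIds` index the event table rows.
#' @export
extractEpochs <- function(recording, window = c(0, 3), events = NULL) {
  stopifnot(is(recording, "ContinuousRecording"))
  if (is.null(events)) events <- recording@events
  if (!nrow(events)) stop("no events to epoch")
  fs <- recording@fs
  nSamp <- round(diff(window) * fs)
  if (nSamp < 1) stop("empty epoch window")
  startOff <- round(window[1] * fs)
  n <- ncol(recording@data)
  arr <- array(0, dim = c(nrow(events), nrow(recording@data), nSamp),
               dimnames = list(NULL, recording@channelNames, NULL))
  for (i in seq_len(nrow(events))) {
    from <- events$onset_sample[i] + startOff
    to <- from + nSamp - 1L
    if (from < 1L || to > n)
      stop("epoch window out of bounds for event ", i, " (condition ",
           events$condition[i], ")")
    arr[i, , ] <- recording@data[, from:to]
  }
  new("EpochSet", data = arr, fs = fs,
      labels = as.character(events$condition),
      parentIds = seq_len(nrow(events)),
      window = as.numeric(window),
      channelNames = recording@channelNames)
}

#' Baseline-correct epochs to the pre-stimulus mean
#'
#' Subtracts, per trial and channel, the mean of the matching pre-stimulus
#' baseline epoch (or of a window within the epochs themselves).
#'
#' @param epochs an [EpochSet].
#' @param baseline either an [EpochSet] of pre-stimulus epochs in trial
#'   correspondence with `epochs`, or a numeric window `(startS, endS)`
#'   relative to onset lying inside the epochs' own window.
#' @return the corrected [EpochSet].
#' @export
baselineCorrect <- function(epochs, baseline) {
  stopifnot(is(epochs, "EpochSet"))
  d <- dim(epochs@data)
  if (is(baseline, "EpochSet")) {
    if (dim(baseline@data)[1] != d[1])
      stop("trial-count mismatch between epochs and baseline")
    if (dim(baseline@data)[2] != d[2])
      stop("channel mismatch between epochs and baseline")
    mu <- apply(baseline@data, c(1, 2), mean)
  } else {
    win <- as.numeric(baseline)
    if (win[1] < epochs@window[1] || win[2] > epochs@window[2])
      stop("baseline window must lie inside the epoch window")
    i0 <- round((win[1] - epochs@window[1]) * epochs@fs) + 1L
    i1 <- i0 + round(diff(win) * epochs@fs) - 1L
    mu <- apply(epochs@data[, , i0:i1, drop = FALSE], c(1, 2), mean)
  }
  out <- epochs@data - array(rep(mu, d[3]), dim = d)
  initialize(epochs, data = out)
}

#' Threshold and EMG-band artifact rejection
#'
#' Applies the two rejection criteria: epochs containing any sample with
#' absolute amplitude beyond `ampThresholdUv` (on the filtered epochs) are
#' rejected, and epochs whose raw (pre-band-pass) signal carries a 50-200 Hz
#' component with peak amplitude inside `emgAmpMv` (in millivolts) are
#' flagged as EMG and rejected. Raw epochs must be supplied for the EMG
#' criterion because the 50-200 Hz band exceeds the analysis band-pass.
#'
#' @param epochs filtered [EpochSet] to screen.
#' @param rawEpochs unfiltered [EpochSet] in trial correspondence with
#'   `epochs`, or NULL to skip the EMG criterion.
#' @param ampThresholdUv amplitude threshold in microvolts (default 100).
#' @param emgBandHz EMG frequency band in Hz (default `c(50, 200)`).
#' @param emgAmpMv EMG amplitude band in millivolts (default `c(1, 10)`).
#' @return list with `epochs` (kept epochs) and `log`, a data.frame with
#'   one row per input epoch: `epoch`, `condition`, `decision` (one of
#'   `"kept"`, `"rejected-amplitude"`, `"flagged-emg"`); thresholds are
#'   recorded as attributes of the log.
#' @export
rejectArtifacts <- function(epochs, rawEpochs = NULL, ampThresholdUv = 100,
                            emgBandHz = c(50, 200), emgAmpMv = c(1, 10)) {
  stopifnot(is(epochs, "EpochSet"))
  if (ampThresholdUv <= 0) stop("ampThresholdUv must be positive")
  d <- dim(epochs@data)
  nTr <- d[1]
  decision <- rep("kept", nTr)

  if (!is.null(rawEpochs)) {
    stopifnot(is(rawEpochs, "EpochSet"))
    if (dim(rawEpochs@data)[1] != nTr)
      stop("trial-count mismatch between epochs and rawEpochs")
    fs <- rawEpochs@fs
    hi <- min(emgBandHz[2], 0.99 * fs / 2)
    bp <- signal::butter(4, c(emgBandHz[1], hi) / (fs / 2), type = "pass")
    for (i in seq_len(nTr)) {
      band <- .filtfiltMat(bp$b, bp$a, t(rawEpochs@data[i, , ]))
      peakMv <- max(abs(band)) / 1000
      if (peakMv >= emgAmpMv[1] && peakMv <= emgAmpMv[2])
        decision[i] <- "flagged-emg"
    }
  }
  for (i in seq_len(nTr))
    if (decision[i] == "kept" && max(abs(epochs@data[i, , ])) > ampThresholdUv)
      decision[i] <- "rejected-amplitude"

  keep <- decision == "kept"
  log <- data.frame(epoch = seq_len(nTr), condition = epochs@labels,
                    parent = epochs@parentIds, decision = decision,
                    stringsAsFactors = FALSE)
  attr(log, "ampThresholdUv") <- ampThresholdUv
  attr(log, "emgBandHz") <- emgBandHz
  attr(log, "emgAmpMv") <- emgAmpMv
  kept <- initialize(epochs,
                     data = epochs@data[keep, , , drop = FALSE],
                     labels = epochs@labels[keep],
                     parentIds = epochs@parentIds[keep])
  list(epochs = kept, log = log)
}
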