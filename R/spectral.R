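# Spectral and spatio-temporal characterization: Welch band power, ERD
# index, trial-averaged evoked responses, global field power, peak
# detection, and the alpha-power-vs-discomfort correlation.

#' Welch power spectral density
#'
#' One-sided PSD by Welch's method: Hann-windowed segments (default 1 s)
#' with 50% overlap, periodograms normalized so that the PSD integrates to
#' the mean square of the signal.
#'
#' @param x numeric signal.
#' @param fs sampling rate in Hz.
#' @param segS segment length in seconds (default 1).
#' @param overlap fractional segment overlap (default 0.5).
#' @return list with `freq` (Hz) and `psd` (power per Hz).
#' @export
welchPsd <- function(x, fs, segS = 1, overlap = 0.5) {
  nseg <- min(round(segS * fs), length(x))
  if (nseg < 2) stop("signal too short for Welch segments")
  step <- max(1L, round(nseg * (1 - overlap)))
  w <- 0.5 * (1 - cos(2 * pi * seq(0, nseg - 1) / (nseg - 1)))
  starts <- seq(1L, length(x) - nseg + 1L, by = step)
  nf <- nseg %/% 2L + 1L
  acc <- numeric(nf)
  for (s in starts) {
    seg <- x[s:(s + nseg - 1L)] * w
    p <- Mod(stats::fft(seg))^2 / (fs * sum(w^2))
    acc <- acc + p[seq_len(nf)]
  }
  psd <- acc / length(starts)
  psd[-1] <- 2 * psd[-1]
  if (nseg %% 2L == 0L) psd[nf] <- psd[nf] / 2  # Nyquist bin is not doubled
  list(freq = (seq_len(nf) - 1L) * fs / nseg, psd = psd)
}

#' Band power per channel
#'
#' Per channel, the mean over trials of the band-integrated Welch PSD
#' (power spectral density summed over band bins times the bin width), in
#' squared microvolts.
#'
#' @param epochs an [EpochSet] (subset to one condition beforehand if a
#'   per-condition map is wanted).
#' @param band numeric `(lowHz, highHz)` inside `(0, fs/2)`; default the
#'   alpha band `c(8, 12)`.
#' @param segS,overlap Welch parameters (defaults 1 s, 50%).
#' @return data.frame with columns `channel`, `power`; attributes `band`
#'   and `nTrials`.
#' @export
bandPower <- function(epochs, band = c(8, 12), segS = 1, overlap = 0.5) {
  stopifnot(is(epochs, "EpochSet"))
  fs <- epochs@fs
  if (band[1] <= 0 || band[2] >= fs / 2 || band[1] >= band[2])
    stop("band must lie inside (0, fs/2)")
  d <- dim(epochs@data)
  if (d[1] < 1) stop("at least one epoch required")
  pow <- matrix(0, d[1], d[2])
  for (tr in seq_len(d[1])) for (ch in seq_len(d[2])) {
    ps <- welchPsd(epochs@data[tr, ch, ], fs, segS, overlap)
    sel <- ps$freq >= band[1] & ps$freq <= band[2]
    df <- ps$freq[2] - ps$freq[1]
    pow[tr, ch] <- sum(ps$psd[sel]) * df
  }
  out <- data.frame(channel = epochs@channelNames, power = colMeans(pow),
                    stringsAsFactors = FALSE)
  attr(out, "band") <- band
  attr(out, "nTrials") <- d[1]
  out
}

#' Event-related desynchronization index
#'
#' Per channel, `(base - stim) / base` on band power; positive values
#' indicate desynchronization (power suppression during stimulation).
#' Channels with zero baseline power are undefined and reported as `NA`.
#'
#' @param stimPower,basePower band-power data.frames from [bandPower()]
#'   over the same channels and band.
#' @return data.frame with columns `channel`, `erd`.
#' @export
erdIndex <- function(stimPower, basePower) {
  if (!identical(stimPower$channel, basePower$channel))
    stop("stim and baseline power maps must share channels")
  b1 <- attr(stimPower, "band"); b2 <- attr(basePower, "band")
  if (!is.null(b1) && !is.null(b2) && !isTRUE(all.equal(b1, b2)))
    stop("stim and baseline power maps must share the band")
  erd <- ifelse(basePower$power > 0,
                (basePower$power - stimPower$power) / basePower$power,
                NA_real_)
  data.frame(channel = stimPower$channel, erd = erd, stringsAsFactors = FALSE)
}

#' Trial-averaged evoked response
#'
#' @param epochs an [EpochSet].
#' @return channels x samples matrix of the mean over trials, with
#'   attributes `fs` and `window`.
#' @export
averageEvoked <- function(epochs) {
  stopifnot(is(epochs, "EpochSet"))
  ev <- apply(epochs@data, c(2, 3), mean)
  rownames(ev) <- epochs@channelNames
  attr(ev, "fs") <- epochs@fs
  attr(ev, "window") <- epochs@window
  ev
}

#' Global field power
#'
#' At each timepoint, the population standard deviation of the instantaneous
#' potentials across all electrodes: `sqrt(mean((u_i - mean(u))^2))` over
#' the N channels. A reference-free measure of overall scalp field
#' strength; a spatially uniform map has GFP 0 and adding a constant to all
#' channels leaves it unchanged.
#'
#' @param evoked channels x samples matrix (e.g. from [averageEvoked()]).
#' @param fs sampling rate in Hz (taken from the `fs` attribute if absent).
#' @param startS time of the first column in seconds (taken from the
#'   `window` attribute if absent, else 0).
#' @return data.frame with columns `time_s`, `gfp`.
#' @export
computeGFP <- function(evoked, fs = NULL, startS = NULL) {
  if (is.null(fs)) fs <- attr(evoked, "fs")
  if (is.null(startS))
    startS <- if (!is.null(attr(evoked, "window"))) attr(evoked, "window")[1] else 0
  if (is.null(fs)) fs <- 1
  if (nrow(evoked) < 2) stop("GFP requires at least two channels")
  gfp <- apply(evoked, 2, .popSd)
  data.frame(time_s = startS + (seq_len(ncol(evoked)) - 1L) / fs, gfp = gfp)
}

#' Detect the peak evoked response
#'
#' Finds the (channel, timepoint) maximizing the absolute amplitude of the
#' evoked response inside a search window. Ties are broken by earliest
#' latency, then channel order.
#'
#' @param evoked channels x samples matrix with `fs`/`window` attributes
#'   (e.g. from [averageEvoked()]).
#' @param window optional `(startS, endS)` search window in seconds; default
#'   the full evoked duration.
#' @param fs,startS overrides as in [computeGFP()].
#' @return data.frame with one row: `channel`, `latency_s`, `amplitude`
#'   (signed value at the peak).
#' @export
detectPeak <- function(evoked, window = NULL, fs = NULL, startS = NULL) {
  if (is.null(fs)) fs <- attr(evoked, "fs")
  if (is.null(startS))
    startS <- if (!is.null(attr(evoked, "window"))) attr(evoked, "window")[1] else 0
  if (is.null(fs)) stop("sampling rate required")
  times <- startS + (seq_len(ncol(evoked)) - 1L) / fs
  if (is.null(window)) window <- range(times)
  cols <- which(times >= window[1] & times <= window[2])
  if (!length(cols)) stop("empty peak search window")
  sub <- abs(evoked[, cols, drop = FALSE])
  amax <- max(sub)
  hits <- which(sub == amax, arr.ind = TRUE)
  hits <- hits[order(hits[, 2], hits[, 1]), , drop = FALSE]  # earliest, then channel
  ch <- hits[1, 1]; tp <- cols[hits[1, 2]]
  data.frame(channel = rownames(evoked)[ch], latency_s = times[tp],
             amplitude = evoked[ch, tp], stringsAsFactors = FALSE)
}

#' Per-trial band power averaged over chosen channels
#'
#' Per trial, the mean over the chosen channels of the band-integrated
#' Welch PSD; the per-trial quantity behind the alpha-vs-discomfort
#' correlation and the condition-wise statistics.
#'
#' @param epochs an [EpochSet].
#' @param band numeric `(lowHz, highHz)`.
#' @param channels channel subset (default all).
#' @param segS,overlap Welch parameters.
#' @return numeric vector, one value per trial.
#' @export
trialBandPower <- function(epochs, band = c(8, 12),
                           channels = channelLabels(epochs),
                           segS = 1, overlap = 0.5) {
  stopifnot(is(epochs, "EpochSet"))
  fs <- epochs@fs
  chIdx <- match(channels, epochs@channelNames)
  if (anyNA(chIdx)) stop("unknown channel(s): ",
                         paste(channels[is.na(chIdx)], collapse = ", "))
  d <- dim(epochs@data)
  out <- numeric(d[1])
  for (tr in seq_len(d[1])) {
    acc <- 0
    for (ch in chIdx) {
      ps <- welchPsd(epochs@data[tr, ch, ], fs, segS, overlap)
      sel <- ps$freq >= band[1] & ps$freq <= band[2]
      acc <- acc + sum(ps$psd[sel]) * (ps$freq[2] - ps$freq[1])
    }
    out[tr] <- acc / length(chIdx)
  }
  out
}

#' Correlation between alpha power and discomfort
#'
#' Pearson's correlation between per-trial alpha-band power (at the chosen
#' channels) and the corresponding discomfort ratings. A negative r means
#' alpha power decreases as discomfort increases.
#'
#' @param alphaPower per-trial alpha power values.
#' @param ratings paired discomfort ratings.
#' @return list with `r`, `p` (two-sided), and `n`; `r` is `NA` when either
#'   variable has zero variance.
#' @export
alphaDiscomfortCorrelation <- function(alphaPower, ratings) {
  if (length(alphaPower) != length(ratings))
    stop("alphaPower and ratings must be paired")
  ok <- is.finite(alphaPower) & is.finite(ratings)
  x <- alphaPower[ok]; y <- ratings[ok]
  if (length(x) < 3) stop("need at least 3 paired finite observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    return(list(r = NA_real_, p = NA_real_, n = length(x)))
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(x))
}
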