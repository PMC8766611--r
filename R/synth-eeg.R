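# Synthetic EEG session generator.
#
# Signal model, per channel c and time t (all amplitudes in microvolts):
#   x_c(t) = pink_c(t) + alpha_c(t) + evoked_c(t) + artifacts_c(t)
# pink_c:  1/f^beta background noise, RMS-normalized per channel;
# alpha_c: ongoing 10 Hz rhythm on posterior/central channels whose
#          amplitude is scaled by sqrt(1 - w_c * f_cond) during the
#          stimulation window, so the condition's fraction f_cond of
#          alpha-band POWER is removed at weighted channels (this is the
#          quantity the ERD index (base - stim)/base measures);
# evoked_c: Gaussian-windowed biphasic (Gabor) transient at the stimulus
#          onset + condition latency, on the configured peak channel, whose
#          absolute maximum falls exactly on the grid sample nearest the
#          configured latency;
# artifacts: injected high-amplitude excursions (> 100 uV) and 50-200 Hz
#          EMG bursts (1-10 mV), bookkept in a ground-truth table.

# Unit-RMS 1/f^beta noise of length n via spectral shaping.
.pinkNoise <- function(n, beta = 1) {
  nf <- n %/% 2L
  k <- seq_len(nf)
  amp <- k^(-beta / 2)
  ph <- stats::runif(nf, 0, 2 * pi)
  half <- amp * exp(1i * ph)
  if (n %% 2L == 0L) {
    half[nf] <- Re(half[nf])  # Nyquist bin must be real
    spec <- c(0, half, Conj(rev(half[-nf])))
  } else {
    spec <- c(0, half, Conj(rev(half)))
  }
  x <- Re(stats::fft(spec, inverse = TRUE)) / n
  x / sqrt(mean(x^2))
}

# Gabor (Gaussian-windowed cosine) transient; absolute max at t = 0.
.gaborPulse <- function(t, amplitude, sigma = 0.05, f0 = 5) {
  amplitude * exp(-t^2 / (2 * sigma^2)) * cos(2 * pi * f0 * t)
}

#' Generate a synthetic EEG session
#'
#' Renders a scheduled [StimulusParadigm] into a [ContinuousRecording] plus
#' ground-truth tables, with the statistical structure the downstream
#' analyses assume: condition-scaled suppression of ongoing alpha power at
#' contralateral-central channels during stimulation, condition-specific
#' evoked transients at the vertex, 1/f background noise, injected
#' high-amplitude and EMG artifacts, and per-trial behavioral ratings.
#' Identical `(paradigm, effects, seed)` reproduce identical samples.
#'
#' @param paradigm a [StimulusParadigm] with a concrete schedule.
#' @param effects an [EffectSpec]; see [defaultEffectSpec()].
#' @param seed integer seed.
#' @param channelNames montage labels (defaults to the first
#'   `nChannels` of [montage64()]).
#' @return list with elements `recording` (a [ContinuousRecording] whose
#'   events are the stimulation onsets), `trials` (the schedule with a
#'   `rating` column), `artifacts` (ground-truth table: `trial`, `type`,
#'   `channel`, `time_s`, `amplitude_uv`, `freq_hz`), `effects`, and
#'   `paradigm`.
#' @examples
#' p <- generateParadigm("warm", 2, seed = 1, fs = 128, nChannels = 8)
#' s <- generateEEGSession(p, seed = 1, channelNames = montage64()[25:32])
#' s$recording
#' @export
generateEEGSession <- function(paradigm, effects = defaultEffectSpec(), seed,
                               channelNames = montage64()[seq_len(paradigm@nChannels)]) {
  stopifnot(is(paradigm, "StimulusParadigm"), is(effects, "EffectSpec"))
  sched <- paradigm@schedule
  if (!nrow(sched)) stop("paradigm has no concrete schedule")
  fs <- paradigm@fs
  nCh <- length(channelNames)
  missingCh <- setdiff(
    c(effects@erdChannels,
      unique(effects@peakChannel[names(effects@peakChannel) %in% sched$condition])),
    channelNames)
  if (length(missingCh))
    stop("effect channel(s) not in montage: ", paste(missingCh, collapse = ", "))

  trialDur <- paradigm@baselineS + paradigm@stimulationS
  trialSamp <- round(trialDur * fs)
  nTrials <- nrow(sched)
  n <- nTrials * trialSamp

  .withSeed(seed, {
    data <- matrix(0, nrow = nCh, ncol = n,
                   dimnames = list(channelNames, NULL))

    # 1/f background
    if (effects@pinkAmplitudeUv > 0)
      for (c in seq_len(nCh))
        data[c, ] <- effects@pinkAmplitudeUv *
          .pinkNoise(n, effects@oneOverFExponent)

    # Ongoing 10 Hz alpha rhythm with stimulation-locked desynchronization.
    # The rhythm is spatially coherent, as posterior/central alpha is on the
    # scalp: one common oscillator phase per trial plus a fixed per-channel
    # phase offset drawn once per session. Per-channel alpha variance in any
    # whole-cycle window is then exactly A^2/2 (scaled by 1 - w*f during
    # stimulation), and the cross-channel covariance structure is identical
    # across trials, so spatial filters fitted on some trials transfer to
    # held-out ones.
    if (effects@alphaAmplitudeUv > 0) {
      alphaIdx <- which(channelNames %in%
                          union(effects@alphaChannels, effects@erdChannels))
      erdW <- structure(effects@erdWeights, names = effects@erdChannels)
      tTrial <- (seq_len(trialSamp) - 1) / fs
      stimMask <- tTrial >= paradigm@baselineS  # within-trial stimulation part
      phiChan <- stats::runif(length(alphaIdx), 0, 2 * pi)
      phiTrial <- stats::runif(nTrials, 0, 2 * pi)
      for (k in seq_along(alphaIdx)) {
        c <- alphaIdx[k]
        w <- if (channelNames[c] %in% names(erdW)) erdW[[channelNames[c]]] else 0
        for (tr in seq_len(nTrials)) {
          f <- effects@alphaErdFraction[[sched$condition[tr]]]
          if (is.null(f)) f <- 0
          off <- (tr - 1L) * trialSamp
          scale <- ifelse(stimMask, sqrt(max(0, 1 - w * f)), 1)
          data[c, off + seq_len(trialSamp)] <-
            data[c, off + seq_len(trialSamp)] +
            effects@alphaAmplitudeUv * scale *
              sin(2 * pi * 10 * tTrial + phiTrial[tr] + phiChan[k])
        }
      }
    }

    # evoked transients, centered on the grid sample nearest the latency
    onsetSamp <- round(sched$onset_s * fs) + 1L
    for (tr in seq_len(nTrials)) {
      cond <- sched$condition[tr]
      amp <- effects@peakAmplitudeUv[[cond]]
      if (is.null(amp) || amp == 0) next
      lat <- effects@peakLatencyS[[cond]]
      chName <- effects@peakChannel[[cond]]
      ch <- match(chName, channelNames)
      center <- onsetSamp[tr] + round(lat * fs)
      halfWin <- round(0.3 * fs)
      idx <- max(1L, center - halfWin):min(n, center + halfWin)
      data[ch, idx] <- data[ch, idx] +
        .gaborPulse((idx - center) / fs, amp)
    }

    # injected artifacts (within the stimulation window of each trial)
    artRows <- list()
    for (tr in seq_len(nTrials)) {
      stimStart <- sched$onset_s[tr]
      stimEnd <- sched$trial_start_s[tr] + trialDur
      nAmp <- stats::rpois(1, effects@artifactRateAmp)
      nEmg <- stats::rpois(1, effects@artifactRateEmg)
      if (nAmp > 0) for (k in seq_len(nAmp)) {
        at <- stats::runif(1, stimStart + 0.3, stimEnd - 0.3)
        ch <- sample.int(nCh, 1)
        amp <- sample(c(-1, 1), 1) * stats::runif(1, 180, 300)
        center <- round(at * fs) + 1L
        halfWin <- round(0.1 * fs)
        idx <- max(1L, center - halfWin):min(n, center + halfWin)
        data[ch, idx] <- data[ch, idx] +
          amp * exp(-((idx - center) / fs)^2 / (2 * 0.02^2))
        artRows[[length(artRows) + 1L]] <- data.frame(
          trial = tr, type = "amplitude", channel = channelNames[ch],
          time_s = (center - 1L) / fs, amplitude_uv = amp, freq_hz = NA_real_)
      }
      if (nEmg > 0) for (k in seq_len(nEmg)) {
        at <- stats::runif(1, stimStart + 0.3, stimEnd - 0.3)
        ch <- sample.int(nCh, 1)
        ampMv <- stats::runif(1, 1.5, 5)           # within the 1-10 mV band
        f0 <- stats::runif(1, 100, 180)            # within 50-200 Hz, above
        center <- round(at * fs) + 1L              # the 0.5-70 Hz band-pass
        halfWin <- round(0.15 * fs)
        idx <- max(1L, center - halfWin):min(n, center + halfWin)
        tt <- (idx - center) / fs
        env <- 0.5 * (1 + cos(pi * tt / 0.15))
        data[ch, idx] <- data[ch, idx] +
          1000 * ampMv * env * sin(2 * pi * f0 * tt)
        artRows[[length(artRows) + 1L]] <- data.frame(
          trial = tr, type = "emg", channel = channelNames[ch],
          time_s = (center - 1L) / fs, amplitude_uv = 1000 * ampMv,
          freq_hz = f0)
      }
    }
    artifacts <- if (length(artRows)) do.call(rbind, artRows) else
      data.frame(trial = integer(), type = character(), channel = character(),
                 time_s = numeric(), amplitude_uv = numeric(),
                 freq_hz = numeric())

    # behavioral ratings (truncated normal per condition)
    tab <- thermalConditions()
    ci <- match(sched$condition, tab$name)
    rating <- pmin(pmax(
      stats::rnorm(nTrials, tab$discomfort_mean[ci], tab$discomfort_sd[ci]),
      0), 9)
    trials <- cbind(sched, rating = rating)

    rec <- new("ContinuousRecording",
               data = data, fs = fs, channelNames = channelNames,
               events = data.frame(onset_sample = onsetSamp,
                                   condition = sched$condition,
                                   session = sched$session,
                                   stringsAsFactors = FALSE),
               reference = "Cz")
    list(recording = rec, trials = trials, artifacts = artifacts,
         effects = effects, paradigm = paradigm)
  })
}

#' Generate a robot-skin contact temperature profile
#'
#' Two temperature-cell channels sampled at 250 Hz. Each sensor starts at
#' ambient temperature and relaxes exponentially toward the object's
#' temperature with time constant `tauS`, plus independent Gaussian sensor
#' noise. With `tauS = 0` the sensors equilibrate instantaneously.
#'
#' @param objectTempC object temperature in degrees Celsius.
#' @param durationS contact duration in seconds (> 0).
#' @param seed integer seed.
#' @param ambientC ambient start temperature (default 28).
#' @param tauS relaxation time constant in seconds (default 1).
#' @param noiseSdC sensor noise SD in degrees Celsius (default 0.05).
#' @param fs sampling rate in Hz (default 250).
#' @return a [SkinProfile] with `round(durationS * fs)` samples per channel.
#' @examples
#' p <- generateSkinProfile(12, 3, seed = 1)
#' ncol(skinData(p))  # 750
#' @export
generateSkinProfile <- function(objectTempC, durationS, seed, ambientC = 28,
                                tauS = 1, noiseSdC = 0.05, fs = 250) {
  .assertScalarPositive(durationS, "durationS")
  nSamp <- round(durationS * fs)
  t <- (seq_len(nSamp) - 1) / fs
  base <- if (tauS <= 0) rep(objectTempC, nSamp) else
    objectTempC + (ambientC - objectTempC) * exp(-t / tauS)
  data <- .withSeed(seed, {
    rbind(base + stats::rnorm(nSamp, 0, noiseSdC),
          base + stats::rnorm(nSamp, 0, noiseSdC))
  })
  lab <- tempToClass(objectTempC)$condition
  new("SkinProfile", data = data, fs = fs, objectTempC = objectTempC,
      ambientC = ambientC, label = if (is.na(lab)) "" else lab)
}
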