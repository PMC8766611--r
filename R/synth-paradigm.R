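#' Generate a thermal stimulation session schedule
#'
#' Builds a [StimulusParadigm] with a concrete, seeded pseudorandom trial
#' schedule: the balanced set of `length(conditions) * trialsPerCondition`
#' trials is shuffled uniformly, so every session delivers each condition
#' exactly `trialsPerCondition` times in randomized order. Each trial
#' occupies `baselineS + stimulationS` seconds of recording (recovery breaks
#' are not recorded); the schedule lists both the trial start and the
#' stimulation onset.
#'
#' The study design this emulates used two sessions: day 1 with
#' `c("very_hot", "hot", "warm")` (30 trials) and day 2 with
#' `c("very_cold", "cold")` (20 trials), 10 trials per condition.
#'
#' @param conditions condition names (subset of `thermalConditions()$name`).
#' @param trialsPerCondition trials per condition (default 10).
#' @param seed integer seed for the trial order.
#' @param sessionId session identifier.
#' @param baselineS,stimulationS,recoveryS,beepLeadS trial layout in seconds
#'   (defaults 10, 30, 120, 5).
#' @param fs sampling rate in Hz (default 512).
#' @param nChannels montage size (default 64).
#' @return a [StimulusParadigm] whose `schedule` has one row per trial with
#'   columns `trial`, `condition`, `trial_start_s`, `onset_s` (stimulation
#'   onset), `session`.
#' @examples
#' p <- generateParadigm(c("very_hot", "hot", "warm"), 10, seed = 1)
#' nrow(schedule(p))  # 30
#' @export
generateParadigm <- function(conditions, trialsPerCondition = 10L, seed,
                             sessionId = "day1",
                             baselineS = 10, stimulationS = 30,
                             recoveryS = 120, beepLeadS = 5,
                             fs = 512, nChannels = 64L) {
  if (length(conditions) < 1L)
    stop("configuration error: at least one condition is required")
  if (trialsPerCondition < 1L)
    stop("configuration error: trialsPerCondition must be >= 1")
  trialDur <- baselineS + stimulationS
  order <- .withSeed(seed, sample(rep(conditions, each = trialsPerCondition)))
  n <- length(order)
  sched <- data.frame(
    trial = seq_len(n),
    condition = order,
    trial_start_s = (seq_len(n) - 1L) * trialDur,
    onset_s = (seq_len(n) - 1L) * trialDur + baselineS,
    session = sessionId,
    stringsAsFactors = FALSE
  )
  new("StimulusParadigm",
      sessionId = sessionId, conditions = conditions,
      trialsPerCondition = as.integer(trialsPerCondition),
      baselineS = baselineS, stimulationS = stimulationS,
      recoveryS = recoveryS, beepLeadS = beepLeadS,
      fs = fs, nChannels = as.integer(nChannels),
      schedule = sched, seed = as.integer(seed))
}

#' Default effect specification for the synthetic generator
#'
#' The generator's default study conditions: the fraction of ongoing
#' alpha-band (8-12 Hz) power suppressed during stimulation increases
#' strictly with the condition's mean discomfort rating (so alpha power is
#' negatively correlated with discomfort by construction), the suppression
#' is carried by the contralateral-central channels (right-hand stimulation,
#' left hemisphere), and each condition adds an evoked transient at the
#' vertex with the condition-specific latency (0.3, 0.45, 0.65, 0.95, 0.8 s
#' for very cold, very hot, hot, cold, warm) and an amplitude ordered by
#' discomfort. Background activity is 1/f (pink) noise on every channel
#' plus an ongoing 10 Hz rhythm on posterior and central channels.
#'
#' @param alphaErdFraction named per-condition fraction of alpha power
#'   removed during stimulation.
#' @param erdChannels channels carrying the desynchronization.
#' @param erdWeights per-channel effect weight.
#' @param peakLatencyS,peakChannel,peakAmplitudeUv evoked transient
#'   latency (s), channel and amplitude (uV) per condition.
#' @param alphaAmplitudeUv ongoing alpha amplitude in uV.
#' @param alphaChannels channels carrying the ongoing alpha rhythm.
#' @param pinkAmplitudeUv RMS of the 1/f background in uV.
#' @param oneOverFExponent spectral exponent of the background.
#' @param artifactRateAmp expected high-amplitude artifacts per trial.
#' @param artifactRateEmg expected EMG bursts per trial.
#' @return an [EffectSpec].
#' @export
defaultEffectSpec <- function(
    alphaErdFraction = c(very_cold = 0.55, very_hot = 0.45, cold = 0.30,
                         hot = 0.20, warm = 0.05),
    erdChannels = c("C3", "C5", "C1", "CP3", "CP5"),
    erdWeights = rep(1, length(erdChannels)),
    peakLatencyS = c(very_cold = 0.30, very_hot = 0.45, hot = 0.65,
                     cold = 0.95, warm = 0.80),
    peakChannel = c(very_cold = "Cz", very_hot = "Cz", hot = "Cz",
                    cold = "Cz", warm = "Cz"),
    peakAmplitudeUv = c(very_cold = 8, very_hot = 6.5, cold = 5,
                        hot = 4.5, warm = 3),
    alphaAmplitudeUv = 20,
    alphaChannels = grep("^(C|CP|P|PO|O)[0-9z]", montage64(), value = TRUE),
    pinkAmplitudeUv = 10,
    oneOverFExponent = 1,
    artifactRateAmp = 0.05,
    artifactRateEmg = 0.05) {
  new("EffectSpec",
      alphaErdFraction = alphaErdFraction,
      erdChannels = erdChannels,
      erdWeights = erdWeights,
      peakLatencyS = peakLatencyS,
      peakChannel = peakChannel,
      peakAmplitudeUv = peakAmplitudeUv,
      alphaAmplitudeUv = alphaAmplitudeUv,
      alphaChannels = alphaChannels,
      pinkAmplitudeUv = pinkAmplitudeUv,
      oneOverFExponent = oneOverFExponent,
      artifactRateAmp = artifactRateAmp,
      artifactRateEmg = artifactRateEmg)
}

#' Generate behavioral thermal-sensation ratings
#'
#' Draws ratings on the 0-9 thermal sensation scale from a normal
#' distribution with the condition's mean and SD, truncated (clamped) to
#' `[0, 9]`. By default the condition table supplies mean and SD; both can
#' be overridden. With `round = TRUE` ratings are reported as integers, as
#' on the discrete scale handed to participants.
#'
#' @param condition condition name (used to look up mean/SD).
#' @param n number of ratings (>= 1).
#' @param seed integer seed.
#' @param mean,sd optional overrides of the condition's rating distribution.
#' @param round report integer ratings (default FALSE).
#' @return numeric vector of `n` ratings in `[0, 9]`.
#' @examples
#' generateRatings("very_cold", 5, seed = 1)
#' @export
generateRatings <- function(condition, n, seed, mean = NULL, sd = NULL,
                            round = FALSE) {
  if (!is.numeric(n) || length(n) != 1L || n < 1)
    stop("n must be >= 1")
  if (is.null(mean) || is.null(sd)) {
    row <- .conditionRow(condition)
    if (is.null(mean)) mean <- row$discomfort_mean
    if (is.null(sd)) sd <- row$discomfort_sd
  }
  r <- .withSeed(seed, stats::rnorm(n, mean, sd))
  r <- pmin(pmax(r, 0), 9)
  if (round) r <- base::round(r)
  r
}

#' @describeIn schedule-accessors schedule of a paradigm
#' @export
setGeneric("schedule", function(x) standardGeneric("schedule"))

#' Accessors for paradigm schedules
#'
#' @param x a [StimulusParadigm].
#' @return `schedule()` returns the trial schedule data.frame.
#' @name schedule-accessors
#' @aliases schedule,StimulusParadigm-method
setMethod("schedule", "StimulusParadigm", function(x) x@schedule)
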