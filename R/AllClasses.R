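#' @useDynLib thermoEEG, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @import methods
NULL

#' Continuous multichannel EEG recording
#'
#' Holds a channels-by-samples matrix in microvolts together with the
#' sampling rate, 10/20-system channel labels, and the stimulation event
#' schedule (one row per trial, onset given as a 1-based sample index).
#'
#' @slot data numeric matrix, channels x samples, in microvolts.
#' @slot fs sampling rate in Hz.
#' @slot channelNames unique channel labels.
#' @slot events data.frame with columns `onset_sample`, `condition`, `session`.
#' @slot reference label of the reference electrode ("" if unknown).
#'
#' @exportClass ContinuousRecording
setClass("ContinuousRecording",
  representation(
    data = "matrix",
    fs = "numeric",
    channelNames = "character",
    events = "data.frame",
    reference = "character"
  ),
  prototype(events = data.frame(onset_sample = integer(), condition = character(),
                                session = character()),
            reference = "")
)

setValidity("ContinuousRecording", function(object) {
  msg <- character()
  if (length(object@fs) != 1L || !is.finite(object@fs) || object@fs <= 0)
    msg <- c(msg, "fs must be a single positive number")
  if (nrow(object@data) != length(object@channelNames))
    msg <- c(msg, "nrow(data) must equal length(channelNames)")
  if (anyDuplicated(object@channelNames))
    msg <- c(msg, "channel names must be unique")
  ev <- object@events
  if (!all(c("onset_sample", "condition") %in% names(ev)))
    msg <- c(msg, "events must have onset_sample and condition columns")
  else if (nrow(ev) &&
           (any(ev$onset_sample < 1L) || any(ev$onset_sample > ncol(object@data))))
    msg <- c(msg, "event onsets must lie within the recording")
  if (length(msg)) msg else TRUE
})

#' Set of fixed-length EEG epochs
#'
#' Trials x channels x samples array cut from a [ContinuousRecording],
#' with one condition label and one parent-trial index per epoch and the
#' epoch window in seconds relative to stimulus onset (half-open
#' `[start, end)`).
#'
#' @slot data numeric array, trials x channels x samples (microvolts).
#' @slot fs sampling rate in Hz.
#' @slot labels condition label per trial.
#' @slot parentIds index of the originating trial in the source schedule.
#' @slot window numeric length-2, `(start_s, end_s)` relative to onset.
#' @slot channelNames channel labels.
#'
#' @exportClass EpochSet
setClass("EpochSet",
  representation(
    data = "array",
    fs = "numeric",
    labels = "character",
    parentIds = "integer",
    window = "numeric",
    channelNames = "character"
  )
)

setValidity("EpochSet", function(object) {
  msg <- character()
  d <- dim(object@data)
  if (length(d) != 3L)
    return("data must be a trials x channels x samples array")
  if (d[1] != length(object@labels))
    msg <- c(msg, "one label per trial required")
  if (d[1] != length(object@parentIds))
    msg <- c(msg, "one parent id per trial required")
  if (d[2] != length(object@channelNames))
    msg <- c(msg, "one channel name per channel required")
  if (length(object@window) != 2L || diff(object@window) <= 0)
    msg <- c(msg, "window must be (start_s, end_s) with end > start")
  else if (abs(round(diff(object@window) * object@fs) - d[3]) > 0.5)
    msg <- c(msg, "window length times fs must equal the sample count")
  if (length(msg)) msg else TRUE
})

#' Fitted common spatial patterns model
#'
#' Spatial filters from the simultaneous diagonalization of two class-average
#' covariance matrices. Eigenvalues are the fraction of (whitened) variance
#' the corresponding filter captures for the first class of `classPair`;
#' filters are ordered extremes-first (most class-A-discriminative, then most
#' class-B-discriminative, alternating outside-in).
#'
#' @slot filters numeric matrix, nFilters x channels.
#' @slot patterns numeric matrix, nFilters x channels (forward model rows).
#' @slot eigenvalues per-filter class-A variance ratio, in `[0, 1]`.
#' @slot classPair the two class labels, class A first.
#' @slot shrinkage trace-scaled covariance shrinkage used in the fit.
#' @slot channelNames channel labels the filters apply to.
#'
#' @exportClass CSPModel
setClass("CSPModel",
  representation(
    filters = "matrix",
    patterns = "matrix",
    eigenvalues = "numeric",
    classPair = "character",
    shrinkage = "numeric",
    channelNames = "character"
  )
)

setValidity("CSPModel", function(object) {
  msg <- character()
  if (nrow(object@filters) != length(object@eigenvalues))
    msg <- c(msg, "one eigenvalue per filter required")
  if (ncol(object@filters) != length(object@channelNames))
    msg <- c(msg, "filters must have one column per channel")
  if (any(object@eigenvalues < -1e-8 | object@eigenvalues > 1 + 1e-8))
    msg <- c(msg, "eigenvalues must lie in [0, 1]")
  if (length(object@classPair) < 2L)
    msg <- c(msg, "classPair must name at least two classes")
  if (length(msg)) msg else TRUE
})

#' Classifier evaluation report
#'
#' Confusion matrix on the held-out test portion, per-fold validation
#' balanced accuracies, the held-out balanced accuracy, and the seed and
#' splitting mode that produced them. Confusion rows are true classes,
#' columns predicted.
#'
#' @slot confusion integer confusion matrix (rows: truth).
#' @slot foldScores balanced accuracy per validation fold.
#' @slot testScore balanced accuracy on the held-out test set.
#' @slot seed integer seed used for the split.
#' @slot classPair class labels involved.
#' @slot mode splitting mode, `"group"` (parent-trial-aware) or `"crop"`.
#' @slot testIndices indices of the samples held out for the test phase.
#'
#' @exportClass ClassifierReport
setClass("ClassifierReport",
  representation(
    confusion = "matrix",
    foldScores = "numeric",
    testScore = "numeric",
    seed = "integer",
    classPair = "character",
    mode = "character",
    testIndices = "integer"
  ),
  prototype(testIndices = integer(0))
)

setValidity("ClassifierReport", function(object) {
  msg <- character()
  if (any(object@confusion < 0))
    msg <- c(msg, "confusion counts must be non-negative")
  if (length(object@testScore) == 1L &&
      is.finite(object@testScore) &&
      (object@testScore < 0 || object@testScore > 1))
    msg <- c(msg, "balanced accuracy must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' Robot-skin contact temperature profile
#'
#' Two temperature-cell channels sampled at 250 Hz during contact with an
#' object, plus the object's true temperature and condition label.
#'
#' @slot data numeric matrix, 2 x samples, in degrees Celsius.
#' @slot fs sampling rate in Hz (250).
#' @slot objectTempC true object temperature.
#' @slot ambientC ambient temperature the sensors start from.
#' @slot label true condition label of the object's temperature bin.
#'
#' @exportClass SkinProfile
setClass("SkinProfile",
  representation(
    data = "matrix",
    fs = "numeric",
    objectTempC = "numeric",
    ambientC = "numeric",
    label = "character"
  )
)

setValidity("SkinProfile", function(object) {
  msg <- character()
  if (nrow(object@data) != 2L)
    msg <- c(msg, "a skin profile has exactly two sensor channels")
  if (object@fs <= 0) msg <- c(msg, "fs must be positive")
  if (length(msg)) msg else TRUE
})

#' Thermal stimulation paradigm with a concrete trial schedule
#'
#' Describes one recording session: the conditions delivered, trials per
#' condition, the trial layout in seconds, sampling rate and montage size,
#' and (after generation) the seeded pseudorandom trial schedule. Onsets in
#' the schedule are stimulation onsets; each trial occupies
#' `baselineS + stimulationS` seconds of recording.
#'
#' @slot sessionId session identifier.
#' @slot conditions condition names delivered in this session.
#' @slot trialsPerCondition trials per condition.
#' @slot baselineS,stimulationS,recoveryS,beepLeadS trial layout in seconds.
#' @slot fs sampling rate in Hz.
#' @slot nChannels montage size.
#' @slot schedule data.frame: `trial`, `condition`, `trial_start_s`, `onset_s`.
#' @slot seed seed that produced the schedule.
#'
#' @exportClass StimulusParadigm
setClass("StimulusParadigm",
  representation(
    sessionId = "character",
    conditions = "character",
    trialsPerCondition = "integer",
    baselineS = "numeric",
    stimulationS = "numeric",
    recoveryS = "numeric",
    beepLeadS = "numeric",
    fs = "numeric",
    nChannels = "integer",
    schedule = "data.frame",
    seed = "integer"
  )
)

setValidity("StimulusParadigm", function(object) {
  msg <- character()
  if (length(object@conditions) < 1L)
    msg <- c(msg, "at least one condition is required")
  if (object@trialsPerCondition < 1L)
    msg <- c(msg, "trialsPerCondition must be >= 1")
  if (!all(object@conditions %in% thermalConditions()$name))
    msg <- c(msg, "unknown condition name")
  if (nrow(object@schedule) &&
      nrow(object@schedule) !=
        length(object@conditions) * object@trialsPerCondition)
    msg <- c(msg, "schedule length must equal conditions x trialsPerCondition")
  if (length(msg)) msg else TRUE
})

#' Effect specification for the synthetic EEG generator
#'
#' Per-condition effect sizes and the background-noise model the generator
#' realizes: the fraction of ongoing alpha-band power suppressed during
#' stimulation (event-related desynchronization), the spatial weighting of
#' that suppression, evoked-transient latency/channel/amplitude per
#' condition, the pink-noise and alpha-rhythm amplitudes, and the injected
#' artifact rates.
#'
#' @slot alphaErdFraction named fraction of alpha power removed per condition.
#' @slot erdChannels channels carrying the desynchronization.
#' @slot erdWeights per-channel weight for `erdChannels` (1 = full effect).
#' @slot peakLatencyS named evoked-peak latency per condition, seconds.
#' @slot peakChannel named evoked-peak channel per condition.
#' @slot peakAmplitudeUv named evoked-peak amplitude per condition, microvolts.
#' @slot alphaAmplitudeUv amplitude of the ongoing 10 Hz rhythm, microvolts.
#' @slot alphaChannels channels carrying the ongoing alpha rhythm.
#' @slot pinkAmplitudeUv RMS amplitude of the 1/f background, microvolts.
#' @slot oneOverFExponent spectral exponent of the background noise.
#' @slot artifactRateAmp expected >100 uV excursions per trial.
#' @slot artifactRateEmg expected 50-200 Hz EMG bursts per trial.
#'
#' @exportClass EffectSpec
setClass("EffectSpec",
  representation(
    alphaErdFraction = "numeric",
    erdChannels = "character",
    erdWeights = "numeric",
    peakLatencyS = "numeric",
    peakChannel = "character",
    peakAmplitudeUv = "numeric",
    alphaAmplitudeUv = "numeric",
    alphaChannels = "character",
    pinkAmplitudeUv = "numeric",
    oneOverFExponent = "numeric",
    artifactRateAmp = "numeric",
    artifactRateEmg = "numeric"
  )
)

setValidity("EffectSpec", function(object) {
  msg <- character()
  if (any(object@alphaErdFraction < 0 | object@alphaErdFraction > 1))
    msg <- c(msg, "alphaErdFraction must lie in [0, 1]")
  if (length(object@erdWeights) != length(object@erdChannels))
    msg <- c(msg, "one weight per ERD channel required")
  if (length(msg)) msg else TRUE
})
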