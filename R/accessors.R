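# Accessor generics and methods, plus show() methods.

#' @rdname accessors
#' @export
setGeneric("samplingRate", function(x) standardGeneric("samplingRate"))
#' @rdname accessors
#' @export
setGeneric("channelLabels", function(x) standardGeneric("channelLabels"))
#' @rdname accessors
#' @export
setGeneric("signalData", function(x) standardGeneric("signalData"))
#' @rdname accessors
#' @export
setGeneric("eventTable", function(x) standardGeneric("eventTable"))
#' @rdname accessors
#' @export
setGeneric("epochLabels", function(x) standardGeneric("epochLabels"))
#' @rdname accessors
#' @export
setGeneric("parentIds", function(x) standardGeneric("parentIds"))
#' @rdname accessors
#' @export
setGeneric("epochWindow", function(x) standardGeneric("epochWindow"))
#' @rdname accessors
#' @export
setGeneric("nEpochs", function(x) standardGeneric("nEpochs"))
#' @rdname accessors
#' @export
setGeneric("spatialFilters", function(x) standardGeneric("spatialFilters"))
#' @rdname accessors
#' @export
setGeneric("cspEigenvalues", function(x) standardGeneric("cspEigenvalues"))
#' @rdname accessors
#' @export
setGeneric("confusionMatrix", function(x) standardGeneric("confusionMatrix"))
#' @rdname accessors
#' @export
setGeneric("foldScores", function(x) standardGeneric("foldScores"))
#' @rdname accessors
#' @export
setGeneric("balancedAccuracy", function(x) standardGeneric("balancedAccuracy"))
#' @rdname accessors
#' @export
setGeneric("skinData", function(x) standardGeneric("skinData"))

#' Accessors for thermoEEG data classes
#'
#' Slot accessors: `samplingRate()` (Hz), `channelLabels()`,
#' `signalData()` (channels x samples matrix for recordings, the
#' trials x channels x samples array for epoch sets), `eventTable()`,
#' `epochLabels()`, `parentIds()`, `epochWindow()`, `nEpochs()`,
#' `spatialFilters()`, `cspEigenvalues()`, `confusionMatrix()`,
#' `foldScores()`, `balancedAccuracy()`, `skinData()`.
#'
#' @param x a thermoEEG object.
#' @return the slot value.
#' @name accessors
#' @aliases samplingRate,ContinuousRecording-method
NULL

setMethod("samplingRate", "ContinuousRecording", function(x) x@fs)
setMethod("samplingRate", "EpochSet", function(x) x@fs)
setMethod("samplingRate", "SkinProfile", function(x) x@fs)
setMethod("channelLabels", "ContinuousRecording", function(x) x@channelNames)
setMethod("channelLabels", "EpochSet", function(x) x@channelNames)
setMethod("channelLabels", "CSPModel", function(x) x@channelNames)
setMethod("signalData", "ContinuousRecording", function(x) x@data)
setMethod("signalData", "EpochSet", function(x) x@data)
setMethod("eventTable", "ContinuousRecording", function(x) x@events)
setMethod("epochLabels", "EpochSet", function(x) x@labels)
setMethod("parentIds", "EpochSet", function(x) x@parentIds)
setMethod("epochWindow", "EpochSet", function(x) x@window)
setMethod("nEpochs", "EpochSet", function(x) dim(x@data)[1])
setMethod("spatialFilters", "CSPModel", function(x) x@filters)
setMethod("cspEigenvalues", "CSPModel", function(x) x@eigenvalues)
setMethod("confusionMatrix", "ClassifierReport", function(x) x@confusion)
setMethod("foldScores", "ClassifierReport", function(x) x@foldScores)
setMethod("balancedAccuracy", "ClassifierReport", function(x) x@testScore)
setMethod("skinData", "SkinProfile", function(x) x@data)

setMethod("show", "ContinuousRecording", function(object) {
  cat("ContinuousRecording:", nrow(object@data), "channels x",
      ncol(object@data), "samples @", object@fs, "Hz\n")
  cat("  duration:", round(ncol(object@data) / object@fs, 2), "s;",
      nrow(object@events), "events\n")
  if (nrow(object@events))
    cat("  conditions:",
        paste(sort(unique(object@events$condition)), collapse = ", "), "\n")
})

setMethod("show", "EpochSet", function(object) {
  d <- dim(object@data)
  cat("EpochSet:", d[1], "epochs x", d[2], "channels x", d[3],
      "samples @", object@fs, "Hz\n")
  cat("  window: [", object@window[1], ",", object@window[2],
      ") s relative to onset\n")
  cat("  labels:", paste(names(table(object@labels)),
                         table(object@labels), sep = ":", collapse = " "), "\n")
})

setMethod("show", "CSPModel", function(object) {
  cat("CSPModel:", nrow(object@filters), "spatial filters over",
      ncol(object@filters), "channels\n")
  cat("  class pair:", paste(object@classPair, collapse = " vs "),
      "; shrinkage:", object@shrinkage, "\n")
  cat("  eigenvalues:", paste(round(object@eigenvalues, 3), collapse = ", "),
      "\n")
})

setMethod("show", "ClassifierReport", function(object) {
  cat("ClassifierReport (", paste(object@classPair, collapse = " vs "),
      "; mode=", object@mode, ", seed=", object@seed, ")\n", sep = "")
  if (length(object@foldScores))
    cat("  validation bACC: mean", round(mean(object@foldScores), 4),
        "over", length(object@foldScores), "folds\n")
  cat("  test bACC:", round(object@testScore, 4), "\n")
  cat("  confusion (rows = truth):\n")
  print(object@confusion)
})

setMethod("show", "SkinProfile", function(object) {
  cat("SkinProfile: 2 sensors x", ncol(object@data), "samples @",
      object@fs, "Hz\n")
  cat("  object:", object@objectTempC, "C (", object@label,
      "); ambient:", object@ambientC, "C\n")
})

setMethod("show", "StimulusParadigm", function(object) {
  cat("StimulusParadigm '", object@sessionId, "': ",
      length(object@conditions), " conditions x ",
      object@trialsPerCondition, " trials (",
      nrow(object@schedule), " scheduled)\n", sep = "")
  cat("  trial: ", object@baselineS, " s baseline + ", object@stimulationS,
      " s stimulation; fs = ", object@fs, " Hz, ",
      object@nChannels, " channels\n", sep = "")
})
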