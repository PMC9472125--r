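#' @include AllClasses.R
NULL

#' Number of channels of a recording
#' @param x a [Recording-class]
#' @return integer count
#' @export
setGeneric("nChannels", function(x) standardGeneric("nChannels"))

#' Number of samples of a recording
#' @param x a [Recording-class]
#' @return integer count
#' @export
setGeneric("nSamples", function(x) standardGeneric("nSamples"))

#' Sampling rate in Hz
#' @param x a recording-like object
#' @return numeric rate
#' @export
setGeneric("samplingRate", function(x) standardGeneric("samplingRate"))

#' Recording duration in seconds
#' @param x a recording-like object
#' @return numeric seconds
#' @export
setGeneric("duration", function(x) standardGeneric("duration"))

#' Modality tag of an object
#' @param x object carrying a modality
#' @return character scalar
#' @export
setGeneric("modality", function(x) standardGeneric("modality"))

#' Channel metadata table
#' @param x a [Recording-class]
#' @return `data.frame`
#' @export
setGeneric("channels", function(x) standardGeneric("channels"))

#' Raw signal matrix (channels x samples)
#' @param x a [Recording-class]
#' @return numeric matrix
#' @export
setGeneric("signalData", function(x) standardGeneric("signalData"))

#' Event table of a schedule
#' @param x an [EventSchedule-class]
#' @return `data.frame` with onset, duration, label
#' @export
setGeneric("events", function(x) standardGeneric("events"))

#' Class label of a labeled object
#' @param x labeled object (e.g. [RPSequence-class])
#' @return character scalar
#' @export
setGeneric("rpLabel", function(x) standardGeneric("rpLabel"))

#' Recurrence-plot images of a sequence
#' @param x an [RPSequence-class]
#' @return list of square matrices
#' @export
setGeneric("rpImages", function(x) standardGeneric("rpImages"))

setMethod("nChannels", "Recording", function(x) nrow(x@data))
setMethod("nSamples", "Recording", function(x) ncol(x@data))
setMethod("samplingRate", "Recording", function(x) x@rate)
setMethod("samplingRate", "HemoRecording", function(x) x@rate)
setMethod("duration", "Recording", function(x) ncol(x@data) / x@rate)
setMethod("duration", "HemoRecording", function(x) ncol(x@hbo) / x@rate)
setMethod("modality", "Recording", function(x) x@modality)
setMethod("modality", "RPSequence", function(x) x@modality)
setMethod("channels", "Recording", function(x) x@channels)
setMethod("signalData", "Recording", function(x) x@data)
setMethod("events", "EventSchedule", function(x) x@events)
setMethod("rpLabel", "RPSequence", function(x) x@label)
setMethod("rpImages", "RPSequence", function(x) x@images)

setMethod("show", "Recording", function(object) {
  cat(sprintf("Recording [%s]: %d channels x %d samples @ %g Hz (%.1f s)\n",
              object@modality, nrow(object@data), ncol(object@data),
              object@rate, ncol(object@data) / object@rate))
})

setMethod("show", "EventSchedule", function(object) {
  cat(sprintf("EventSchedule: session %d, series %d, %d events\n",
              object@sessionId, object@seriesId, nrow(object@events)))
  if (nrow(object@events)) print(utils::head(object@events, 6))
})

setMethod("show", "HemoRecording", function(object) {
  cat(sprintf("HemoRecording: %d sites x %d samples @ %g Hz (HbO/HbR, umol/L)\n",
              nrow(object@hbo), ncol(object@hbo), object@rate))
})

setMethod("show", "RPSequence", function(object) {
  sz <- if (length(object@images)) nrow(object@images[[1]]) else 0L
  cat(sprintf("RPSequence [%s] '%s': %d plots of %dx%d\n", object@modality,
              object@label, length(object@images), sz, sz))
})

setMethod("show", "EvalReport", function(object) {
  cat(sprintf("EvalReport [%s]: %d folds\n", object@modality, nrow(object@folds)))
  cat(sprintf("  mean accuracy %.2f%%, precision %.2f%%, recall %.2f%%, F1 %.2f%%\n",
              object@mean["accuracy"], object@mean["precision"],
              object@mean["recall"], object@mean["f1"]))
})
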