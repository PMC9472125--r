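#' @import methods
NULL

.MODALITIES <- c("eeg", "fnirs_od", "fnirs_hb")
.EVENT_LABELS <- c("0-back", "2-back", "3-back", "rest", "instruction")
.CLASS_LABELS <- c("0-back", "2-back", "3-back", "rest")

#' Multichannel physiological recording
#'
#' A `Recording` holds one continuous multichannel time series together with
#' its sampling rate and per-channel metadata. EEG data are in microvolts;
#' fNIRS data are either optical density (modality `"fnirs_od"`, one channel
#' per site-wavelength pair) or hemoglobin concentration change.
#'
#' @slot data numeric matrix, channels x samples.
#' @slot rate sampling rate in Hz (> 0).
#' @slot channels `data.frame` with one row per channel and columns
#'   `label` (unique), `role` (`"eeg"` or `"source-detector pair"`),
#'   `wavelength` (nm, `NA` unless modality is `fnirs_od`) and
#'   `sourceDetectorDistance` (cm, `NA` for EEG).
#' @slot modality one of `"eeg"`, `"fnirs_od"`, `"fnirs_hb"`.
#' @slot startTime recording start in seconds.
#'
#' @seealso [Recording()], [readEEGEDF()], [readFNIRSSNIRF()]
#' @export
setClass("Recording", representation(
  data = "matrix",
  rate = "numeric",
  channels = "data.frame",
  modality = "character",
  startTime = "numeric"
))

setValidity("Recording", function(object) {
  msg <- character()
  if (length(object@rate) != 1L || !is.finite(object@rate) || object@rate <= 0)
    msg <- c(msg, "rate must be a single positive number")
  if (!is.numeric(object@data))
    msg <- c(msg, "data must be a numeric matrix")
  if (length(object@modality) != 1L || !object@modality %in% .MODALITIES)
    msg <- c(msg, sprintf("modality must be one of %s",
                          paste(.MODALITIES, collapse = ", ")))
  ch <- object@channels
  if (nrow(ch) != nrow(object@data))
    msg <- c(msg, "channels must have one row per data row")
  if (anyDuplicated(ch$label))
    msg <- c(msg, "channel labels must be unique")
  if (length(object@modality) == 1L && object@modality == "fnirs_od") {
    if (nrow(ch) %% 2L != 0L)
      msg <- c(msg, "fnirs_od recordings need an even channel count (paired wavelengths per site)")
    if (any(is.na(ch$wavelength)))
      msg <- c(msg, "fnirs_od channels must all carry a wavelength")
    if (any(!is.na(ch$sourceDetectorDistance) & ch$sourceDetectorDistance <= 0))
      msg <- c(msg, "source-detector distances must be positive")
  } else if (length(object@modality) == 1L && object@modality == "eeg") {
    if (!all(is.na(ch$wavelength)))
      msg <- c(msg, "eeg channels must not carry a wavelength")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a Recording
#'
#' @param data channels x samples numeric matrix.
#' @param rate sampling rate (Hz).
#' @param channels per-channel metadata `data.frame` (see [Recording-class]);
#'   a character vector of labels is also accepted and expanded.
#' @param modality `"eeg"`, `"fnirs_od"` or `"fnirs_hb"`.
#' @param startTime recording start time in seconds.
#' @return a validated [Recording-class] object.
#' @examples
#' rec <- Recording(matrix(rnorm(200), 2), rate = 100,
#'                  channels = c("C1", "C2"), modality = "eeg")
#' nChannels(rec)
#' @export
Recording <- function(data, rate, channels, modality, startTime = 0) {
  data <- as.matrix(data)
  if (is.character(channels))
    channels <- channelInfo(channels,
                            role = if (modality == "eeg") "eeg" else "source-detector pair")
  new("Recording", data = data, rate = as.numeric(rate), channels = channels,
      modality = modality, startTime = as.numeric(startTime))
}

#' Per-channel metadata table
#'
#' @param label channel labels (unique).
#' @param role `"eeg"` or `"source-detector pair"`.
#' @param wavelength wavelength in nm (fNIRS optical-density channels only).
#' @param sourceDetectorDistance source-detector separation in cm (fNIRS only).
#' @return `data.frame` with one row per channel.
#' @export
channelInfo <- function(label, role = "eeg", wavelength = NA_real_,
                        sourceDetectorDistance = NA_real_) {
  data.frame(label = as.character(label), role = role,
             wavelength = as.numeric(wavelength),
             sourceDetectorDistance = as.numeric(sourceDetectorDistance),
             stringsAsFactors = FALSE)
}

#' Timed protocol events for one series
#'
#' Onsets are seconds from recording start; conversion to sample indices is
#' `floor(onset * rate)` with half-open `[start, end)` intervals, so the same
#' schedule drives both the EEG and the fNIRS stream.
#'
#' @slot events `data.frame` with columns `onset` (s), `duration` (s) and
#'   `label` (one of `0-back`, `2-back`, `3-back`, `rest`, `instruction`).
#' @slot sessionId integer session index.
#' @slot seriesId integer series index within the run.
#' @export
setClass("EventSchedule", representation(
  events = "data.frame",
  sessionId = "integer",
  seriesId = "integer"
))

setValidity("EventSchedule", function(object) {
  ev <- object@events
  msg <- character()
  if (!all(c("onset", "duration", "label") %in% names(ev)))
    return("events must have columns onset, duration, label")
  if (nrow(ev)) {
    if (is.unsorted(ev$onset))
      msg <- c(msg, "event onsets must be non-decreasing")
    if (any(ev$duration < 0))
      msg <- c(msg, "event durations must be non-negative")
    bad <- setdiff(unique(ev$label), .EVENT_LABELS)
    if (length(bad))
      msg <- c(msg, sprintf("unknown event label(s) %s; allowed: %s",
                            paste(sQuote(bad), collapse = ", "),
                            paste(.EVENT_LABELS, collapse = ", ")))
    if (nrow(ev) > 1L) {
      ends <- ev$onset + ev$duration
      if (any(ev$onset[-1L] < ends[-nrow(ev)] - 1e-9))
        msg <- c(msg, "events must not overlap")
    }
  }
  if (length(msg)) msg else TRUE
})

#' Construct an EventSchedule
#'
#' @param onset,duration event timing in seconds.
#' @param label event labels from the closed set
#'   `0-back`, `2-back`, `3-back`, `rest`, `instruction`.
#' @param sessionId,seriesId provenance indices.
#' @return validated [EventSchedule-class].
#' @export
EventSchedule <- function(onset = numeric(), duration = numeric(),
                          label = character(), sessionId = 1L, seriesId = 1L) {
  new("EventSchedule",
      events = data.frame(onset = as.numeric(onset),
                          duration = as.numeric(duration),
                          label = as.character(label),
                          stringsAsFactors = FALSE),
      sessionId = as.integer(sessionId), seriesId = as.integer(seriesId))
}

#' Hemoglobin concentration-change recording
#'
#' Result of the modified Beer-Lambert conversion: per-site oxygenated (HbO)
#' and deoxygenated (HbR) hemoglobin concentration changes in micromolar.
#'
#' @slot hbo,hbr sites x samples matrices (umol/L).
#' @slot rate sampling rate (Hz).
#' @slot sites `data.frame` of per-site metadata (label, distance).
#' @slot startTime seconds.
#' @export
setClass("HemoRecording", representation(
  hbo = "matrix", hbr = "matrix", rate = "numeric",
  sites = "data.frame", startTime = "numeric"
))

setValidity("HemoRecording", function(object) {
  msg <- character()
  if (!identical(dim(object@hbo), dim(object@hbr)))
    msg <- c(msg, "hbo and hbr must have the same shape")
  if (length(object@rate) != 1L || object@rate <= 0)
    msg <- c(msg, "rate must be positive")
  if (length(msg)) msg else TRUE
})

#' Delay-embedded phase-space trajectory
#'
#' Rows are phase-space state vectors built by time-delay embedding: for a
#' scalar series the i-th state is `(x_i, x_{i+d}, ..., x_{i+(m-1)d})`; for a
#' multichannel window the per-channel delay vectors are concatenated.
#'
#' @slot states T x (m * C) numeric matrix of state vectors.
#' @slot m,d embedding dimension and delay (samples, post-stride).
#' @slot window numeric length-2 vector, source window bounds in seconds.
#' @export
setClass("StateTrajectory", representation(
  states = "matrix", m = "integer", d = "integer", window = "numeric"
))

#' Recurrence-plot image sequence for one labeled segment
#'
#' Chronologically ordered stack of square recurrence matrices (one per
#' analysis window) computed from one labeled segment of one modality.
#'
#' @slot images list of square matrices; binary plots have values in
#'   `{0, 1}` with a unit main diagonal, grayscale plots values in `[0, 1]`.
#' @slot label class label (`0-back`, `2-back`, `3-back` or `rest`).
#' @slot modality `"eeg"` or `"fnirs"`.
#' @slot provenance named list (subject/session/series indices etc.).
#' @export
setClass("RPSequence", representation(
  images = "list", label = "character", modality = "character",
  provenance = "list"
))

setValidity("RPSequence", function(object) {
  msg <- character()
  if (length(object@images)) {
    dims <- vapply(object@images, function(im) dim(im), integer(2))
    if (any(dims[1, ] != dims[2, ]))
      msg <- c(msg, "all recurrence plots must be square")
    if (length(unique(dims[1, ])) != 1L)
      msg <- c(msg, "all recurrence plots in a sequence must have the same size")
  }
  if (length(object@label) != 1L || !object@label %in% .CLASS_LABELS)
    msg <- c(msg, "label must be one of 0-back, 2-back, 3-back, rest")
  if (length(msg)) msg else TRUE
})

#' Cross-validation evaluation report
#'
#' @slot folds `data.frame` with one row per fold: accuracy, precision,
#'   recall and F1, all in percent.
#' @slot mean named numeric, arithmetic mean over folds of the four metrics.
#' @slot confusion list of per-fold 4 x 4 confusion matrices
#'   (rows true, columns predicted; class order 0-back, 2-back, 3-back, rest).
#' @slot modality modality tag.
#' @export
setClass("EvalReport", representation(
  folds = "data.frame", mean = "numeric", confusion = "list",
  modality = "character"
))

setValidity("EvalReport", function(object) {
  m <- unlist(object@folds[, intersect(names(object@folds),
                                       c("accuracy", "precision", "recall", "f1"))])
  if (length(m) && (any(m < -1e-9) || any(m > 100 + 1e-9)))
    return("metrics must lie in [0, 100] percent")
  TRUE
})
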