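# Time-delay embedding, phase-space distance matrices, thresholded
# recurrence matrices, and windowed recurrence-plot sequences per modality.

#' Time-delay embedding configuration
#'
#' @slot m embedding dimension (>= 1).
#' @slot d delay in samples (>= 1), applied after any within-window stride.
#' @slot n optional dimension of the underlying system; when given,
#'   [checkEmbedding()] warns unless `m >= 2n + 1` (the sufficient condition
#'   for a delay reconstruction to recover the system's topology).
#' @export
setClass("EmbeddingConfig", representation(
  m = "integer", d = "integer", n = "integer"
))

setValidity("EmbeddingConfig", function(object) {
  if (object@m < 1L || object@d < 1L) "m and d must be >= 1" else TRUE
})

#' @param m embedding dimension.
#' @param d delay (samples).
#' @param n optional underlying-system dimension.
#' @return an [EmbeddingConfig-class].
#' @rdname EmbeddingConfig-class
#' @export
EmbeddingConfig <- function(m = 1, d = 1, n = NA) {
  new("EmbeddingConfig", m = as.integer(m), d = as.integer(d),
      n = as.integer(n))
}

#' Recurrence-plot configuration
#'
#' Defaults follow the analysis settings used throughout the package:
#' 5 s windows with 20% overlap, recurrence threshold `epsilon = 0.1`
#' interpreted as a fraction of the maximum phase-space distance within the
#' window, and a within-window subsampling stride of 10 samples for EEG
#' (1 for fNIRS), keeping EEG plots at 100 x 100 and fNIRS plots at 50 x 50.
#'
#' @slot windowSec analysis window length in seconds.
#' @slot overlap fractional overlap between consecutive windows, in `[0, 1)`.
#' @slot step within-window subsampling stride in samples (>= 1), applied
#'   before embedding.
#' @slot epsilon recurrence threshold (> 0).
#' @slot epsilonMode `"fraction_of_max_distance"` (threshold is
#'   `epsilon * max(D)` per window) or `"absolute"`.
#' @slot outputMode `"binary"` or `"grayscale"` (`1 - D/max(D)` distance map).
#' @export
setClass("RPConfig", representation(
  windowSec = "numeric", overlap = "numeric", step = "integer",
  epsilon = "numeric", epsilonMode = "character", outputMode = "character"
))

setValidity("RPConfig", function(object) {
  msg <- character()
  if (object@overlap < 0 || object@overlap >= 1)
    msg <- c(msg, "overlap must lie in [0, 1)")
  if (object@step < 1L) msg <- c(msg, "step must be >= 1")
  if (object@epsilon <= 0) msg <- c(msg, "epsilon must be > 0")
  if (!object@epsilonMode %in% c("fraction_of_max_distance", "absolute"))
    msg <- c(msg, "epsilonMode must be fraction_of_max_distance or absolute")
  if (!object@outputMode %in% c("binary", "grayscale"))
    msg <- c(msg, "outputMode must be binary or grayscale")
  if (length(msg)) msg else TRUE
})

#' @param windowSec,overlap,step,epsilon,epsilonMode,outputMode see slots.
#' @return an [RPConfig-class].
#' @rdname RPConfig-class
#' @export
RPConfig <- function(windowSec = 5, overlap = 0.2, step = 10, epsilon = 0.1,
                     epsilonMode = "fraction_of_max_distance",
                     outputMode = "binary") {
  new("RPConfig", windowSec = windowSec, overlap = overlap,
      step = as.integer(step), epsilon = epsilon, epsilonMode = epsilonMode,
      outputMode = outputMode)
}

#' Check the delay-embedding dimension condition
#'
#' Warns (never fails) when the underlying-system dimension `n` is given and
#' the embedding dimension does not satisfy `m >= 2n + 1`.
#'
#' @param cfg an [EmbeddingConfig-class].
#' @return `TRUE` (pass) or `FALSE` (warned), invisibly.
#' @export
checkEmbedding <- function(cfg) {
  if (!is.na(cfg@n) && cfg@m < 2L * cfg@n + 1L) {
    warning("embedding dimension m = ", cfg@m, " is below 2n + 1 = ",
            2L * cfg@n + 1L, "; the reconstruction may not recover the ",
            "system's topology")
    return(invisible(FALSE))
  }
  invisible(TRUE)
}

#' Delay-embed a signal window into phase space
#'
#' For each retained time index `i`, the state vector concatenates the `m`
#' delayed copies `x_i, x_{i+d}, ..., x_{i+(m-1)d}` of every channel, giving
#' a `T x (m * C)` trajectory with `T = S - (m - 1) d` for a window of `S`
#' retained samples.
#'
#' @param x numeric vector (single channel) or channels x samples matrix.
#' @param cfg an [EmbeddingConfig-class].
#' @param windowBounds optional length-2 numeric, seconds, carried through.
#' @return a [StateTrajectory-class].
#' @examples
#' embedSeries(c(1, 2, 3, 4, 5), EmbeddingConfig(m = 2, d = 1))@states
#' @export
embedSeries <- function(x, cfg = EmbeddingConfig(), windowBounds = c(NA, NA)) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1L)
  S <- ncol(x)
  m <- cfg@m; d <- cfg@d
  Tn <- S - (m - 1L) * d
  if (Tn < 1L)
    stop("window of ", S, " samples is too short for m = ", m, ", d = ", d,
         " (needs >= ", (m - 1L) * d + 1L, ")")
  C <- nrow(x)
  states <- matrix(0, Tn, m * C)
  for (k in seq_len(m)) {
    cols <- ((k - 1L) * C + 1L):(k * C)
    states[, cols] <- t(x[, (1L + (k - 1L) * d):((k - 1L) * d + Tn),
                          drop = FALSE])
  }
  new("StateTrajectory", states = states, m = m, d = d,
      window = as.numeric(windowBounds))
}

#' Euclidean distance matrix of a phase-space trajectory
#'
#' @param traj a [StateTrajectory-class] (or a plain states matrix).
#' @return symmetric `T x T` matrix with zero diagonal,
#'   `D[i, j] = ||x(i) - x(j)||_2`.
#' @export
distanceMatrix <- function(traj) {
  states <- if (is(traj, "StateTrajectory")) traj@states else as.matrix(traj)
  if (nrow(states) < 2L) stop("trajectory must have at least 2 states")
  as.matrix(stats::dist(states))
}

#' Threshold a distance matrix into a recurrence matrix
#'
#' Binary mode marks `R[i, j] = 1` exactly when `D[i, j] <= eps'`, where
#' `eps'` is `epsilon * max(D)` in fraction mode or `epsilon` itself in
#' absolute mode. Grayscale mode returns `1 - D / max(D)` (all ones when the
#' trajectory is constant). In fraction mode the binary plot is invariant
#' under positive rescaling of the input window.
#'
#' @param D distance matrix from [distanceMatrix()].
#' @param cfg an [RPConfig-class].
#' @return square matrix, values in `{0, 1}` (binary) or `[0, 1]` (grayscale).
#' @export
recurrenceMatrix <- function(D, cfg = RPConfig()) {
  D <- unname(as.matrix(D))
  mx <- max(D)
  if (cfg@outputMode == "grayscale") {
    if (mx == 0) return(matrix(1, nrow(D), ncol(D)))
    return(1 - D / mx)
  }
  eps <- if (cfg@epsilonMode == "fraction_of_max_distance")
    cfg@epsilon * mx else cfg@epsilon
  (D <= eps) * 1
}

#' Number of analysis windows fitting a segment
#'
#' @param nSamples segment length in samples.
#' @param rate sampling rate (Hz).
#' @param cfg an [RPConfig-class].
#' @return list with `width`, `advance` (samples) and `count`.
#' @export
windowGrid <- function(nSamples, rate, cfg = RPConfig()) {
  W <- round(cfg@windowSec * rate)
  A <- round(cfg@windowSec * (1 - cfg@overlap) * rate)
  list(width = as.integer(W), advance = as.integer(A),
       count = if (nSamples < W) 0L else as.integer((nSamples - W) %/% A + 1L))
}

#' Recurrence-plot sequence of one labeled segment
#'
#' Slides a `windowSec` window with the configured overlap across the
#' segment; within each window, samples are subsampled by `step`, each
#' channel is z-scored, the channel-stacked state vectors are delay-embedded,
#' and the recurrence plot is computed. One plot per window, in order.
#'
#' @param rec a [Recording-class] (or [HemoRecording-class], whose HbO and
#'   HbR matrices are stacked as channels) cropped to the segment.
#' @param label class label of the segment.
#' @param ecfg an [EmbeddingConfig-class].
#' @param rcfg an [RPConfig-class].
#' @param provenance named list carried through.
#' @return an [RPSequence-class].
#' @export
windowRPSequence <- function(rec, label, ecfg = EmbeddingConfig(),
                             rcfg = RPConfig(), provenance = list()) {
  if (is(rec, "HemoRecording")) {
    x <- rbind(rec@hbo, rec@hbr)
    rate <- rec@rate
    mod <- "fnirs"
  } else {
    x <- rec@data
    rate <- rec@rate
    mod <- if (rec@modality == "eeg") "eeg" else "fnirs"
  }
  g <- windowGrid(ncol(x), rate, rcfg)
  if (g$count < 1L)
    stop("segment of ", ncol(x), " samples is shorter than one ",
         rcfg@windowSec, " s window (", g$width, " samples)")
  images <- vector("list", g$count)
  for (w in seq_len(g$count)) {
    i0 <- (w - 1L) * g$advance
    win <- x[, (i0 + 1L):(i0 + g$width), drop = FALSE]
    win <- win[, seq.int(1L, ncol(win), by = rcfg@step), drop = FALSE]
    mu <- rowMeans(win)
    sdv <- apply(win, 1L, stats::sd)
    sdv[sdv < .Machine$double.eps] <- 1
    win <- (win - mu) / sdv
    traj <- embedSeries(win, ecfg)
    images[[w]] <- recurrenceMatrix(distanceMatrix(traj), rcfg)
  }
  new("RPSequence", images = images, label = label, modality = mod,
      provenance = provenance)
}

#' Pair EEG and fNIRS recurrence-plot sequences of one segment
#'
#' Window grids are defined in seconds, so the two modalities align
#' positionally. If the counts differ by rounding, the pair is truncated to
#' the shorter sequence with a warning.
#'
#' @param eegSeq,fnirsSeq [RPSequence-class] objects from the same labeled
#'   segment.
#' @return list with `eeg`, `fnirs` (equal-length image lists) and `label`.
#' @export
pairHybrid <- function(eegSeq, fnirsSeq) {
  if (!identical(eegSeq@label, fnirsSeq@label))
    stop("label mismatch: '", eegSeq@label, "' vs '", fnirsSeq@label, "'")
  ne <- length(eegSeq@images); nf <- length(fnirsSeq@images)
  n <- min(ne, nf)
  if (ne != nf)
    warning("window counts differ (", ne, " EEG vs ", nf,
            " fNIRS); truncating to ", n)
  list(eeg = eegSeq@images[seq_len(n)], fnirs = fnirsSeq@images[seq_len(n)],
       label = eegSeq@label)
}

#' Assemble fixed-length window sequences for the classifier
#'
#' Consecutive non-overlapping runs of `tSeq` windows sharing one label form
#' one training sample; a trailing remainder shorter than `tSeq` is dropped.
#'
#' @param images list of square matrices (one labeled segment's plots).
#' @param tSeq windows per sample.
#' @return list of `tSeq`-long lists of matrices.
#' @export
assembleSequences <- function(images, tSeq = 4L) {
  n <- length(images) %/% tSeq
  lapply(seq_len(n), function(i)
    images[((i - 1L) * tSeq + 1L):(i * tSeq)])
}
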