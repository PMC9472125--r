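# Pre-processing: anti-aliased resampling, zero-phase Butterworth filtering,
# the modified Beer-Lambert conversion, labeling, outlier rejection and
# training-fold normalization.

# steady-state initial conditions for filtering (removes the startup
# transient when combined with odd-reflection edge padding)
.filter_zi <- function(b, a) {
  n <- max(length(a), length(b))
  b <- c(b, numeric(n - length(b)))
  a <- c(a, numeric(n - length(a)))
  b <- b / a[1]; a <- a / a[1]
  if (n == 1L) return(numeric(0))
  A <- diag(1, n - 1L) - cbind(-a[-1L], rbind(diag(1, n - 2L),
                                              numeric(n - 2L)))
  B <- b[-1L] - b[1L] * a[-1L]
  solve(A, B)
}

# forward-backward IIR filtering with odd-reflection padding of
# 3 x filter order and steady-state initial conditions (zero phase lag;
# magnitude response squared)
.filtfilt <- function(b, a, x) {
  n <- length(x)
  nfact <- 3L * (max(length(a), length(b)) - 1L)
  if (n <= nfact)
    stop("signal too short for zero-phase filtering (need > ", nfact,
         " samples)")
  pre <- 2 * x[1L] - x[(nfact + 1L):2L]
  post <- 2 * x[n] - x[(n - 1L):(n - nfact)]
  xp <- c(pre, x, post)
  zi <- .filter_zi(b, a)
  y <- .iir_filter(b, a, xp, zi * xp[1L])
  y <- rev(y)
  y <- .iir_filter(b, a, y, zi * y[1L])
  rev(y)[(nfact + 1L):(nfact + n)]
}

.apply_rows <- function(x, f) t(apply(x, 1L, f))

.map_signal <- function(rec, f) {
  if (is(rec, "Recording")) {
    out <- rec
    out@data <- .apply_rows(rec@data, f)
    out
  } else if (is(rec, "HemoRecording")) {
    out <- rec
    out@hbo <- .apply_rows(rec@hbo, f)
    out@hbr <- .apply_rows(rec@hbr, f)
    out
  } else stop("expected a Recording or HemoRecording")
}

#' Zero-phase Butterworth bandpass filter
#'
#' 6th-order (by default) Butterworth bandpass applied forward and backward,
#' so the net filter has zero phase lag and the squared magnitude response
#' of the one-pass design. Edges are handled by odd-reflection padding of
#' three filter orders plus steady-state initial conditions.
#'
#' @param rec a [Recording-class] or [HemoRecording-class].
#' @param low,high passband edges in Hz (`0 < low < high < rate/2`).
#' @param order filter order of the one-pass design.
#' @return the filtered object, same class, sample count preserved.
#' @export
bandpassZeroPhase <- function(rec, low = 1, high = 40, order = 6) {
  rate <- samplingRate(rec)
  if (!(low > 0 && low < high && high < rate / 2))
    stop("band [", low, ", ", high, "] Hz must satisfy 0 < low < high < ",
         rate / 2, " Hz (Nyquist)")
  bf <- signal::butter(order, c(low, high) / (rate / 2), type = "pass")
  .map_signal(rec, function(x) .filtfilt(bf$b, bf$a, x))
}

#' Zero-phase Butterworth low-pass filter
#'
#' @param rec a [Recording-class] or [HemoRecording-class].
#' @param cutoff cutoff frequency in Hz (`0 < cutoff < rate/2`).
#' @param order filter order of the one-pass design.
#' @return the filtered object, same class, sample count preserved.
#' @export
lowpassZeroPhase <- function(rec, cutoff = 0.2, order = 6) {
  rate <- samplingRate(rec)
  if (!(cutoff > 0 && cutoff < rate / 2))
    stop("cutoff ", cutoff, " Hz must lie in (0, ", rate / 2, ") Hz")
  bf <- signal::butter(order, cutoff / (rate / 2), type = "low")
  .map_signal(rec, function(x) .filtfilt(bf$b, bf$a, x))
}

#' Closed-form magnitude response of the zero-phase Butterworth filters
#'
#' Exact magnitude of the digital Butterworth designed by bilinear transform,
#' evaluated through the analog prototype at prewarped frequencies and
#' squared for the two-pass (forward-backward) application. Used as an
#' independent check on the time-domain filtering.
#'
#' @param f frequency in Hz at which to evaluate.
#' @param rate sampling rate in Hz.
#' @param low,high band edges (bandpass) — give `low = NULL` for low-pass.
#' @param cutoff low-pass cutoff in Hz.
#' @param order one-pass filter order.
#' @return magnitude gain (linear, two-pass).
#' @export
butterMagnitudeTwoPass <- function(f, rate, low = NULL, high = NULL,
                                   cutoff = NULL, order = 6) {
  w <- tan(pi * f / rate)
  if (!is.null(low)) {
    wl <- tan(pi * low / rate); wh <- tan(pi * high / rate)
    W <- (w^2 - wl * wh) / (w * (wh - wl))
  } else {
    W <- w / tan(pi * cutoff / rate)
  }
  (1 / (1 + W^(2 * order)))      # |H|^2 of one pass = two-pass gain
}

# Kaiser-window FIR low-pass (type I), ~70 dB stopband
.antialias_fir <- function(rate, target) {
  fpass <- 0.85 * target / 2
  fstop <- target / 2
  dw <- 2 * pi * (fstop - fpass) / rate
  A <- 70
  beta <- 0.1102 * (A - 8.7)
  N <- ceiling((A - 7.95) / (2.285 * dw))
  if (N %% 2L == 1L) N <- N + 1L               # even order, odd taps
  wc <- (fpass + fstop) / 2
  signal::fir1(N, wc / (rate / 2), type = "low",
               window = signal::kaiser(N + 1L, beta))
}

.fir_zero_phase <- function(h, x) {
  L <- length(h)
  P <- L
  n <- length(x)
  xp <- c(2 * x[1L] - x[(P + 1L):2L], x, 2 * x[n] - x[(n - 1L):(n - P)])
  # FFT convolution, padded to a 2-3-5-smooth length
  m <- length(xp) + L - 1L
  N <- stats::nextn(m, c(2L, 3L, 5L))
  X <- stats::fft(c(xp, numeric(N - length(xp))))
  Hf <- stats::fft(c(h, numeric(N - L)))
  y <- Re(stats::fft(X * Hf, inverse = TRUE)) / N
  off <- P + (L - 1L) %/% 2L
  y[(off + 1L):(off + n)]
}

#' Resample a recording to a lower rate
#'
#' Applies a Kaiser-window FIR anti-aliasing low-pass (passband up to 85% of
#' the new Nyquist frequency, ~70 dB stopband attenuation at and above the
#' new Nyquist) with zero phase, then evaluates the filtered signal on the
#' new sample grid (exact decimation for integer rate ratios, cubic spline
#' interpolation otherwise). Upsampling is not supported.
#'
#' @param rec a [Recording-class] or [HemoRecording-class].
#' @param targetRate new sampling rate in Hz (`<=` current rate).
#' @return resampled object; duration preserved within one output sample.
#' @export
resampleRecording <- function(rec, targetRate) {
  rate <- samplingRate(rec)
  if (targetRate > rate)
    stop("upsampling (", rate, " -> ", targetRate, " Hz) is not supported")
  if (isTRUE(all.equal(targetRate, rate))) return(rec)
  h <- .antialias_fir(rate, targetRate)
  q <- rate / targetRate
  int_q <- abs(q - round(q)) < 1e-9
  out <- .map_signal(rec, function(x) {
    n <- length(x)
    nout <- floor(n * targetRate / rate)
    y <- .fir_zero_phase(h, x)
    if (int_q) {
      y[seq.int(1L, by = as.integer(round(q)), length.out = nout)]
    } else {
      told <- (seq_len(n) - 1L) / rate
      tnew <- (seq_len(nout) - 1L) / targetRate
      stats::spline(told, y, xout = tnew)$y
    }
  })
  if (is(out, "Recording")) out@rate <- targetRate else out@rate <- targetRate
  out
}

#' Modified Beer-Lambert conversion from optical density to hemoglobin
#'
#' Converts paired two-wavelength optical-density channels into oxygenated
#' and deoxygenated hemoglobin concentration changes. Per site and sample,
#' `[dHbO; dHbR] = (E * d * DPF)^-1 [dOD_l1; dOD_l2]`, where `E` is the
#' 2 x 2 extinction matrix (rows wavelengths, columns HbO/HbR, in
#' umol^-1 L cm^-1), `d` the source-detector distance (cm) and `DPF` the
#' differential pathlength factor per wavelength. Optical densities are
#' referenced to the per-channel temporal mean before conversion, so the
#' output is a concentration *change* in umol/L.
#'
#' @param od a [Recording-class] with modality `"fnirs_od"`.
#' @param extinction 2 x 2 extinction matrix; default looked up from the
#'   bundled table via [extinctionMatrix()] for the channel wavelengths.
#' @param dpf differential pathlength factor(s), recycled to 2.
#' @param distance source-detector distance in cm; default taken from the
#'   channel metadata.
#' @return a [HemoRecording-class] (sites x samples, umol/L).
#' @export
mbllConvert <- function(od, extinction = NULL, dpf = 6, distance = NULL) {
  stopifnot(is(od, "Recording"))
  if (od@modality != "fnirs_od")
    stop("mbllConvert expects modality 'fnirs_od', got ", od@modality)
  ch <- od@channels
  sites <- unique(.site_of_label(ch$label))
  wls <- sort(unique(ch$wavelength))
  if (length(wls) != 2L)
    stop("need exactly two wavelengths, found ", length(wls))
  if (is.null(extinction)) extinction <- extinctionMatrix(wls)
  dpf <- rep_len(dpf, 2L)

  n <- ncol(od@data)
  hbo <- matrix(0, length(sites), n)
  hbr <- matrix(0, length(sites), n)
  dists <- numeric(length(sites))
  for (s in seq_along(sites)) {
    rows <- which(.site_of_label(ch$label) == sites[s])
    rows <- rows[order(ch$wavelength[rows])]
    if (length(rows) != 2L)
      stop("site ", sites[s], " does not have exactly two wavelengths")
    d <- distance
    if (is.null(d)) d <- ch$sourceDetectorDistance[rows[1L]]
    if (is.na(d) || d <= 0)
      stop("no valid source-detector distance for site ", sites[s],
           "; supply 'distance'")
    M <- diag(d * dpf) %*% extinction
    kappa <- kappa(M, exact = TRUE)
    if (!is.finite(kappa) || kappa > 1e12)
      stop("extinction system is numerically singular (condition number ",
           format(kappa, digits = 3), ")")
    dod <- od@data[rows, , drop = FALSE]
    dod <- dod - rowMeans(dod)
    hb <- solve(M, dod)
    hbo[s, ] <- hb[1L, ]
    hbr[s, ] <- hb[2L, ]
    dists[s] <- d
  }
  new("HemoRecording", hbo = hbo, hbr = hbr, rate = od@rate,
      sites = data.frame(label = sites, sourceDetectorDistance = dists,
                         stringsAsFactors = FALSE),
      startTime = od@startTime)
}

#' Label task and rest segments from protocol schedules
#'
#' Each task block is labeled with its n-back condition and each rest period
#' with `rest`; instruction periods are excluded. Bounds are in seconds, so
#' one segment table serves both modalities.
#'
#' @param schedules an [EventSchedule-class] or list of them.
#' @return `data.frame` with columns `start`, `end` (s), `class`, `session`,
#'   `series`.
#' @export
labelSegments <- function(schedules) {
  if (is(schedules, "EventSchedule")) schedules <- list(schedules)
  if (!length(schedules))
    return(data.frame(start = numeric(), end = numeric(),
                      class = character(), session = integer(),
                      series = integer(), stringsAsFactors = FALSE))
  for (s in schedules) validObject(s)
  .truth_table(schedules)
}

#' Extract the sample window of a segment from a recording
#'
#' Half-open interval `[start, end)` converted to 0-based sample indices by
#' `floor(time * rate)`.
#'
#' @param rec a [Recording-class].
#' @param start,end segment bounds in seconds.
#' @return a [Recording-class] restricted to the segment.
#' @export
cropRecording <- function(rec, start, end) {
  i0 <- floor(start * rec@rate)
  i1 <- floor(end * rec@rate)
  i1 <- min(i1, ncol(rec@data))
  out <- rec
  out@data <- rec@data[, (i0 + 1L):i1, drop = FALSE]
  out@startTime <- start
  out
}

#' Reject artifact windows by robust z-score
#'
#' Channel statistics (median and MAD) are pooled over all windows; a window
#' is rejected when its peak absolute robust z-score exceeds `zMax`.
#'
#' @param windows list of channels x samples matrices.
#' @param zMax rejection threshold (default 5; `Inf` keeps everything).
#' @return list with `windows` (kept), `kept`, `rejected` (indices) and
#'   `log` (`data.frame` of per-window peak z and decision).
#' @export
rejectOutliers <- function(windows, zMax = 5) {
  if (!length(windows))
    return(list(windows = windows, kept = integer(), rejected = integer(),
                log = data.frame()))
  pooled <- do.call(cbind, windows)
  med <- apply(pooled, 1L, stats::median)
  mad <- apply(pooled, 1L, stats::mad)
  mad[mad < .Machine$double.eps] <- .Machine$double.eps
  peak <- vapply(windows, function(w)
    max(abs((w - med) / mad)), numeric(1))
  rejected <- which(peak > zMax)
  if (length(rejected) == length(windows))
    stop("all ", length(windows), " windows rejected at zMax = ", zMax,
         "; review the threshold")
  kept <- setdiff(seq_along(windows), rejected)
  list(windows = windows[kept], kept = kept, rejected = rejected,
       log = data.frame(window = seq_along(windows), peak_z = peak,
                        rejected = seq_along(windows) %in% rejected))
}

#' Per-channel z-scoring with training-fold statistics
#'
#' Computes per-channel mean and standard deviation from the training
#' windows only and applies `(x - mean) / sd` to any further windows, so no
#' test-fold statistics ever leak into the transform.
#'
#' @param windows list of channels x samples matrices to transform.
#' @param stats optional statistics from a previous call (training fold);
#'   when `NULL`, statistics are computed from `windows` themselves.
#' @return list with `windows` (transformed) and `stats`
#'   (list `mean`, `sd` per channel).
#' @export
normalizeWindows <- function(windows, stats = NULL) {
  if (is.null(stats)) {
    pooled <- do.call(cbind, windows)
    mu <- rowMeans(pooled)
    sdv <- apply(pooled, 1L, stats::sd)
    zero <- which(sdv < .Machine$double.eps)
    if (length(zero))
      stop("zero-variance channel(s): ", paste(zero, collapse = ", "))
    stats <- list(mean = mu, sd = sdv)
  }
  out <- lapply(windows, function(w) (w - stats$mean) / stats$sd)
  list(windows = out, stats = stats)
}
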