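#' Read an EEG recording from an EDF/EDF+ file
#'
#' Reads the signal channels into a [Recording-class] with modality `"eeg"`.
#' If the file carries an `EDF Annotations` signal, annotations whose text
#' matches the protocol label set (`0-back`, `2-back`, `3-back`, `rest`,
#' `instruction`) are returned as an [EventSchedule-class].
#'
#' The reader never resamples or filters: sample counts in equal sample
#' counts out, up to the 16-bit quantization inherent to EDF.
#'
#' @param path path to an EDF file.
#' @return list with elements `recording` ([Recording-class]) and `events`
#'   ([EventSchedule-class] or `NULL`).
#' @examples
#' rec <- Recording(matrix(sin(1:2000 / 10), 2, byrow = TRUE), 100,
#'                  c("Fz", "Pz"), "eeg")
#' f <- tempfile(fileext = ".edf")
#' writeRecording(rec, f, format = "edf")
#' readEEGEDF(f)$recording
#' @export
readEEGEDF <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  .read_edf(path)
}

#' Read an fNIRS recording from a SNIRF file
#'
#' Reads a continuous-wave SNIRF file into a [Recording-class] with modality
#' `"fnirs_od"`. Raw-amplitude channels (SNIRF dataType 1) are converted to
#' optical density as `-log(I / I0)` with `I0` the per-channel temporal mean;
#' processed `dOD` channels are taken as-is. Wavelengths and source-detector
#' distances are populated per channel from the probe geometry.
#'
#' @param path path to a SNIRF (HDF5) file.
#' @param distance fallback source-detector distance in cm, used when the
#'   file carries no probe geometry.
#' @return a [Recording-class], modality `"fnirs_od"`.
#' @export
readFNIRSSNIRF <- function(path, distance = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  .read_snirf(path, distance)
}

#' Read a protocol event table from delimited text
#'
#' Expects a header line and columns `onset`, `duration`, `label`
#' (tab-, comma- or whitespace-delimited). Labels must come from the closed
#' set `0-back`, `2-back`, `3-back`, `rest`, `instruction`.
#'
#' @param path path to the delimited text file.
#' @param sessionId,seriesId provenance indices attached to the schedule.
#' @return a validated [EventSchedule-class].
#' @export
readEventsTable <- function(path, sessionId = 1L, seriesId = 1L) {
  if (!file.exists(path)) stop("no such file: ", path)
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header)) "\t" else if (grepl(",", header)) "," else ""
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE)
  if (!all(c("onset", "duration", "label") %in% names(tab)))
    stop("event table must have columns onset, duration, label")
  EventSchedule(tab$onset, tab$duration, tab$label,
                sessionId = sessionId, seriesId = seriesId)
}

#' Write an event table as tab-delimited text
#'
#' @param schedule an [EventSchedule-class] (or list of them; events are
#'   concatenated).
#' @param path output path.
#' @return the path, invisibly.
#' @export
writeEventsTable <- function(schedule, path) {
  if (is(schedule, "EventSchedule")) schedule <- list(schedule)
  ev <- do.call(rbind, lapply(schedule, events))
  utils::write.table(ev, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a recording to disk
#'
#' Supported formats: `"edf"` (EEG only; 16-bit quantized), `"snirf"`
#' (fNIRS optical density only) and `"container"`, a lossless native
#' serialization for intermediate results that round-trips bit-identically.
#'
#' @param rec a [Recording-class].
#' @param path output path.
#' @param format one of `"edf"`, `"snirf"`, `"container"`.
#' @param events optional [EventSchedule-class] stored alongside
#'   (EDF annotations / container slot).
#' @return the path, invisibly.
#' @export
writeRecording <- function(rec, path, format = c("container", "edf", "snirf"),
                           events = NULL) {
  format <- match.arg(format)
  validObject(rec)
  if (format == "edf" && rec@modality != "eeg")
    stop("EDF export is only supported for modality 'eeg', not ", rec@modality)
  if (format == "snirf" && rec@modality != "fnirs_od")
    stop("SNIRF export is only supported for modality 'fnirs_od', not ",
         rec@modality)
  switch(format,
         edf = .write_edf(rec, path, events = events),
         snirf = .write_snirf(rec, path),
         container = saveRDS(list(format = "neurorp-container", version = 1L,
                                  data = rec@data, rate = rec@rate,
                                  channels = rec@channels,
                                  modality = rec@modality,
                                  startTime = rec@startTime,
                                  events = if (is.null(events)) NULL
                                           else events(events)),
                             path))
  invisible(path)
}

#' Read a recording from the lossless container format
#'
#' @param path path written by [writeRecording()] with `format = "container"`.
#' @return list with `recording` and `events` (or `NULL`).
#' @export
readContainer <- function(path) {
  obj <- readRDS(path)
  if (!identical(obj$format, "neurorp-container"))
    stop("not a neurorp container file: ", path)
  ev <- if (is.null(obj$events)) NULL else
    EventSchedule(obj$events$onset, obj$events$duration, obj$events$label)
  list(recording = Recording(obj$data, obj$rate, obj$channels, obj$modality,
                             obj$startTime),
       events = ev)
}

# ---- SNIRF ----------------------------------------------------------------

.site_of_label <- function(label) sub(":[0-9.]+$", "", label)

.write_snirf <- function(rec, path) {
  ch <- rec@channels
  sites <- unique(.site_of_label(ch$label))
  wls <- sort(unique(ch$wavelength))
  if (file.exists(path)) unlink(path)
  rhdf5::h5createFile(path)
  on.exit(rhdf5::h5closeAll())
  rhdf5::h5write("1.0", path, "formatVersion")
  rhdf5::h5createGroup(path, "nirs")
  rhdf5::h5createGroup(path, "nirs/data1")
  n <- ncol(rec@data)
  rhdf5::h5write(t(rec@data), path, "nirs/data1/dataTimeSeries")
  rhdf5::h5write(rec@startTime + (0:(n - 1)) / rec@rate, path, "nirs/data1/time")
  for (i in seq_len(nrow(ch))) {
    g <- sprintf("nirs/data1/measurementList%d", i)
    rhdf5::h5createGroup(path, g)
    si <- match(.site_of_label(ch$label[i]), sites)
    rhdf5::h5write(as.integer(si), path, paste0(g, "/sourceIndex"))
    rhdf5::h5write(as.integer(si), path, paste0(g, "/detectorIndex"))
    rhdf5::h5write(match(ch$wavelength[i], wls), path,
                   paste0(g, "/wavelengthIndex"))
    rhdf5::h5write(99999L, path, paste0(g, "/dataType"))
    rhdf5::h5write("dOD", path, paste0(g, "/dataTypeLabel"))
  }
  rhdf5::h5createGroup(path, "nirs/probe")
  rhdf5::h5write(wls, path, "nirs/probe/wavelengths")
  dist <- ch$sourceDetectorDistance[match(sites, .site_of_label(ch$label))]
  src <- cbind(0, seq_along(sites) * 10, 0)   # sites spread along y (cm)
  det <- cbind(dist, seq_along(sites) * 10, 0)
  rhdf5::h5write(src, path, "nirs/probe/sourcePos3D")
  rhdf5::h5write(det, path, "nirs/probe/detectorPos3D")
  invisible(path)
}

.h5_try <- function(path, name) {
  ls <- rhdf5::h5ls(path)
  full <- file.path(ls$group, ls$name)
  full <- sub("^//", "/", full)
  if (paste0("/", name) %in% full || name %in% sub("^/", "", full))
    rhdf5::h5read(path, name)
  else NULL
}

.read_snirf <- function(path, distance = NULL) {
  on.exit(rhdf5::h5closeAll())
  ls <- rhdf5::h5ls(path)
  entries <- sub("^/+", "", file.path(ls$group, ls$name))
  if (!"nirs/data1/dataTimeSeries" %in% entries)
    stop("not a SNIRF file (missing /nirs/data1/dataTimeSeries): ", path)
  ts <- rhdf5::h5read(path, "nirs/data1/dataTimeSeries")
  tm <- as.numeric(rhdf5::h5read(path, "nirs/data1/time"))
  x <- t(ts)                      # channels x samples
  if (length(tm) == ncol(ts) && length(tm) != nrow(ts)) x <- ts
  rate <- 1 / stats::median(diff(tm))

  ml_names <- grep("^nirs/data1/measurementList[0-9]+$", entries, value = TRUE)
  ord <- order(as.integer(sub(".*measurementList", "", ml_names)))
  ml_names <- ml_names[ord]
  if (length(ml_names) != nrow(x))
    stop("SNIRF measurementList count (", length(ml_names),
         ") does not match channel count (", nrow(x), ")")
  wls <- as.numeric(rhdf5::h5read(path, "nirs/probe/wavelengths"))
  if (length(wls) < 2)
    stop("SNIRF probe carries ", length(wls),
         " wavelength(s); the Beer-Lambert conversion needs at least 2")

  src <- .h5_try(path, "nirs/probe/sourcePos3D")
  det <- .h5_try(path, "nirs/probe/detectorPos3D")
  if (is.null(src)) src <- .h5_try(path, "nirs/probe/sourcePos2D")
  if (is.null(det)) det <- .h5_try(path, "nirs/probe/detectorPos2D")
  .fix_pos <- function(p, n) {
    if (is.null(p)) return(NULL)
    p <- as.matrix(p)
    if (nrow(p) != n && ncol(p) == n) p <- t(p)
    p
  }

  meta <- lapply(ml_names, function(g) {
    list(si = as.integer(rhdf5::h5read(path, paste0(g, "/sourceIndex"))),
         di = as.integer(rhdf5::h5read(path, paste0(g, "/detectorIndex"))),
         wi = as.integer(rhdf5::h5read(path, paste0(g, "/wavelengthIndex"))),
         dt = as.integer(rhdf5::h5read(path, paste0(g, "/dataType"))))
  })
  nsrc <- max(vapply(meta, `[[`, 1L, "si"))
  ndet <- max(vapply(meta, `[[`, 1L, "di"))
  src <- .fix_pos(src, nsrc); det <- .fix_pos(det, ndet)

  dists <- vapply(meta, function(m) {
    if (!is.null(src) && !is.null(det))
      sqrt(sum((src[m$si, ] - det[m$di, ])^2))
    else NA_real_
  }, numeric(1))
  if (anyNA(dists)) {
    if (is.null(distance))
      stop("SNIRF file has no probe geometry; supply the source-detector ",
           "distance explicitly via the 'distance' argument")
    dists[is.na(dists)] <- distance
  }

  labs <- vapply(seq_along(meta), function(i)
    sprintf("S%d-D%d:%g", meta[[i]]$si, meta[[i]]$di, wls[meta[[i]]$wi]),
    character(1))
  chinfo <- channelInfo(labs, role = "source-detector pair",
                        wavelength = wls[vapply(meta, `[[`, 1L, "wi")],
                        sourceDetectorDistance = dists)

  is_amp <- vapply(meta, function(m) m$dt == 1L, logical(1))
  if (any(is_amp)) {
    for (i in which(is_amp)) {
      i0 <- mean(x[i, ])
      if (i0 <= 0) stop("non-positive mean amplitude on channel ", labs[i])
      x[i, ] <- -log(x[i, ] / i0)
    }
  }
  Recording(x, rate = rate, channels = chinfo, modality = "fnirs_od",
            startTime = tm[1])
}
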