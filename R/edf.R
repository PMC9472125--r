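# Minimal EDF/EDF+ reader and writer.
#
# EDF stores a 256-byte ASCII header, 256 ASCII bytes per signal, then data
# records of little-endian int16 samples with per-signal linear scaling
# between digital and physical ranges. Values therefore round-trip only up
# to 16-bit quantization of the physical range. An optional "EDF Annotations"
# signal carries timestamped text annotations (TALs), which the reader maps
# onto the protocol event labels when possible.

.edf_pad <- function(x, width) {
  x <- as.character(x)
  if (nchar(x) > width) stop("EDF header field too long: ", x)
  formatC(x, width = -width)
}

.edf_num <- function(x, width) {
  s <- formatC(x, format = "g", digits = width - 1)
  if (nchar(s) > width) s <- substr(s, 1, width)
  .edf_pad(s, width)
}

# shortest record duration (integer seconds) making samples-per-record integral
.edf_record_split <- function(rate) {
  for (q in 1:1000) {
    if (abs(rate * q - round(rate * q)) < 1e-6) {
      return(list(dur = q, spr = as.integer(round(rate * q))))
    }
  }
  stop("sampling rate ", rate, " cannot be represented in an EDF record grid")
}

.write_edf <- function(rec, path, events = NULL) {
  x <- rec@data
  nsig <- nrow(x)
  n <- ncol(x)
  split <- .edf_record_split(rec@rate)
  nrec <- as.integer(ceiling(n / split$spr))
  npad <- nrec * split$spr - n

  pmin <- apply(x, 1, min); pmax <- apply(x, 1, max)
  flat <- pmax - pmin < .Machine$double.eps
  pmin[flat] <- pmin[flat] - 1; pmax[flat] <- pmax[flat] + 1
  dmin <- -32768; dmax <- 32767

  ann <- NULL
  if (!is.null(events) && nrow(events@events)) {
    ann <- c(charToRaw("+0\x14\x14"), as.raw(0))
    for (i in seq_len(nrow(events@events))) {
      ev <- events@events[i, ]
      ann <- c(ann, charToRaw(sprintf("+%g\x15%g\x14%s\x14", ev$onset,
                                      ev$duration, ev$label)), as.raw(0))
    }
    if (length(ann) %% 2L) ann <- c(ann, as.raw(0))
  }
  n_ann <- if (is.null(ann)) 0L else 1L
  ann_spr <- if (n_ann) as.integer(max(16L, length(ann) / 2L)) else 0L

  con <- file(path, "wb")
  on.exit(close(con))
  wr <- function(s) writeChar(s, con, nchar(s), eos = NULL)
  total_sig <- nsig + n_ann
  wr(.edf_pad("0", 8))
  wr(.edf_pad("X X X X", 80))
  wr(.edf_pad("Startdate X X X X", 80))
  wr(.edf_pad("01.01.00", 8))
  wr(.edf_pad("00.00.00", 8))
  wr(.edf_pad(256L * (1L + total_sig), 8))
  wr(.edf_pad(sprintf("%sNSAMP:%d", if (n_ann) "EDF+C " else "", n), 44))
  wr(.edf_pad(nrec, 8))
  wr(.edf_num(split$dur, 8))
  wr(.edf_pad(total_sig, 4))

  labels <- c(rec@channels$label, if (n_ann) "EDF Annotations")
  for (lab in labels) wr(.edf_pad(lab, 16))
  for (i in seq_len(total_sig)) wr(.edf_pad("", 80))             # transducer
  dims <- c(rep(if (rec@modality == "eeg") "uV" else "", nsig), if (n_ann) "")
  for (d in dims) wr(.edf_pad(d, 8))
  for (v in c(pmin, if (n_ann) -1)) wr(.edf_num(v, 8))
  for (v in c(pmax, if (n_ann) 1)) wr(.edf_num(v, 8))
  for (i in seq_len(total_sig)) wr(.edf_pad(dmin, 8))
  for (i in seq_len(total_sig)) wr(.edf_pad(dmax, 8))
  for (i in seq_len(total_sig)) wr(.edf_pad("", 80))             # prefiltering
  for (s in c(rep(split$spr, nsig), if (n_ann) ann_spr)) wr(.edf_pad(s, 8))
  for (i in seq_len(total_sig)) wr(.edf_pad("", 32))

  scale <- (dmax - dmin) / (pmax - pmin)
  if (npad) x <- cbind(x, x[, rep.int(n, npad), drop = FALSE])
  for (r in seq_len(nrec)) {
    idx <- ((r - 1L) * split$spr + 1L):(r * split$spr)
    dig <- round((x[, idx, drop = FALSE] - pmin) * scale + dmin)
    writeBin(as.integer(t(dig)), con, size = 2L, endian = "little")
    if (n_ann) {
      chunk <- raw(2L * ann_spr)
      if (r == 1L) chunk[seq_along(ann)] <- ann
      else {
        ts <- charToRaw(sprintf("+%g\x14\x14", (r - 1L) * split$dur))
        chunk[seq_along(ts)] <- ts
      }
      writeBin(chunk, con)
    }
  }
  invisible(path)
}

.edf_parse_tals <- function(bytes) {
  # TALs are NUL-separated; each is "onset[<21>duration]<20>label<20>..."
  breaks <- which(bytes == as.raw(0))
  starts <- c(1L, breaks + 1L)
  ends <- c(breaks - 1L, length(bytes))
  tals <- character()
  for (i in seq_along(starts)) {
    if (starts[i] <= ends[i])
      tals <- c(tals, rawToChar(bytes[starts[i]:ends[i]]))
  }
  out <- list()
  for (tal in tals) {
    parts <- strsplit(tal, "\x14", fixed = TRUE)[[1]]
    if (!length(parts)) next
    head <- strsplit(parts[1], "\x15", fixed = TRUE)[[1]]
    onset <- suppressWarnings(as.numeric(head[1]))
    dur <- if (length(head) > 1) suppressWarnings(as.numeric(head[2])) else 0
    labs <- parts[-1]
    for (lab in labs[nzchar(labs)]) {
      out[[length(out) + 1L]] <- data.frame(onset = onset, duration = dur,
                                            label = lab)
    }
  }
  if (length(out)) do.call(rbind, out) else NULL
}

.read_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(width) trimws(readChar(con, width, useBytes = TRUE))
  version <- rd(8)
  if (!identical(version, "0"))
    stop("not an EDF file: header field 'version' is ", sQuote(version))
  rd(80); rd(80); rd(8); rd(8)
  header_bytes <- as.integer(rd(8))
  reserved <- rd(44)
  nrec <- as.integer(rd(8))
  recdur <- as.numeric(rd(8))
  nsig <- as.integer(rd(4))
  if (is.na(nsig) || nsig < 1)
    stop("malformed EDF header: field 'number of signals' is not a count")
  fld <- function(width) vapply(seq_len(nsig), function(i) rd(width), character(1))
  labels <- fld(16); fld(80); fld(8)
  pmin <- as.numeric(fld(8)); pmax <- as.numeric(fld(8))
  dmin <- as.numeric(fld(8)); dmax <- as.numeric(fld(8))
  fld(80)
  spr <- as.integer(fld(8)); fld(32)
  if (any(is.na(pmin) | is.na(pmax) | is.na(spr)))
    stop("malformed EDF header: unparseable physical range or samples-per-record")

  is_ann <- labels == "EDF Annotations"
  sig_idx <- which(!is_ann)
  if (anyDuplicated(labels[sig_idx]))
    stop("EDF file has duplicate channel labels")
  data <- vector("list", nsig)
  for (i in seq_len(nsig)) data[[i]] <- vector("list", nrec)
  for (r in seq_len(nrec)) {
    for (i in seq_len(nsig)) {
      if (is_ann[i]) {
        data[[i]][[r]] <- readBin(con, "raw", 2L * spr[i])
      } else {
        data[[i]][[r]] <- readBin(con, "integer", spr[i], size = 2L,
                                  signed = TRUE, endian = "little")
      }
    }
  }

  nsamp_hint <- if (grepl("NSAMP:", reserved)) {
    as.integer(sub(".*NSAMP:([0-9]+).*", "\\1", reserved))
  } else NA_integer_

  mats <- lapply(sig_idx, function(i) {
    dig <- unlist(data[[i]], use.names = FALSE)
    pmin[i] + (dig - dmin[i]) * (pmax[i] - pmin[i]) / (dmax[i] - dmin[i])
  })
  x <- do.call(rbind, mats)
  if (!is.na(nsamp_hint) && nsamp_hint <= ncol(x)) x <- x[, seq_len(nsamp_hint), drop = FALSE]
  rate <- spr[sig_idx[1]] / recdur

  sched <- NULL
  if (any(is_ann)) {
    ann <- .edf_parse_tals(unlist(data[[which(is_ann)[1]]], use.names = FALSE))
    if (!is.null(ann)) {
      keep <- ann$label %in% .EVENT_LABELS
      if (any(!keep))
        warning("dropping ", sum(!keep), " EDF annotation(s) outside the protocol label set")
      ann <- ann[keep, , drop = FALSE]
      ann <- ann[order(ann$onset), , drop = FALSE]
      if (nrow(ann))
        sched <- EventSchedule(ann$onset, ann$duration, ann$label)
    }
  }
  list(recording = Recording(x, rate = rate, channels = labels[sig_idx],
                             modality = "eeg"),
       events = sched)
}
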