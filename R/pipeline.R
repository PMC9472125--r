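# End-to-end glue: pre-process both modality streams, convert labeled
# segments to paired recurrence-plot sequences, and run the desk-scale
# cross-validated workload study on synthetic data.

#' Pre-process a raw EEG recording
#'
#' Downsamples to `targetRate` (default 200 Hz) and applies the zero-phase
#' 6th-order Butterworth bandpass (1-40 Hz by default).
#'
#' @param rec raw EEG [Recording-class].
#' @param targetRate output rate (Hz).
#' @param low,high,order bandpass parameters.
#' @return filtered, downsampled [Recording-class].
#' @export
preprocessEEG <- function(rec, targetRate = 200, low = 1, high = 40,
                          order = 6) {
  rec <- resampleRecording(rec, targetRate)
  bandpassZeroPhase(rec, low = low, high = high, order = order)
}

#' Pre-process a raw fNIRS optical-density recording
#'
#' Converts optical density to HbO/HbR concentration changes via the
#' modified Beer-Lambert law, downsamples to `targetRate` (default 10 Hz),
#' then applies the zero-phase 6th-order Butterworth low-pass (0.2 Hz by
#' default) to suppress physiological oscillations above the hemodynamic
#' band.
#'
#' @param od fNIRS [Recording-class], modality `"fnirs_od"`.
#' @param targetRate output rate (Hz).
#' @param cutoff,order low-pass parameters.
#' @param dpf,distance,extinction Beer-Lambert parameters
#'   (see [mbllConvert()]).
#' @return a [HemoRecording-class].
#' @export
preprocessFNIRS <- function(od, targetRate = 10, cutoff = 0.2, order = 6,
                            dpf = 6, distance = NULL, extinction = NULL) {
  hemo <- mbllConvert(od, extinction = extinction, dpf = dpf,
                      distance = distance)
  hemo <- resampleRecording(hemo, targetRate)
  lowpassZeroPhase(hemo, cutoff = cutoff, order = order)
}

.crop_hemo <- function(hemo, start, end) {
  i0 <- floor(start * hemo@rate); i1 <- floor(end * hemo@rate)
  i1 <- min(i1, ncol(hemo@hbo))
  rbind(hemo@hbo[, (i0 + 1L):i1, drop = FALSE],
        hemo@hbr[, (i0 + 1L):i1, drop = FALSE])
}

# z-score per channel, stride, embed, threshold: one window -> one plot
.window_rp <- function(win, ecfg, rcfg) {
  win <- win[, seq.int(1L, ncol(win), by = rcfg@step), drop = FALSE]
  mu <- rowMeans(win)
  sdv <- apply(win, 1L, stats::sd)
  sdv[sdv < .Machine$double.eps] <- 1
  win <- (win - mu) / sdv
  recurrenceMatrix(distanceMatrix(embedSeries(win, ecfg)), rcfg)
}

#' Build the paired recurrence-plot dataset of one subject
#'
#' For every labeled segment, both modality streams are cut into the shared
#' 5 s / 20% overlap window grid, artifact windows are rejected by pooled
#' robust z-score (a window rejected in either modality removes the pair),
#' each retained window becomes one recurrence plot per modality, and
#' consecutive runs of `tSeq` windows form one classifier sample.
#'
#' @param eeg pre-processed EEG [Recording-class].
#' @param hemo pre-processed [HemoRecording-class] (HbO and HbR stacked as
#'   channels for the recurrence plots).
#' @param segments labeled segment table from [labelSegments()].
#' @param ecfg an [EmbeddingConfig-class].
#' @param rcfgEEG,rcfgFNIRS per-modality [RPConfig-class]; defaults keep the
#'   EEG stride at 10 (100 x 100 plots at 200 Hz) and the fNIRS stride at 1
#'   (50 x 50 plots at 10 Hz).
#' @param tSeq windows per classifier sample.
#' @param zMax outlier-rejection threshold ([rejectOutliers()]); `Inf`
#'   disables rejection.
#' @return list with `eeg`, `fnirs`, `hybrid` (sample lists for
#'   [trainModel()]), `labels`, and `rejected` (count of dropped windows).
#' @export
buildRPDataset <- function(eeg, hemo, segments, ecfg = EmbeddingConfig(),
                           rcfgEEG = RPConfig(step = 10),
                           rcfgFNIRS = RPConfig(step = 1),
                           tSeq = 4L, zMax = 5) {
  stopifnot(nrow(segments) > 0)
  seg_eeg <- list(); seg_fnirs <- list(); seg_label <- character()
  for (i in seq_len(nrow(segments))) {
    e <- cropRecording(eeg, segments$start[i], segments$end[i])
    fx <- .crop_hemo(hemo, segments$start[i], segments$end[i])
    ge <- windowGrid(ncol(e@data), eeg@rate, rcfgEEG)
    gf <- windowGrid(ncol(fx), hemo@rate, rcfgFNIRS)
    nw <- min(ge$count, gf$count)
    if (nw < 1L) next
    seg_eeg[[length(seg_eeg) + 1L]] <- lapply(seq_len(nw), function(w) {
      i0 <- (w - 1L) * ge$advance
      e@data[, (i0 + 1L):(i0 + ge$width), drop = FALSE]
    })
    seg_fnirs[[length(seg_fnirs) + 1L]] <- lapply(seq_len(nw), function(w) {
      i0 <- (w - 1L) * gf$advance
      fx[, (i0 + 1L):(i0 + gf$width), drop = FALSE]
    })
    seg_label <- c(seg_label, segments$class[i])
  }

  flat_e <- unlist(seg_eeg, recursive = FALSE)
  flat_f <- unlist(seg_fnirs, recursive = FALSE)
  drop_idx <- integer()
  if (is.finite(zMax)) {
    re <- rejectOutliers(flat_e, zMax)
    rf <- rejectOutliers(flat_f, zMax)
    drop_idx <- union(re$rejected, rf$rejected)
  }

  eeg_s <- list(); fnirs_s <- list(); hybrid_s <- list(); labels <- character()
  off <- 0L
  for (s in seq_along(seg_eeg)) {
    nw <- length(seg_eeg[[s]])
    keep <- setdiff(seq_len(nw), drop_idx[drop_idx > off &
                                          drop_idx <= off + nw] - off)
    rps_e <- lapply(seg_eeg[[s]][keep], .window_rp, ecfg = ecfg,
                    rcfg = rcfgEEG)
    rps_f <- lapply(seg_fnirs[[s]][keep], .window_rp, ecfg = ecfg,
                    rcfg = rcfgFNIRS)
    seqs_e <- assembleSequences(rps_e, tSeq)
    seqs_f <- assembleSequences(rps_f, tSeq)
    for (q in seq_along(seqs_e)) {
      eeg_s[[length(eeg_s) + 1L]] <- seqs_e[[q]]
      fnirs_s[[length(fnirs_s) + 1L]] <- seqs_f[[q]]
      hybrid_s[[length(hybrid_s) + 1L]] <- list(eeg = seqs_e[[q]],
                                                fnirs = seqs_f[[q]])
      labels <- c(labels, seg_label[s])
    }
    off <- off + nw
  }
  list(eeg = eeg_s, fnirs = fnirs_s, hybrid = hybrid_s, labels = labels,
       rejected = length(drop_idx))
}

#' Desk-scale synthetic workload study
#'
#' Simulates one synthetic subject, runs the full pipeline (pre-processing,
#' recurrence plots, sequence assembly) and evaluates the EEG-only,
#' fNIRS-only and hybrid classifiers by stratified k-fold cross-validation.
#'
#' @param spec a [ProtocolSpec-class] (default: one session).
#' @param profile a [SubjectProfile-class]; the default uses a strong class
#'   effect and reduced noise so the study runs at desk scale.
#' @param k folds.
#' @param seed simulation seed (subject generation).
#' @param evalSeeds one or more seeds for fold assignment and training; the
#'   same synthetic subject is re-evaluated under each.
#' @param epochs,batchSize training budget per fold.
#' @param modalities subset of `c("eeg", "fnirs", "hybrid")`.
#' @param tSeq windows per classifier sample.
#' @return list with `reports` (per modality: list of [EvalReport-class],
#'   one per evaluation seed), `median` (per-modality median accuracy over
#'   seeds, percent) and `n` (dataset sizes).
#' @export
runWorkloadStudy <- function(spec = ProtocolSpec(nSessions = 1),
                             profile = NULL, k = 5, seed = 1,
                             evalSeeds = seed, epochs = 12, batchSize = 4,
                             modalities = c("eeg", "fnirs", "hybrid"),
                             tSeq = 4L) {
  if (is.null(profile))
    profile <- SubjectProfile(seed = seed, effectSize = 3,
                              noiseLevels = .DEFAULT_NOISE * 0.3)
  sub <- simulateSubject(spec, profile)
  eeg <- preprocessEEG(sub$eeg$recording)
  hemo <- preprocessFNIRS(sub$fnirs$recording)
  segments <- labelSegments(sub$schedules)
  ds <- buildRPDataset(eeg, hemo, segments, tSeq = tSeq)

  shapes <- list(
    eeg = c(tSeq, dim(ds$eeg[[1]][[1]])),
    fnirs = c(tSeq, dim(ds$fnirs[[1]][[1]]))
  )
  reports <- list()
  for (mod in modalities) {
    spec_m <- ArchitectureSpec(hybrid = mod == "hybrid")
    shp <- switch(mod, eeg = shapes$eeg, fnirs = shapes$fnirs,
                  hybrid = list(shapes$eeg, shapes$fnirs))
    reports[[mod]] <- lapply(evalSeeds, function(s) {
      cfg <- TrainConfig(epochs = epochs, batchSize = batchSize, seed = s,
                         patience = epochs)
      rep <- kfoldCV(ds[[mod]], ds$labels, spec_m, shp, k = k, seed = s,
                     cfg = cfg)
      rep@modality <- mod
      rep
    })
    names(reports[[mod]]) <- paste0("seed", evalSeeds)
  }
  list(reports = reports,
       median = vapply(reports, function(rs)
         stats::median(vapply(rs, function(r) r@mean[["accuracy"]],
                              numeric(1))), numeric(1)),
       n = c(samples = length(ds$labels), windows_rejected = ds$rejected))
}
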