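# k-fold cross-validated evaluation and the four performance metrics.

#' Confusion matrix from true and predicted labels
#'
#' @param truth,predicted character vectors of class labels.
#' @param classes fixed class ordering (rows = true, columns = predicted).
#' @return square integer matrix of counts.
#' @export
confusionMatrix <- function(truth, predicted, classes = .CLASS_LABELS) {
  truth <- factor(as.character(truth), levels = classes)
  predicted <- factor(as.character(predicted), levels = classes)
  unclass(table(truth, predicted, dnn = NULL))
}

#' Accuracy, macro precision, macro recall and F1 of a confusion matrix
#'
#' Accuracy is the proportion of correct predictions (trace over total).
#' Precision and recall are computed one-vs-rest per class and
#' macro-averaged; the F1 score is the harmonic mean of the macro precision
#' and macro recall. A class with no predicted (or no actual) positives
#' contributes 0 to its macro average, with a warning.
#'
#' @param cm square count matrix, rows = true class, columns = predicted.
#' @return named numeric: `accuracy`, `precision`, `recall`, `f1`, in percent.
#' @examples
#' cm <- matrix(c(8, 3, 2, 7), 2, dimnames = NULL)  # rows true, cols pred
#' classificationMetrics(cm)["accuracy"]            # 75
#' @export
classificationMetrics <- function(cm) {
  cm <- as.matrix(cm)
  total <- sum(cm)
  if (total == 0) stop("empty confusion matrix")
  tp <- diag(cm)
  pred_pos <- colSums(cm)
  act_pos <- rowSums(cm)
  if (any(pred_pos == 0))
    warning("class(es) with no predicted positives contribute 0 to precision")
  if (any(act_pos == 0))
    warning("class(es) with no actual positives contribute 0 to recall")
  prec <- ifelse(pred_pos > 0, tp / pred_pos, 0)
  rec <- ifelse(act_pos > 0, tp / act_pos, 0)
  mp <- mean(prec); mr <- mean(rec)
  f1 <- if (mp + mr > 0) 2 * mp * mr / (mp + mr) else 0
  100 * c(accuracy = sum(tp) / total, precision = mp, recall = mr, f1 = f1)
}

#' Stratified fold assignment
#'
#' @param labels class label per sample.
#' @param k number of folds.
#' @param seed RNG seed.
#' @param stratified keep per-fold class proportions within one sample of
#'   the global proportions.
#' @return integer fold index (1..k) per sample.
#' @export
foldAssignment <- function(labels, k = 10, seed = 1, stratified = TRUE) {
  labels <- as.character(labels)
  n <- length(labels)
  counts <- table(labels)
  if (any(counts < k))
    stop("class(es) ", paste(names(counts)[counts < k], collapse = ", "),
         " have fewer than k = ", k, " samples; use a smaller k")
  .with_seed(seed, {
    fold <- integer(n)
    if (stratified) {
      # continuous round-robin across classes keeps per-class and total
      # fold sizes within one sample of balance
      perm <- sample.int(k)
      pos <- 0L
      for (cl in sample(names(counts))) {
        idx <- sample(which(labels == cl))
        fold[idx] <- perm[((pos + seq_along(idx) - 1L) %% k) + 1L]
        pos <- pos + length(idx)
      }
    } else {
      fold[sample.int(n)] <- rep_len(sample.int(k), n)
    }
    fold
  })
}

#' k-fold cross-validated evaluation of a recurrence-plot classifier
#'
#' Splits the samples into `k` disjoint stratified folds; for each fold a
#' model is trained from scratch on the remaining folds and evaluated on the
#' held-out fold. When `normalize = TRUE`, per-pixel image statistics (mean
#' and standard deviation over the training fold) standardize both training
#' and test samples — test folds never contribute to the statistics. The
#' fold unit is one window sequence, so overlapping windows of one sequence
#' can never straddle a fold boundary.
#'
#' @param samples list of samples (see [trainModel()]).
#' @param labels class label per sample.
#' @param spec an [ArchitectureSpec-class].
#' @param inputShapes input shape(s) per branch, as for [buildModel()].
#' @param k number of folds (default 10).
#' @param seed seed driving fold assignment and per-fold training.
#' @param stratified stratify folds by class.
#' @param cfg a [TrainConfig-class]; its seed is offset per fold.
#' @param normalize standardize images with training-fold statistics.
#' @return an [EvalReport-class].
#' @export
kfoldCV <- function(samples, labels, spec, inputShapes, k = 10, seed = 1,
                    stratified = TRUE, cfg = TrainConfig(),
                    normalize = FALSE) {
  labels <- as.character(labels)
  fold <- foldAssignment(labels, k = k, seed = seed, stratified = stratified)
  per_fold <- list()
  cms <- list()
  for (f in sort(unique(fold))) {
    tr <- which(fold != f); te <- which(fold == f)
    stopifnot(length(intersect(tr, te)) == 0L)
    strain <- samples[tr]; stest <- samples[te]
    if (normalize) {
      ns <- .image_stats(strain, spec@hybrid)
      strain <- lapply(strain, .apply_image_stats, stats = ns,
                       hybrid = spec@hybrid)
      stest <- lapply(stest, .apply_image_stats, stats = ns,
                      hybrid = spec@hybrid)
    }
    model <- buildModel(spec, inputShapes, seed = cfg@seed + f)
    fcfg <- cfg
    fcfg@seed <- cfg@seed + f
    model <- trainModel(model, strain, labels[tr], fcfg)
    pred <- predictClass(model, stest)
    cm <- confusionMatrix(labels[te], pred)
    cms[[f]] <- cm
    per_fold[[f]] <- suppressWarnings(classificationMetrics(cm))
  }
  folds <- as.data.frame(do.call(rbind, per_fold))
  folds$fold <- seq_len(nrow(folds))
  new("EvalReport", folds = folds,
      mean = colMeans(folds[, c("accuracy", "precision", "recall", "f1")]),
      confusion = cms, modality = "")
}

.image_stats <- function(samples, hybrid) {
  pool <- function(extract) {
    v <- unlist(lapply(samples, extract))
    s <- stats::sd(v)
    list(mean = mean(v), sd = if (s < .Machine$double.eps) 1 else s)
  }
  if (hybrid)
    list(eeg = pool(function(s) s$eeg), fnirs = pool(function(s) s$fnirs))
  else pool(identity)
}

.apply_image_stats <- function(sample, stats, hybrid) {
  z <- function(ims, st) lapply(ims, function(im) (im - st$mean) / st$sd)
  if (hybrid)
    list(eeg = z(sample$eeg, stats$eeg), fnirs = z(sample$fnirs, stats$fnirs))
  else z(sample, stats)
}

#' Summarize evaluation reports across subjects
#'
#' @param reports named list (modality tag -> list of [EvalReport-class],
#'   one per subject) or a flat list of reports with modality tags set.
#' @return `data.frame` with per-modality mean and max of each metric
#'   across subjects.
#' @export
summarizeReports <- function(reports) {
  if (!length(reports)) stop("need at least one report")
  if (is(reports[[1]], "EvalReport"))
    reports <- split(reports, vapply(reports, function(r) r@modality,
                                     character(1)))
  rows <- list()
  for (mod in names(reports)) {
    rs <- reports[[mod]]
    if (!length(rs)) {
      warning("no reports for modality ", mod, "; omitted")
      next
    }
    acc <- vapply(rs, function(r) r@mean[["accuracy"]], numeric(1))
    rows[[mod]] <- data.frame(
      modality = mod, subjects = length(rs),
      mean_accuracy = mean(acc), max_accuracy = max(acc),
      mean_precision = mean(vapply(rs, function(r) r@mean[["precision"]],
                                   numeric(1))),
      mean_recall = mean(vapply(rs, function(r) r@mean[["recall"]],
                                numeric(1))),
      mean_f1 = mean(vapply(rs, function(r) r@mean[["f1"]], numeric(1))))
  }
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}
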