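# Time-distributed CNN-LSTM for recurrence-plot sequence classification.
#
# Each temporal slice (one recurrence plot per modality) passes through a
# shared-weight convolutional block — two 3x3 convolutions with 16 filters
# and rectified-linear activations, a 2x2 max-pool, flatten, and a dense
# projection — wrapped time-distributed so the same parameters apply to
# every window in the sequence. The per-window feature vectors (concatenated
# across modalities in the hybrid network) feed an LSTM whose final hidden
# state passes through a dense layer into the 4-class softmax output.
#
# The network, its backpropagation and the Adam optimizer are implemented
# here directly (convolution and pooling kernels in compiled code), so
# training is deterministic given the seed.

#' Network architecture specification
#'
#' @slot nFilters filters per convolution layer (default 16).
#' @slot kernel convolution kernel size (square, default 3).
#' @slot pool max-pooling size/stride (default 2).
#' @slot tdDenseUnits width of the time-distributed dense projection.
#' @slot lstmUnits LSTM hidden units.
#' @slot headDenseUnits width of the dense layer before the output.
#' @slot nClasses output classes (4).
#' @slot dropout training-time dropout rate on the time-distributed
#'   feature vectors (inverted dropout). Default 0: at the package's
#'   desk-scale sample sizes and short training budgets dropout slows
#'   convergence more than it helps generalization.
#' @slot hybrid logical; two convolutional branches (EEG + fNIRS) whose
#'   per-window features are concatenated before the LSTM.
#' @export
setClass("ArchitectureSpec", representation(
  nFilters = "integer", kernel = "integer", pool = "integer",
  tdDenseUnits = "integer", lstmUnits = "integer", headDenseUnits = "integer",
  nClasses = "integer", dropout = "numeric", hybrid = "logical"
))

setValidity("ArchitectureSpec", function(object) {
  if (any(c(object@nFilters, object@kernel, object@pool, object@tdDenseUnits,
            object@lstmUnits, object@headDenseUnits, object@nClasses) < 1L))
    "all unit counts must be >= 1"
  else if (object@dropout < 0 || object@dropout >= 1)
    "dropout must lie in [0, 1)" else TRUE
})

#' @param nFilters,kernel,pool,tdDenseUnits,lstmUnits,headDenseUnits,nClasses,dropout,hybrid see slots.
#' @return an [ArchitectureSpec-class].
#' @rdname ArchitectureSpec-class
#' @export
ArchitectureSpec <- function(nFilters = 16, kernel = 3, pool = 2,
                             tdDenseUnits = 64, lstmUnits = 64,
                             headDenseUnits = 32, nClasses = 4,
                             dropout = 0, hybrid = FALSE) {
  new("ArchitectureSpec", nFilters = as.integer(nFilters),
      kernel = as.integer(kernel), pool = as.integer(pool),
      tdDenseUnits = as.integer(tdDenseUnits),
      lstmUnits = as.integer(lstmUnits),
      headDenseUnits = as.integer(headDenseUnits),
      nClasses = as.integer(nClasses), dropout = dropout, hybrid = hybrid)
}

#' Training configuration
#'
#' @slot learningRate Adam step size (default 1e-3).
#' @slot epochs maximum epochs (default 50).
#' @slot batchSize minibatch size (default 32).
#' @slot seed integer; fixes initialization and shuffling.
#' @slot patience early-stopping patience in epochs on the monitored loss
#'   (validation loss when `valFraction > 0`, else training loss).
#' @slot valFraction fraction of the training set held out for monitoring.
#' @export
setClass("TrainConfig", representation(
  learningRate = "numeric", epochs = "integer", batchSize = "integer",
  seed = "integer", patience = "integer", valFraction = "numeric"
))

#' @param learningRate,epochs,batchSize,seed,patience,valFraction see slots.
#' @return a [TrainConfig-class].
#' @rdname TrainConfig-class
#' @export
TrainConfig <- function(learningRate = 1e-3, epochs = 50, batchSize = 32,
                        seed = 1, patience = 10, valFraction = 0) {
  stopifnot(epochs >= 1)
  new("TrainConfig", learningRate = learningRate, epochs = as.integer(epochs),
      batchSize = as.integer(batchSize), seed = as.integer(seed),
      patience = as.integer(patience), valFraction = valFraction)
}

#' Trained (or initialized) time-distributed CNN-LSTM
#'
#' @slot spec the [ArchitectureSpec-class].
#' @slot inputShapes list of `c(T, H, W)` per branch.
#' @slot params named list of weight matrices and bias vectors.
#' @slot history `data.frame` of per-epoch loss/accuracy.
#' @slot classes class-label ordering of the softmax output.
#' @export
setClass("TDCNNLSTM", representation(
  spec = "ArchitectureSpec", inputShapes = "list", params = "list",
  history = "data.frame", classes = "character"
))

setMethod("show", "TDCNNLSTM", function(object) {
  sh <- vapply(object@inputShapes, paste, character(1), collapse = "x")
  np <- sum(vapply(object@params, length, numeric(1)))
  cat(sprintf("TDCNNLSTM (%s): input %s, %d classes, %s parameters%s\n",
              if (object@spec@hybrid) "hybrid" else "single-modality",
              paste(sh, collapse = " + "), object@spec@nClasses,
              format(np, big.mark = ","),
              if (nrow(object@history)) " [trained]" else ""))
})

.branch_flat_dim <- function(H, W, spec) {
  k <- spec@kernel
  Ho <- H - 2L * (k - 1L); Wo <- W - 2L * (k - 1L)
  if (Ho < spec@pool || Wo < spec@pool)
    stop("input ", H, "x", W, " too small for two ", k, "x", k,
         " convolutions and a ", spec@pool, "x", spec@pool, " pool")
  (Ho %/% spec@pool) * (Wo %/% spec@pool) * spec@nFilters
}

#' Build an untrained time-distributed CNN-LSTM
#'
#' The convolutional block is applied with shared weights to every temporal
#' slice, so its parameter count is independent of the sequence length. For
#' a hybrid model give two input shapes (EEG branch first); their per-window
#' feature vectors are concatenated before the LSTM.
#'
#' @param spec an [ArchitectureSpec-class].
#' @param inputShapes `c(T, H, W)` for single modality, or a list of two
#'   such vectors for `hybrid = TRUE`. Plots must be square (`H == W`).
#' @param classes class-label ordering of the output layer.
#' @param seed initialization seed.
#' @return a [TDCNNLSTM-class] with freshly initialized parameters.
#' @export
buildModel <- function(spec, inputShapes, classes = .CLASS_LABELS, seed = 1) {
  if (!is.list(inputShapes[[1]]) && !is.list(inputShapes))
    inputShapes <- list(inputShapes)
  if (is.numeric(inputShapes[[1]]) && length(inputShapes[[1]]) == 1L)
    inputShapes <- list(unlist(inputShapes))
  nb <- length(inputShapes)
  if (spec@hybrid && nb != 2L)
    stop("hybrid model needs exactly two input shapes, got ", nb)
  if (!spec@hybrid && nb != 1L)
    stop("single-modality model needs one input shape, got ", nb)
  Ts <- vapply(inputShapes, `[`, numeric(1), 1L)
  if (length(unique(Ts)) != 1L)
    stop("all branches must share the sequence length")
  for (sh in inputShapes)
    if (sh[2L] != sh[3L])
      stop("recurrence plots must be square; got ", sh[2L], "x", sh[3L])
  if (length(classes) != spec@nClasses)
    stop("expected ", spec@nClasses, " class labels, got ", length(classes))

  .with_seed(seed, {
    he <- function(nr, nc, fan) matrix(stats::rnorm(nr * nc, 0,
                                                    sqrt(2 / fan)), nr, nc)
    k <- spec@kernel; F <- spec@nFilters
    params <- list()
    for (b in seq_len(nb)) {
      H <- inputShapes[[b]][2L]; W <- inputShapes[[b]][3L]
      flat <- .branch_flat_dim(H, W, spec)
      params[[paste0("W1_", b)]] <- he(k * k, F, k * k)
      params[[paste0("b1_", b)]] <- numeric(F)
      params[[paste0("W2_", b)]] <- he(k * k * F, F, k * k * F)
      params[[paste0("b2_", b)]] <- numeric(F)
      params[[paste0("Wd_", b)]] <- he(flat, spec@tdDenseUnits, flat)
      params[[paste0("bd_", b)]] <- numeric(spec@tdDenseUnits)
    }
    Din <- nb * spec@tdDenseUnits
    Hn <- spec@lstmUnits
    sc <- sqrt(1 / Hn)
    params$Wx <- matrix(stats::rnorm(Din * 4 * Hn, 0, sc), Din, 4L * Hn)
    params$Wh <- matrix(stats::rnorm(Hn * 4 * Hn, 0, sc), Hn, 4L * Hn)
    params$bl <- rep(c(0, 1, 0, 0), each = Hn)   # forget-gate bias 1
    params$V1 <- he(Hn, spec@headDenseUnits, Hn)
    params$c1 <- numeric(spec@headDenseUnits)
    params$V2 <- he(spec@headDenseUnits, spec@nClasses, spec@headDenseUnits)
    params$c2 <- numeric(spec@nClasses)
    new("TDCNNLSTM", spec = spec, inputShapes = inputShapes, params = params,
        history = data.frame(), classes = classes)
  })
}

# coerce one sample into a list of per-branch (H, W, T) window stacks
.as_branches <- function(sample, hybrid) {
  stack <- function(ims) {
    if (is.array(ims) && length(dim(ims)) == 3L) return(ims)
    array(unlist(ims), c(dim(ims[[1L]]), length(ims)))
  }
  if (hybrid) {
    stopifnot(all(c("eeg", "fnirs") %in% names(sample)))
    list(stack(sample$eeg), stack(sample$fnirs))
  } else {
    list(stack(sample))
  }
}

.sigmoid <- function(x) 1 / (1 + exp(-x))

# forward pass for one sample; returns probs and (optionally) the cache
.nn_forward <- function(model, branches, keep = FALSE) {
  p <- model@params
  spec <- model@spec
  nb <- length(branches)
  Tn <- dim(branches[[1L]])[3L]
  Hn <- spec@lstmUnits
  k <- spec@kernel
  feats <- matrix(0, spec@tdDenseUnits * nb, Tn)
  cache <- if (keep) list(branches = vector("list", nb)) else NULL
  for (b in seq_len(nb)) {
    td <- .td_fw(branches[[b]],
                 p[[paste0("W1_", b)]], p[[paste0("b1_", b)]],
                 p[[paste0("W2_", b)]], p[[paste0("b2_", b)]],
                 p[[paste0("Wd_", b)]], p[[paste0("bd_", b)]],
                 k, spec@pool, keep)
    rows <- ((b - 1L) * spec@tdDenseUnits + 1L):(b * spec@tdDenseUnits)
    feats[rows, ] <- td$feats
    if (keep) cache$branches[[b]] <- td
  }
  if (keep && spec@dropout > 0) {
    # inverted dropout on the time-distributed features (training only)
    mask <- (matrix(stats::runif(length(feats)), nrow(feats)) >=
               spec@dropout) / (1 - spec@dropout)
    feats <- feats * mask
    cache$dropmask <- mask
  }
  # LSTM over T steps (gates ordered i, f, g, o)
  h <- numeric(Hn); cs <- numeric(Hn)
  if (keep) cache$lstm <- vector("list", Tn)
  for (t in seq_len(Tn)) {
    z <- drop(crossprod(p$Wx, feats[, t])) + drop(crossprod(p$Wh, h)) + p$bl
    ig <- .sigmoid(z[1:Hn]); fg <- .sigmoid(z[(Hn + 1):(2 * Hn)])
    gg <- tanh(z[(2 * Hn + 1):(3 * Hn)]); og <- .sigmoid(z[(3 * Hn + 1):(4 * Hn)])
    cprev <- cs
    cs <- fg * cprev + ig * gg
    tc <- tanh(cs)
    if (keep) cache$lstm[[t]] <- list(ig = ig, fg = fg, gg = gg, og = og,
                                      cprev = cprev, cs = cs, tc = tc,
                                      hprev = if (t > 1L) cache$lstm[[t - 1L]]$h
                                              else numeric(Hn))
    h <- og * tc
    if (keep) cache$lstm[[t]]$h <- h
  }
  ah <- drop(crossprod(p$V1, h)) + p$c1
  rh <- pmax(ah, 0)
  logits <- drop(crossprod(p$V2, rh)) + p$c2
  mlog <- logits - max(logits)
  probs <- exp(mlog) / sum(exp(mlog))
  if (keep) {
    cache$feats <- feats; cache$h <- h; cache$ahpos <- ah > 0; cache$rh <- rh
    cache$probs <- probs
  }
  list(probs = probs, cache = cache)
}

# backward pass for one sample; returns gradient list (same names as params)
.nn_backward <- function(model, cache, y) {
  p <- model@params
  spec <- model@spec
  Hn <- spec@lstmUnits
  nb <- length(cache$branches)
  Tn <- ncol(cache$feats)
  g <- lapply(p, function(w) array(0, dim(w) %||% length(w)))
  names(g) <- names(p)

  dlogit <- cache$probs
  dlogit[y] <- dlogit[y] - 1
  g$V2 <- g$V2 + outer(cache$rh, dlogit)
  g$c2 <- g$c2 + dlogit
  drh <- drop(p$V2 %*% dlogit) * cache$ahpos
  g$V1 <- g$V1 + outer(cache$h, drh)
  g$c1 <- g$c1 + drh
  dh <- drop(p$V1 %*% drh)

  dfeats <- matrix(0, nrow(cache$feats), Tn)
  dc <- numeric(Hn)
  for (t in rev(seq_len(Tn))) {
    L <- cache$lstm[[t]]
    do <- dh * L$tc * L$og * (1 - L$og)
    dcs <- dc + dh * L$og * (1 - L$tc^2)
    di <- dcs * L$gg * L$ig * (1 - L$ig)
    df <- dcs * L$cprev * L$fg * (1 - L$fg)
    dg <- dcs * L$ig * (1 - L$gg^2)
    dz <- c(di, df, dg, do)
    g$Wx <- g$Wx + outer(cache$feats[, t], dz)
    g$Wh <- g$Wh + outer(L$hprev, dz)
    g$bl <- g$bl + dz
    dfeats[, t] <- drop(p$Wx %*% dz)
    dh <- drop(p$Wh %*% dz)
    dc <- dcs * L$fg
  }

  if (!is.null(cache$dropmask)) dfeats <- dfeats * cache$dropmask
  for (b in seq_len(nb)) {
    rows <- ((b - 1L) * spec@tdDenseUnits + 1L):(b * spec@tdDenseUnits)
    cb <- cache$branches[[b]]
    bw <- .td_bw(cb$cache, p[[paste0("W1_", b)]],
                 p[[paste0("W2_", b)]], p[[paste0("Wd_", b)]],
                 dfeats[rows, , drop = FALSE], spec@kernel, spec@pool)
    g[[paste0("W1_", b)]] <- g[[paste0("W1_", b)]] + bw$gW1
    g[[paste0("b1_", b)]] <- g[[paste0("b1_", b)]] + drop(bw$gb1)
    g[[paste0("W2_", b)]] <- g[[paste0("W2_", b)]] + bw$gW2
    g[[paste0("b2_", b)]] <- g[[paste0("b2_", b)]] + drop(bw$gb2)
    g[[paste0("Wd_", b)]] <- g[[paste0("Wd_", b)]] + bw$gWd
    g[[paste0("bd_", b)]] <- g[[paste0("bd_", b)]] + drop(bw$gbd)
  }
  g
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Train a time-distributed CNN-LSTM
#'
#' Minimizes categorical cross-entropy with the Adam optimizer. Given the
#' same data, configuration and seed, training is bit-reproducible (no
#' threading nondeterminism). Training history (per-epoch loss and accuracy,
#' plus validation metrics when a monitoring split is configured) is stored
#' on the returned model.
#'
#' @param model a [TDCNNLSTM-class] from [buildModel()] (its parameters are
#'   re-initialized from `cfg@seed`).
#' @param samples list of samples; single modality: each a list of `T`
#'   square matrices; hybrid: each a `list(eeg = ..., fnirs = ...)`.
#' @param labels character/factor of class labels, one per sample.
#' @param cfg a [TrainConfig-class].
#' @return the trained [TDCNNLSTM-class].
#' @export
trainModel <- function(model, samples, labels, cfg = TrainConfig()) {
  labels <- as.character(labels)
  if (length(unique(labels)) < 2L)
    stop("training set must contain at least 2 classes, found ",
         length(unique(labels)))
  if (length(samples) != length(labels))
    stop("length(samples) != length(labels)")
  bad <- setdiff(unique(labels), model@classes)
  if (length(bad))
    stop("unknown label(s): ", paste(bad, collapse = ", "))

  model <- buildModel(model@spec, model@inputShapes, model@classes,
                      seed = cfg@seed)
  hybrid <- model@spec@hybrid
  data <- lapply(samples, .as_branches, hybrid = hybrid)
  yidx <- match(labels, model@classes)
  .check_shapes(model, data)

  .with_seed(cfg@seed + 1L, {
    n <- length(data)
    if (cfg@valFraction > 0) {
      nval <- max(1L, round(cfg@valFraction * n))
      vi <- sample.int(n, nval)
      ti <- setdiff(seq_len(n), vi)
    } else {
      vi <- integer(); ti <- seq_len(n)
    }

    p <- model@params
    mAdam <- lapply(p, function(w) array(0, dim(w) %||% length(w)))
    vAdam <- mAdam
    step <- 0L
    b1 <- 0.9; b2 <- 0.999; epsA <- 1e-8
    best <- list(loss = Inf, params = p, wait = 0L)
    hist <- list()

    for (epoch in seq_len(cfg@epochs)) {
      ord <- ti[sample.int(length(ti))]
      tot_loss <- 0; tot_correct <- 0L
      for (start in seq(1L, length(ord), by = cfg@batchSize)) {
        idx <- ord[start:min(start + cfg@batchSize - 1L, length(ord))]
        gsum <- NULL
        for (i in idx) {
          model@params <- p
          fw <- .nn_forward(model, data[[i]], keep = TRUE)
          pr <- fw$probs
          tot_loss <- tot_loss - log(max(pr[yidx[i]], 1e-12))
          tot_correct <- tot_correct + (which.max(pr) == yidx[i])
          gi <- .nn_backward(model, fw$cache, yidx[i])
          gsum <- if (is.null(gsum)) gi
                  else Map(`+`, gsum, gi)
        }
        step <- step + 1L
        sc <- 1 / length(idx)
        for (nm in names(p)) {
          gr <- gsum[[nm]] * sc
          mAdam[[nm]] <- b1 * mAdam[[nm]] + (1 - b1) * gr
          vAdam[[nm]] <- b2 * vAdam[[nm]] + (1 - b2) * gr^2
          mh <- mAdam[[nm]] / (1 - b1^step)
          vh <- vAdam[[nm]] / (1 - b2^step)
          p[[nm]] <- p[[nm]] - cfg@learningRate * mh / (sqrt(vh) + epsA)
        }
      }
      model@params <- p
      train_loss <- tot_loss / length(ord)
      train_acc <- tot_correct / length(ord)
      if (length(vi)) {
        vloss <- 0; vcorrect <- 0L
        for (i in vi) {
          pr <- .nn_forward(model, data[[i]])$probs
          vloss <- vloss - log(max(pr[yidx[i]], 1e-12))
          vcorrect <- vcorrect + (which.max(pr) == yidx[i])
        }
        mon <- vloss / length(vi)
        hist[[epoch]] <- data.frame(epoch = epoch, loss = train_loss,
                                    accuracy = train_acc, val_loss = mon,
                                    val_accuracy = vcorrect / length(vi))
      } else {
        mon <- train_loss
        hist[[epoch]] <- data.frame(epoch = epoch, loss = train_loss,
                                    accuracy = train_acc)
      }
      if (mon < best$loss - 1e-6) {
        best <- list(loss = mon, params = p, wait = 0L)
      } else {
        best$wait <- best$wait + 1L
        if (best$wait >= cfg@patience) break
      }
    }
    model@params <- best$params
    model@history <- do.call(rbind, hist)
    model
  })
}

.check_shapes <- function(model, data) {
  for (b in seq_along(model@inputShapes)) {
    sh <- model@inputShapes[[b]]
    d1 <- dim(data[[1L]][[b]])
    if (d1[3L] != sh[1L] || !all(d1[1:2] == sh[2:3]))
      stop("sample shape (", d1[3L], ", ", d1[1L], "x", d1[2L],
           ") does not match the model input shape (", sh[1L], ", ",
           sh[2L], "x", sh[3L], ")")
  }
  invisible(TRUE)
}

#' Class probabilities for recurrence-plot sequences
#'
#' @param model a trained [TDCNNLSTM-class].
#' @param samples list of samples (same layout as in [trainModel()]).
#' @return `n x nClasses` matrix of softmax probabilities (rows sum to 1),
#'   columns named by `model@classes`.
#' @export
predictProba <- function(model, samples) {
  data <- lapply(samples, .as_branches, hybrid = model@spec@hybrid)
  .check_shapes(model, data)
  out <- t(vapply(data, function(d) .nn_forward(model, d)$probs,
                  numeric(model@spec@nClasses)))
  colnames(out) <- model@classes
  out
}

#' Predicted class labels
#'
#' @param model a trained [TDCNNLSTM-class].
#' @param samples list of samples.
#' @return character vector of predicted labels (softmax argmax).
#' @export
predictClass <- function(model, samples) {
  pr <- predictProba(model, samples)
  model@classes[max.col(pr, ties.method = "first")]
}
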