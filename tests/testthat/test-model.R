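test_that("models propagate shapes and output 4-class probabilities", {
  m <- buildModel(ArchitectureSpec(), c(4, 100, 100), seed = 1)
  s <- tinySamples(1, tSeq = 4, size = 100)
  p <- predictProba(m, s)
  expect_equal(dim(p), c(1L, 4L))
  expect_equal(sum(p), 1, tolerance = 1e-6)
  expect_true(all(p >= 0))

  h <- buildModel(ArchitectureSpec(hybrid = TRUE),
                  list(c(4, 100, 100), c(4, 50, 50)), seed = 1)
  sh <- list(list(eeg = tinySamples(1, 4, 100)[[1]],
                  fnirs = tinySamples(1, 4, 50)[[1]]))
  ph <- predictProba(h, sh)
  expect_equal(dim(ph), c(1L, 4L))
  expect_equal(sum(ph), 1, tolerance = 1e-6)
})

test_that("shape mismatches and non-square plots are refused", {
  expect_error(buildModel(ArchitectureSpec(), c(4, 100, 50)), "square")
  m <- buildModel(tinySpec(), c(2, 12, 12), seed = 1)
  expect_error(predictProba(m, tinySamples(1, tSeq = 3, size = 12)),
               "input shape")
  expect_error(predictProba(m, tinySamples(1, tSeq = 2, size = 10)),
               "input shape")
  expect_error(buildModel(ArchitectureSpec(hybrid = TRUE), c(4, 20, 20)),
               "two input shapes")
})

test_that("the convolutional block's parameter count is independent of sequence length", {
  m2 <- buildModel(tinySpec(), c(2, 12, 12), seed = 1)
  m6 <- buildModel(tinySpec(), c(6, 12, 12), seed = 1)
  np <- function(m) vapply(m@params, length, numeric(1))
  expect_identical(np(m2), np(m6))
})

test_that("time-distributed weights are shared: a window's features do not depend on its slot", {
  m <- buildModel(tinySpec(), c(3, 12, 12), seed = 2)
  set.seed(7)
  w <- lapply(1:3, function(i) matrix(rnorm(144), 12))
  f1 <- neurorp:::.td_fw(array(unlist(w), c(12, 12, 3)),
                         m@params$W1_1, m@params$b1_1, m@params$W2_1,
                         m@params$b2_1, m@params$Wd_1, m@params$bd_1,
                         3L, 2L, FALSE)$feats
  wperm <- w[c(3, 1, 2)]
  f2 <- neurorp:::.td_fw(array(unlist(wperm), c(12, 12, 3)),
                         m@params$W1_1, m@params$b1_1, m@params$W2_1,
                         m@params$b2_1, m@params$Wd_1, m@params$bd_1,
                         3L, 2L, FALSE)$feats
  expect_equal(f1[, c(3, 1, 2)], f2, tolerance = 1e-12)
})

test_that("analytic gradients match numerical differentiation", {
  spec <- ArchitectureSpec(nFilters = 3, tdDenseUnits = 5, lstmUnits = 4,
                           headDenseUnits = 3, dropout = 0, hybrid = TRUE)
  m <- buildModel(spec, list(c(2, 10, 10), c(2, 8, 8)), seed = 7)
  set.seed(8)
  samp <- list(eeg = lapply(1:2, function(i) matrix(rnorm(100), 10)),
               fnirs = lapply(1:2, function(i) matrix(rnorm(64), 8)))
  br <- neurorp:::.as_branches(samp, TRUE)
  fw <- neurorp:::.nn_forward(m, br, keep = TRUE)
  g <- neurorp:::.nn_backward(m, fw$cache, 2L)
  loss_at <- function(mm) -log(neurorp:::.nn_forward(mm, br)$probs[2])
  eps <- 1e-4
  for (nm in names(m@params)) {
    w <- m@params[[nm]]
    for (j in sample(length(w), min(4, length(w)))) {
      m2 <- m; m2@params[[nm]][j] <- w[j] + eps
      m3 <- m; m3@params[[nm]][j] <- w[j] - eps
      num <- (loss_at(m2) - loss_at(m3)) / (2 * eps)
      ana <- g[[nm]][j]
      expect_lt(abs(num - ana) / max(1e-4, abs(num) + abs(ana)), 0.05)
    }
  }
})

test_that("the network memorizes a small labeled set (overfit sanity)", {
  set.seed(9)
  n_per <- 10
  samples <- c(tinySamples(n_per, 2, 12, mean = 0, seed = 1),
               tinySamples(n_per, 2, 12, mean = 0.8, seed = 2),
               tinySamples(n_per, 2, 12, mean = -0.8, seed = 3),
               tinySamples(n_per, 2, 12, mean = 1.6, seed = 4))
  labels <- rep(c("0-back", "2-back", "3-back", "rest"), each = n_per)
  m <- buildModel(tinySpec(), c(2, 12, 12), seed = 1)
  m <- trainModel(m, samples, labels,
                  TrainConfig(epochs = 200, batchSize = 8, seed = 1,
                              patience = 200))
  acc <- mean(predictClass(m, samples) == labels)
  expect_gte(acc, 0.95)

  # trained probabilities still form a simplex; duplicates agree
  p <- predictProba(m, samples[c(1, 1)])
  expect_equal(p[1, ], p[2, ], tolerance = 1e-12)
  expect_equal(rowSums(p), c(1, 1), tolerance = 1e-6)
})

test_that("training is deterministic given the seed", {
  samples <- c(tinySamples(6, 2, 12, 0, seed = 5),
               tinySamples(6, 2, 12, 1, seed = 6))
  labels <- rep(c("0-back", "rest"), each = 6)
  m <- buildModel(tinySpec(), c(2, 12, 12), seed = 1)
  cfg <- TrainConfig(epochs = 5, batchSize = 4, seed = 3, patience = 5)
  m1 <- trainModel(m, samples, labels, cfg)
  m2 <- trainModel(m, samples, labels, cfg)
  expect_identical(m1@history, m2@history)
  expect_identical(m1@params, m2@params)
})

test_that("label-shuffled training stays near the 4-class chance level", {
  set.seed(10)
  samples <- tinySamples(40, 2, 12, 0, seed = 11)
  accs <- vapply(1:3, function(s) {
    set.seed(100 + s)
    labels <- sample(rep(c("0-back", "2-back", "3-back", "rest"), 10))
    m <- buildModel(tinySpec(), c(2, 12, 12), seed = s)
    m <- trainModel(m, samples[1:32], labels[1:32],
                    TrainConfig(epochs = 15, batchSize = 8, seed = s,
                                patience = 15))
    mean(predictClass(m, samples[33:40]) == labels[33:40])
  }, numeric(1))
  expect_lt(abs(mean(accs) - 0.25), 0.25)
})

test_that("degenerate training sets are refused", {
  samples <- tinySamples(4, 2, 12)
  m <- buildModel(tinySpec(), c(2, 12, 12), seed = 1)
  expect_error(trainModel(m, samples, rep("rest", 4)), "2 classes")
  expect_error(trainModel(m, samples, rep(c("rest", "up"), 2)),
               "unknown label")
})

test_that("the fused block agrees with the elementary double-precision primitives", {
  set.seed(12)
  m <- buildModel(tinySpec(), c(2, 12, 12), seed = 3)
  w <- array(rnorm(12 * 12 * 2), c(12, 12, 2))
  td <- neurorp:::.td_fw(w, m@params$W1_1, m@params$b1_1, m@params$W2_1,
                         m@params$b2_1, m@params$Wd_1, m@params$bd_1,
                         3L, 2L, FALSE)
  for (t in 1:2) {
    x <- array(w[, , t], c(12, 12, 1))
    r1 <- pmax(neurorp:::.conv2d_fw(x, m@params$W1_1, m@params$b1_1, 3L), 0)
    r2 <- pmax(neurorp:::.conv2d_fw(r1, m@params$W2_1, m@params$b2_1, 3L), 0)
    pl <- neurorp:::.maxpool_fw(r2, 2L)
    f <- pmax(drop(crossprod(m@params$Wd_1, as.vector(pl$out))) +
                m@params$bd_1, 0)
    expect_equal(td$feats[, t], f, tolerance = 1e-5)
  }
})
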