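test_that("delay embedding expands a scalar series per the defining expansion", {
  tr <- embedSeries(c(1, 2, 3, 4, 5), EmbeddingConfig(m = 2, d = 1))
  expect_equal(tr@states, rbind(c(1, 2), c(2, 3), c(3, 4), c(4, 5)))

  ident <- embedSeries(c(4, 7, 1), EmbeddingConfig(m = 1))
  expect_equal(as.vector(ident@states), c(4, 7, 1))

  expect_error(embedSeries(1:4, EmbeddingConfig(m = 3, d = 2)), ">= 5")
})

test_that("multichannel embedding concatenates per-channel delay vectors", {
  x <- rbind(1:5, 11:15)
  tr <- embedSeries(x, EmbeddingConfig(m = 2, d = 2))
  expect_equal(dim(tr@states), c(3L, 4L))
  expect_equal(tr@states[1, ], c(1, 11, 3, 13))
})

test_that("the embedding-dimension condition warns below 2n + 1 and passes otherwise", {
  expect_silent(expect_true(checkEmbedding(EmbeddingConfig(m = 3, n = 1))))
  expect_warning(checkEmbedding(EmbeddingConfig(m = 2, n = 1)), "2n \\+ 1")
  expect_silent(expect_true(checkEmbedding(EmbeddingConfig(m = 1))))
})

test_that("distance matrices are symmetric, zero-diagonal and match hand values", {
  D <- distanceMatrix(embedSeries(c(0, 3, 4)))
  expect_equal(unname(D), rbind(c(0, 3, 4), c(3, 0, 1), c(4, 1, 0)))
  set.seed(41)
  D2 <- distanceMatrix(matrix(rnorm(60), 20))
  expect_equal(max(abs(D2 - t(D2))), 0)
  expect_equal(max(abs(diag(D2))), 0)
})

test_that("the vectorized distance matrix equals the double-loop oracle", {
  set.seed(42)
  for (rep in 1:5) {
    Tn <- sample(5:200, 1)
    st <- matrix(rnorm(Tn * 3), Tn)
    D <- distanceMatrix(st)
    O <- matrix(0, Tn, Tn)
    for (i in seq_len(Tn)) for (j in seq_len(Tn))
      O[i, j] <- sqrt(sum((st[i, ] - st[j, ])^2))
    expect_equal(unname(D), O, tolerance = 1e-12)
  }
})

test_that("thresholding reproduces hand-computed recurrence matrices", {
  cfgAbs <- RPConfig(epsilon = 0.1, epsilonMode = "absolute", step = 1)
  R <- recurrenceMatrix(distanceMatrix(embedSeries(c(0, 0.05, 0.5))), cfgAbs)
  expect_equal(R, rbind(c(1, 1, 0), c(1, 1, 0), c(0, 0, 1)))

  const <- recurrenceMatrix(distanceMatrix(embedSeries(rep(2, 6))))
  expect_true(all(const == 1))
})

test_that("binary plots are symmetric with a unit diagonal; grayscale lies in [0,1]", {
  set.seed(43)
  D <- distanceMatrix(matrix(rnorm(40), 20))
  R <- recurrenceMatrix(D, RPConfig())
  expect_identical(R, t(R))
  expect_true(all(diag(R) == 1))
  expect_true(all(R %in% c(0, 1)))
  G <- recurrenceMatrix(D, RPConfig(outputMode = "grayscale"))
  expect_true(all(G >= 0 & G <= 1))
  expect_true(all(diag(G) == 1))
})

test_that("fraction-mode binary plots are invariant under positive rescaling", {
  set.seed(44)
  x <- rnorm(80)
  R1 <- recurrenceMatrix(distanceMatrix(embedSeries(x)), RPConfig())
  for (c in c(0.01, 3, 250)) {
    Rc <- recurrenceMatrix(distanceMatrix(embedSeries(c * x)), RPConfig())
    expect_identical(Rc, R1)
  }
})

test_that("the recurrence rate is non-decreasing in the threshold", {
  set.seed(45)
  D <- distanceMatrix(matrix(rnorm(90), 30))
  rates <- vapply(c(0.02, 0.05, 0.1, 0.3, 0.6, 1), function(e)
    mean(recurrenceMatrix(D, RPConfig(epsilon = e))), numeric(1))
  expect_true(all(diff(rates) >= 0))
  expect_equal(rates[length(rates)], 1)
})

test_that("a noise-free sinusoid produces periodic secondary diagonals", {
  P <- 20                                 # samples per period (post-stride)
  x <- sin(2 * pi * (0:159) / P)
  R <- recurrenceMatrix(distanceMatrix(embedSeries(x)), RPConfig())
  n <- nrow(R)
  diag_mean <- vapply(0:(n - 10), function(k)
    mean(R[cbind(1:(n - k), (1 + k):n)]), numeric(1))
  peaks <- which(diag_mean > 0.9) - 1
  expect_true(all(abs((peaks %% P + P / 2) %% P - P / 2) <= 1))
  expect_true(any(peaks >= P - 1))        # the k = P diagonal is present
})

test_that("the window grid reproduces the counting formula", {
  g <- windowGrid(400, 10, RPConfig(step = 1))
  expect_equal(g$count, 9L)                 # floor((400 - 50) / 40) + 1
  expect_equal(g$width, 50L)
  expect_equal(g$advance, 40L)

  g2 <- windowGrid(8000, 200, RPConfig(step = 10))
  expect_equal(g2$count, 9L)

  g3 <- windowGrid(150, 10, RPConfig(step = 1, overlap = 0))
  expect_equal(g3$count, 3L)                # exact tiling
})

test_that("EEG windows at 200 Hz with stride 10 give 100 x 100 plots", {
  rec <- Recording(matrix(rnorm(2 * 2000), 2), 200, c("a", "b"), "eeg")
  rp <- windowRPSequence(rec, "rest", rcfg = RPConfig(step = 10))
  expect_length(rpImages(rp), 2L)
  expect_equal(dim(rpImages(rp)[[1]]), c(100L, 100L))
  expect_equal(modality(rp), "eeg")
})

test_that("segments shorter than one window are refused", {
  rec <- Recording(matrix(rnorm(100), 1), 200, "a", "eeg")
  expect_error(windowRPSequence(rec, "rest"), "shorter than one")
})

test_that("hybrid pairing aligns, truncates with a warning, refuses label mismatch", {
  im <- function(n, sz) lapply(seq_len(n), function(i) diag(sz))
  e9 <- new("RPSequence", images = im(9, 4), label = "2-back",
            modality = "eeg", provenance = list())
  f9 <- new("RPSequence", images = im(9, 3), label = "2-back",
            modality = "fnirs", provenance = list())
  pr <- pairHybrid(e9, f9)
  expect_length(pr$eeg, 9L)
  expect_length(pr$fnirs, 9L)

  f8 <- new("RPSequence", images = im(8, 3), label = "2-back",
            modality = "fnirs", provenance = list())
  expect_warning(pr8 <- pairHybrid(e9, f8), "truncating")
  expect_length(pr8$eeg, 8L)

  frest <- new("RPSequence", images = im(9, 3), label = "rest",
               modality = "fnirs", provenance = list())
  expect_error(pairHybrid(e9, frest), "label mismatch")
})

test_that("sequence assembly chunks windows into non-overlapping runs", {
  ims <- lapply(1:9, function(i) matrix(i, 2, 2))
  seqs <- assembleSequences(ims, 4)
  expect_length(seqs, 2L)
  expect_equal(seqs[[1]][[1]][1, 1], 1)
  expect_equal(seqs[[2]][[4]][1, 1], 8)     # the 9th window is dropped
})

test_that("the full recurrence pipeline matches the naive oracle on random windows", {
  set.seed(46)
  for (rep in 1:50) {
    C <- sample(1:3, 1)
    S <- sample(20:200, 1)
    m <- sample(1:3, 1)
    d <- sample(1:2, 1)
    if (S - (m - 1) * d < 2) next
    x <- matrix(rnorm(C * S), C)
    mode <- sample(c("fraction", "absolute"), 1)
    cfg <- RPConfig(step = 1, epsilon = if (mode == "fraction") 0.1 else 0.8,
                    epsilonMode = if (mode == "fraction")
                      "fraction_of_max_distance" else "absolute")
    R <- recurrenceMatrix(distanceMatrix(
      embedSeries(x, EmbeddingConfig(m = m, d = d))), cfg)
    O <- naiveRP(x, m, d, cfg@epsilon, mode)
    expect_identical(unname(R), O)
  }
})
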