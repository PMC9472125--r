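# Shared fixtures, built once per test run.

.fixture_env <- new.env(parent = emptyenv())

# a quiet (noise-free) profile for deterministic oracles
quietProfile <- function(seed = 11, sites = 2, channels = 3, eegRate = 200) {
  SubjectProfile(seed = seed, eegChannels = channels, fnirsSites = sites,
                 eegRate = eegRate,
                 noiseLevels = c(pink = 0, line = 0, cardiac = 0,
                                 respiration = 0, mayer = 0, drift = 0,
                                 od_white = 0))
}

# a short protocol (one series per condition, shortened task/rest) so that
# simulation-based tests stay fast
shortSpec <- function(stimuli = 5, rest = 8)
  ProtocolSpec(nSessions = 1, seriesPerCondition = 1,
               stimuliPerSeries = stimuli, restDuration = rest)

# single-channel sinusoid recording
sineRecording <- function(freq, rate, seconds = 20, amp = 1) {
  t <- seq(0, seconds - 1 / rate, by = 1 / rate)
  Recording(matrix(amp * sin(2 * pi * freq * t), 1), rate, "c1", "eeg")
}

# amplitude of a sinusoid estimated away from the edges
interiorAmplitude <- function(x, frac = 0.2) {
  n <- length(x)
  i <- floor(n * frac):ceiling(n * (1 - frac))
  sqrt(2) * stats::sd(x[i])
}

# naive direct implementation of the recurrence pipeline (embedding by
# explicit loops, double-loop distances, elementwise thresholding); serves
# as the independent oracle for the vectorized path
naiveRP <- function(x, m, d, epsilon, mode = c("fraction", "absolute")) {
  mode <- match.arg(mode)
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  C <- nrow(x); S <- ncol(x)
  Tn <- S - (m - 1) * d
  states <- matrix(0, Tn, m * C)
  for (i in seq_len(Tn))
    for (k in seq_len(m))
      for (ch in seq_len(C))
        states[i, (k - 1) * C + ch] <- x[ch, i + (k - 1) * d]
  D <- matrix(0, Tn, Tn)
  for (i in seq_len(Tn))
    for (j in seq_len(Tn))
      D[i, j] <- sqrt(sum((states[i, ] - states[j, ])^2))
  eps <- if (mode == "fraction") epsilon * max(D) else epsilon
  (D <= eps) * 1
}

# tiny architecture for fast model tests
tinySpec <- function(hybrid = FALSE)
  ArchitectureSpec(nFilters = 4, tdDenseUnits = 8, lstmUnits = 6,
                   headDenseUnits = 5, hybrid = hybrid)

# random small RP-like sample lists for model tests
tinySamples <- function(n, tSeq = 2, size = 12, mean = 0, seed = 1) {
  set.seed(seed)
  lapply(seq_len(n), function(i)
    lapply(seq_len(tSeq), function(t) matrix(rnorm(size^2, mean), size)))
}
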