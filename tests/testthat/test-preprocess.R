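test_that("resampling to the current rate is the identity", {
  rec <- sineRecording(5, 100, 10)
  out <- resampleRecording(rec, 100)
  expect_identical(signalData(out), signalData(rec))
})

test_that("1 kHz EEG downsamples to 200 Hz with duration preserved", {
  rec <- sineRecording(10, 1000, 8)
  out <- resampleRecording(rec, 200)
  expect_equal(samplingRate(out), 200)
  expect_equal(nSamples(out), floor(nSamples(rec) * 200 / 1000))
  expect_lt(abs(duration(out) - duration(rec)), 1 / 200 + 1e-9)
})

test_that("an 80 Hz tone survives 1000 -> 200 Hz resampling in place and amplitude", {
  rec <- sineRecording(80, 1000, 10)
  out <- resampleRecording(rec, 200)
  y <- signalData(out)[1, ]
  sp <- Mod(stats::fft(y))[2:(length(y) %/% 2)]
  fpeak <- which.max(sp) * 200 / length(y)
  expect_lt(abs(fpeak - 80), 0.2)
  expect_lt(abs(interiorAmplitude(y) - 1), 0.05)
})

test_that("non-integer rate ratios (10.4 -> 10 Hz) are supported", {
  rec <- sineRecording(0.5, 10.4, 60)
  out <- resampleRecording(rec, 10)
  expect_equal(samplingRate(out), 10)
  expect_lt(abs(interiorAmplitude(signalData(out)[1, ]) - 1), 0.05)
})

test_that("upsampling is refused", {
  expect_error(resampleRecording(sineRecording(1, 10, 5), 20), "upsampling")
})

test_that("the bandpass removes DC to below 1e-6 of the offset", {
  rec <- Recording(matrix(rep(100, 2000), 1), 200, "c1", "eeg")
  out <- bandpassZeroPhase(rec, 1, 40, 6)
  expect_lt(abs(mean(signalData(out))), 1e-6 * 100)
})

test_that("bandpass magnitudes match the closed-form two-pass Butterworth response", {
  rate <- 200
  for (freq in c(20, 50)) {
    rec <- sineRecording(freq, rate, 30)
    out <- bandpassZeroPhase(rec, 1, 40, 6)
    gain <- interiorAmplitude(signalData(out)[1, ])
    db_meas <- -20 * log10(gain)
    db_form <- -20 * log10(butterMagnitudeTwoPass(freq, rate, low = 1,
                                                  high = 40, order = 6))
    expect_lt(abs(db_meas - db_form), 1)
  }
})

test_that("the 50 Hz attenuation is at least the doubled one-pass closed form", {
  rate <- 200
  rec <- sineRecording(50, rate, 30)
  out <- bandpassZeroPhase(rec, 1, 40, 6)
  atten_db <- -20 * log10(interiorAmplitude(signalData(out)[1, ]))
  bound_db <- 2 * 20 * log10(sqrt(1 + (50 / 40)^12))
  expect_gt(atten_db, bound_db - 0.5)
})

test_that("low-pass keeps constants and slow tones, rejects 1 Hz by >= 80 dB", {
  rate <- 10
  const <- Recording(matrix(rep(3, 600), 1), rate, "c1", "eeg")
  outc <- lowpassZeroPhase(const, 0.2, 6)
  expect_equal(signalData(outc)[1, ], rep(3, 600), tolerance = 1e-6)

  slow <- sineRecording(0.05, rate, 400)
  outs <- lowpassZeroPhase(slow, 0.2, 6)
  expect_lt(abs(interiorAmplitude(signalData(outs)[1, ]) - 1), 0.02)

  fast <- sineRecording(1, rate, 400)
  outf <- lowpassZeroPhase(fast, 0.2, 6)
  expect_gt(-20 * log10(interiorAmplitude(signalData(outf)[1, ])), 80)
})

test_that("filtering is zero-phase: cross-correlation peak at lag 0, counts preserved", {
  rate <- 200
  rec <- sineRecording(10, rate, 10)
  out <- bandpassZeroPhase(rec, 1, 40, 6)
  expect_equal(nSamples(out), nSamples(rec))
  x <- signalData(rec)[1, ]; y <- signalData(out)[1, ]
  cc <- stats::ccf(x, y, lag.max = 20, plot = FALSE)
  expect_equal(cc$lag[which.max(cc$acf)], 0)
})

test_that("filters refuse bands outside the Nyquist range", {
  rec <- sineRecording(1, 50, 10)
  expect_error(bandpassZeroPhase(rec, 1, 40, 6), "Nyquist")
  expect_error(lowpassZeroPhase(rec, 30, 6), "Hz")
})

test_that("zero optical density converts to zero concentration change", {
  ch <- channelInfo(c("S1-D1:760", "S1-D1:850"), "source-detector pair",
                    wavelength = c(760, 850), sourceDetectorDistance = 3)
  od <- Recording(matrix(0, 2, 50), 10, ch, "fnirs_od")
  hemo <- mbllConvert(od)
  expect_equal(max(abs(hemo@hbo)), 0)
  expect_equal(max(abs(hemo@hbr)), 0)
})

test_that("identity extinction with unit pathlength maps dOD to dHb directly", {
  ch <- channelInfo(c("S1-D1:760", "S1-D1:850"), "source-detector pair",
                    wavelength = c(760, 850), sourceDetectorDistance = 1)
  dod <- rbind(c(1, -1, 2, -2), c(0.5, -0.5, 1, -1))   # already zero-mean
  od <- Recording(dod, 10, ch, "fnirs_od")
  hemo <- mbllConvert(od, extinction = diag(2), dpf = 1, distance = 1)
  expect_equal(hemo@hbo[1, ], dod[1, ], ignore_attr = TRUE)
  expect_equal(hemo@hbr[1, ], dod[2, ], ignore_attr = TRUE)
})

test_that("singular extinction matrices are rejected with a condition number", {
  ch <- channelInfo(c("S1-D1:760", "S1-D1:850"), "source-detector pair",
                    wavelength = c(760, 850), sourceDetectorDistance = 3)
  od <- Recording(matrix(rnorm(20), 2), 10, ch, "fnirs_od")
  E <- matrix(c(1, 1, 1, 1), 2)
  expect_error(mbllConvert(od, extinction = E), "condition number")
})

test_that("label_segments excludes instructions and counts task/rest blocks", {
  sch <- buildSchedule(ProtocolSpec(), 1)
  seg <- labelSegments(sch)
  expect_equal(sum(seg$class != "rest"), 27L)
  expect_equal(sum(seg$class == "rest"), 27L)
  expect_false("instruction" %in% seg$class)
  expect_equal(unname(table(seg$class[seg$class != "rest"])), rep(9L, 3),
               ignore_attr = TRUE)

  one <- buildSchedule(ProtocolSpec(nSessions = 1, seriesPerCondition = 1,
                                    conditions = "2-back"), 1)
  seg1 <- labelSegments(one)
  expect_equal(nrow(seg1), 2L)

  expect_equal(nrow(labelSegments(list())), 0L)
})

test_that("outlier rejection drops exactly the contaminated window", {
  set.seed(31)
  windows <- lapply(1:10, function(i) matrix(rnorm(3 * 100), 3))
  clean <- rejectOutliers(windows, zMax = 5)
  expect_length(clean$rejected, 0L)
  expect_length(clean$windows, 10L)

  spiked <- windows
  spiked[[4]][2, 50] <- 50 * stats::mad(do.call(cbind, windows)[2, ])
  out <- rejectOutliers(spiked, zMax = 5)
  expect_equal(out$rejected, 4L)
  expect_length(out$windows, 9L)

  idn <- rejectOutliers(spiked, zMax = Inf)
  expect_length(idn$rejected, 0L)

  expect_error(rejectOutliers(windows, zMax = 0), "rejected")
})

test_that("normalization uses training statistics only and flags zero variance", {
  set.seed(32)
  train <- lapply(1:5, function(i) matrix(rnorm(2 * 50, mean = 3, sd = 2), 2))
  norm <- normalizeWindows(train)
  pooled <- do.call(cbind, norm$windows)
  expect_equal(rowMeans(pooled), c(0, 0), tolerance = 1e-10)
  expect_equal(apply(pooled, 1, sd), c(1, 1), tolerance = 1e-10)

  shift <- lapply(train, function(w) w + 1)
  shifted <- normalizeWindows(shift, stats = norm$stats)
  expect_equal(rowMeans(do.call(cbind, shifted$windows)),
               1 / norm$stats$sd, tolerance = 1e-10)

  flat <- lapply(1:3, function(i) rbind(rnorm(10), rep(2, 10)))
  expect_error(normalizeWindows(flat), "zero-variance channel")
})
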