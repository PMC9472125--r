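test_that("EDF round-trips rate, labels and data within 16-bit quantization", {
  rate <- 100
  t <- (0:499) / rate
  x <- rbind(50 * sin(2 * pi * 3 * t), 20 * cos(2 * pi * 7 * t))
  rec <- Recording(x, rate, c("Fz", "Pz"), "eeg")
  f <- tempfile(fileext = ".edf")
  writeRecording(rec, f, format = "edf")
  back <- readEEGEDF(f)$recording
  expect_equal(samplingRate(back), rate)
  expect_equal(channels(back)$label, c("Fz", "Pz"))
  expect_equal(nSamples(back), 500L)
  qtol <- (apply(x, 1, max) - apply(x, 1, min)) / 65535
  for (ch in 1:2)
    expect_lt(max(abs(signalData(back)[ch, ] - x[ch, ])), qtol[ch] * 1.01)
})

test_that("EDF annotations round-trip as an event schedule", {
  rec <- Recording(matrix(sin(1:400 / 7), 1), 100, "Cz", "eeg")
  ev <- EventSchedule(c(0, 2, 42), c(2, 40, 20),
                      c("instruction", "2-back", "rest"))
  f <- tempfile(fileext = ".edf")
  writeRecording(rec, f, format = "edf", events = ev)
  out <- readEEGEDF(f)
  expect_s4_class(out$events, "EventSchedule")
  expect_equal(events(out$events)$label, c("instruction", "2-back", "rest"))
  expect_equal(events(out$events)$onset, c(0, 2, 42))
})

test_that("EDF reader rejects files with duplicate channel labels", {
  rec <- Recording(matrix(rnorm(200), 2), 100, c("A", "B"), "eeg")
  f <- tempfile(fileext = ".edf")
  writeRecording(rec, f, format = "edf")
  # overwrite the second signal's 16-byte label field with the first's
  con <- file(f, "r+b")
  seek(con, 256 + 16, rw = "write")
  writeChar(formatC("A", width = -16), con, 16, eos = NULL)
  close(con)
  expect_error(readEEGEDF(f), "duplicate")
})

test_that("non-EDF input fails naming the offending header field", {
  f <- tempfile()
  writeLines("not an EDF file at all, just text", f)
  expect_error(readEEGEDF(f), "version")
})

test_that("a 30-channel 1 kHz EDF reads back with the acquisition geometry", {
  rec <- Recording(matrix(rnorm(30 * 500), 30), 1000,
                   sprintf("EEG%02d", 1:30), "eeg")
  f <- tempfile(fileext = ".edf")
  writeRecording(rec, f, format = "edf")
  back <- readEEGEDF(f)$recording
  expect_equal(nChannels(back), 30L)
  expect_equal(samplingRate(back), 1000)
})

test_that("SNIRF round-trips optical density recordings at 10.4 Hz", {
  sim <- simulateFNIRS(buildSchedule(shortSpec(), 5), quietProfile(sites = 2))
  rec <- sim$recording
  f <- tempfile(fileext = ".snirf")
  writeRecording(rec, f, format = "snirf")
  back <- readFNIRSSNIRF(f)
  expect_equal(samplingRate(back), 10.4, tolerance = 1e-9)
  expect_equal(modality(back), "fnirs_od")
  expect_equal(nChannels(back), nChannels(rec))
  expect_equal(channels(back)$wavelength, channels(rec)$wavelength)
  expect_equal(channels(back)$sourceDetectorDistance,
               channels(rec)$sourceDetectorDistance, tolerance = 1e-9)
  expect_equal(signalData(back), signalData(rec), tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("16 fNIRS sites export as 32 SNIRF data channels", {
  sim <- simulateFNIRS(buildSchedule(shortSpec(stimuli = 2, rest = 4), 5),
                       quietProfile(sites = 16))
  f <- tempfile(fileext = ".snirf")
  writeRecording(sim$recording, f, format = "snirf")
  ls <- rhdf5::h5ls(f)
  rhdf5::h5closeAll()
  expect_equal(sum(grepl("^measurementList[0-9]+$", ls$name)), 32L)
})

test_that("single-wavelength SNIRF is rejected (Beer-Lambert needs two)", {
  n <- 40
  ch <- channelInfo(c("S1-D1:760", "S2-D2:760"),
                    role = "source-detector pair", wavelength = 760,
                    sourceDetectorDistance = 3)
  rec <- Recording(matrix(rnorm(2 * n, sd = 1e-3), 2), 10.4, ch, "fnirs_od")
  f <- tempfile(fileext = ".snirf")
  neurorp:::.write_snirf(rec, f)
  expect_error(readFNIRSSNIRF(f), "at least 2")
})

test_that("amplitude-typed SNIRF converts to OD against hand computation", {
  f <- tempfile(fileext = ".snirf")
  amp1 <- c(1.0, 1.1, 0.9, 1.05, 0.95)
  amp2 <- c(2.0, 2.2, 1.9, 2.05, 2.1)
  rhdf5::h5createFile(f)
  rhdf5::h5write("1.0", f, "formatVersion")
  rhdf5::h5createGroup(f, "nirs")
  rhdf5::h5createGroup(f, "nirs/data1")
  rhdf5::h5write(cbind(amp1, amp2), f, "nirs/data1/dataTimeSeries")
  rhdf5::h5write((0:4) / 10.4, f, "nirs/data1/time")
  for (i in 1:2) {
    g <- sprintf("nirs/data1/measurementList%d", i)
    rhdf5::h5createGroup(f, g)
    rhdf5::h5write(1L, f, paste0(g, "/sourceIndex"))
    rhdf5::h5write(1L, f, paste0(g, "/detectorIndex"))
    rhdf5::h5write(i, f, paste0(g, "/wavelengthIndex"))
    rhdf5::h5write(1L, f, paste0(g, "/dataType"))
  }
  rhdf5::h5createGroup(f, "nirs/probe")
  rhdf5::h5write(c(760, 850), f, "nirs/probe/wavelengths")
  rhdf5::h5closeAll()
  rec <- readFNIRSSNIRF(f, distance = 3)
  expect_equal(signalData(rec)[1, ], -log(amp1 / mean(amp1)),
               ignore_attr = TRUE)
  expect_equal(signalData(rec)[2, ], -log(amp2 / mean(amp2)),
               ignore_attr = TRUE)
})

test_that("SNIRF without probe geometry demands an explicit distance", {
  f <- tempfile(fileext = ".snirf")
  rhdf5::h5createFile(f)
  rhdf5::h5write("1.0", f, "formatVersion")
  rhdf5::h5createGroup(f, "nirs")
  rhdf5::h5createGroup(f, "nirs/data1")
  rhdf5::h5write(matrix(rnorm(10), 5), f, "nirs/data1/dataTimeSeries")
  rhdf5::h5write((0:4) / 10, f, "nirs/data1/time")
  for (i in 1:2) {
    g <- sprintf("nirs/data1/measurementList%d", i)
    rhdf5::h5createGroup(f, g)
    rhdf5::h5write(1L, f, paste0(g, "/sourceIndex"))
    rhdf5::h5write(1L, f, paste0(g, "/detectorIndex"))
    rhdf5::h5write(i, f, paste0(g, "/wavelengthIndex"))
    rhdf5::h5write(99999L, f, paste0(g, "/dataType"))
  }
  rhdf5::h5createGroup(f, "nirs/probe")
  rhdf5::h5write(c(760, 850), f, "nirs/probe/wavelengths")
  rhdf5::h5closeAll()
  expect_error(readFNIRSSNIRF(f), "distance")
  expect_s4_class(readFNIRSSNIRF(f, distance = 3), "Recording")
})

test_that("event tables read, validate and reject unknown or overlapping labels", {
  f <- tempfile(fileext = ".tsv")
  writeLines(c("onset\tduration\tlabel",
               "0\t2\tinstruction", "2\t40\t2-back", "42\t20\trest"), f)
  sch <- readEventsTable(f)
  expect_equal(nrow(events(sch)), 3L)
  expect_equal(sum(events(sch)$duration), 62)

  writeLines("onset\tduration\tlabel", f)
  expect_equal(nrow(events(readEventsTable(f))), 0L)

  writeLines(c("onset\tduration\tlabel", "0\t5\t2-back", "3\t5\trest"), f)
  expect_error(readEventsTable(f), "overlap")

  writeLines(c("onset\tduration\tlabel", "0\t5\t9-back"), f)
  expect_error(readEventsTable(f), "0-back")
})

test_that("event tables written by the package read back identically", {
  sch <- buildSchedule(shortSpec(), 3)
  f <- tempfile(fileext = ".tsv")
  writeEventsTable(sch, f)
  all_ev <- do.call(rbind, lapply(sch, events))
  back <- readEventsTable(f)
  expect_equal(events(back), all_ev, ignore_attr = TRUE)
})

test_that("the container format is bit-lossless", {
  rec <- Recording(matrix(rnorm(300), 3), 123.456,
                   c("a", "b", "c"), "eeg", startTime = 1.5)
  f <- tempfile(fileext = ".rds")
  writeRecording(rec, f, format = "container")
  back <- readContainer(f)$recording
  expect_identical(signalData(back), signalData(rec))
  expect_identical(samplingRate(back), samplingRate(rec))
  expect_identical(channels(back)$label, channels(rec)$label)
})

test_that("invalid recordings are rejected before any file is written", {
  rec <- Recording(matrix(rnorm(100), 1), 100, "a", "eeg")
  methods::slot(rec, "rate", check = FALSE) <- 0
  f <- tempfile(fileext = ".edf")
  expect_error(writeRecording(rec, f, format = "edf"), "rate")
  expect_false(file.exists(f))
})

test_that("format/modality mismatches are refused", {
  eeg <- Recording(matrix(rnorm(100), 1), 100, "a", "eeg")
  expect_error(writeRecording(eeg, tempfile(), format = "snirf"), "fnirs_od")
  od <- simulateFNIRS(buildSchedule(shortSpec(), 1), quietProfile())$recording
  expect_error(writeRecording(od, tempfile(), format = "edf"), "eeg")
})
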