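test_that("epoch extraction follows the half-open 0-based sample convention", {
  set.seed(1)
  rec <- ContinuousRecording(matrix(rnorm(2 * 1000), 2, 1000), srate = 100)
  ev <- EventTable(onsets = seq(100L, 800L, by = 100L), labels = rep("std", 8))
  ep <- extractEpochs(rec, ev, "std", tmin = -0.3, tmax = 0.7)
  expect_equal(nTrials(ep), 8)
  expect_equal(dim(recordingData(ep))[2], 100)
  expect_equal(epochTimes(ep)[1], -0.3)
  expect_equal(diff(epochTimes(ep))[1], 1 / 100)
  # trial 1 covers samples 70..169 (0-based), i.e. columns 71..170
  expect_identical(recordingData(ep)[, , 1],
                   recordingData(rec)[, 71:170])
})

test_that("an event at sample 0 with tmin = 0 yields a trial starting at sample 0", {
  rec <- ContinuousRecording(matrix(1:200, 2, 100, byrow = TRUE), srate = 100)
  ev <- EventTable(onsets = 0L, labels = "x")
  ep <- extractEpochs(rec, ev, "x", tmin = 0, tmax = 0.1)
  expect_equal(nTrials(ep), 1)
  expect_identical(recordingData(ep)[, , 1], recordingData(rec)[, 1:10])
  expect_equal(epochTimes(ep)[1], 0)
})

test_that("out-of-bounds events are dropped and counted; retained + dropped add up", {
  set.seed(2)
  rec <- ContinuousRecording(matrix(rnorm(500), 1, 500), srate = 100)
  ev <- EventTable(onsets = c(10L, 200L, 480L), labels = rep("x", 3))
  expect_message(
    ep <- extractEpochs(rec, ev, "x", tmin = -0.3, tmax = 0.7),
    "dropped 2")
  expect_equal(nTrials(ep) + attr(ep, "nDropped"), 3)
  # concatenating the extracted trials reproduces the source bit-exactly
  expect_identical(as.vector(recordingData(ep)[, , 1]),
                   as.vector(recordingData(rec)[1, 171:270]))
})

test_that("epoch extraction rejects bad inputs", {
  rec <- ContinuousRecording(matrix(0, 1, 100), srate = 100)
  ev <- EventTable(onsets = 50L, labels = "x")
  expect_error(extractEpochs(rec, ev, "missing"), "empty condition")
  expect_error(extractEpochs(rec, ev, "x", tmin = 0.5, tmax = 0.5),
               "invalid window")
})

test_that("container round trips are bit-exact for recordings and epoch sets", {
  set.seed(3)
  rec <- ContinuousRecording(matrix(rnorm(20), 2, 10), srate = 250,
                             channelLabels = c("Cz", "Pz"),
                             channelPositions = erpsig:::.spiralPositions(2),
                             subjectId = "S07")
  tf <- tempfile(fileext = ".ers")
  writeContainer(rec, tf)
  back <- readContainer(tf)
  expect_identical(recordingData(back), recordingData(rec))
  expect_identical(channelLabels(back), channelLabels(rec))
  expect_identical(channelPositions(back), channelPositions(rec))
  expect_identical(samplingRate(back), samplingRate(rec))
  expect_identical(subjectId(back), subjectId(rec))

  ep <- makeEpochSet(3, 5, 3, condition = "odd", subjectId = "S08")
  tf2 <- tempfile(fileext = ".ers")
  writeContainer(ep, tf2)
  back2 <- readContainer(tf2)
  expect_identical(recordingData(back2), recordingData(ep))
  expect_identical(epochTimes(back2), epochTimes(ep))
  expect_identical(condition(back2), condition(ep))
})

test_that("malformed containers report the missing field", {
  tf <- tempfile()
  saveRDS(list(type = "ContinuousRecording", data = matrix(0, 1, 4),
               labels = "Ch1", positions = matrix(numeric(0), 0, 3),
               subject_id = "s"), tf)
  expect_error(readContainer(tf), "missing field: srate")
  expect_error(readContainer(tempfile()), "no such container")
})

test_that("channel selection at read time drops auxiliary channels", {
  rec <- ContinuousRecording(matrix(1:30, 3, 10, byrow = TRUE), srate = 100,
                             channelLabels = c("Cz", "EXG1", "Pz"))
  tf <- tempfile()
  writeContainer(rec, tf)
  eeg <- readContainer(tf, channels = c("Cz", "Pz"))
  expect_identical(channelLabels(eeg), c("Cz", "Pz"))
  expect_identical(recordingData(eeg), recordingData(rec)[c(1, 3), ])
})

test_that("events TSV is parsed with onset rounding to the sample grid", {
  tf <- tempfile(fileext = ".tsv")
  writeLines(c("onset\ttrial_type", "0.5\ttarget", "1.0\tstandard"), tf)
  ev <- readEventsTsv(tf, srate = 250)
  expect_identical(eventOnsets(ev), c(125L, 250L))
  expect_identical(eventLabels(ev), c("target", "standard"))

  # header-only and zero-byte files give an empty table
  tf2 <- tempfile(fileext = ".tsv")
  writeLines("onset\ttrial_type", tf2)
  expect_equal(length(eventOnsets(readEventsTsv(tf2, 250))), 0)
  tf3 <- tempfile(fileext = ".tsv")
  file.create(tf3)
  expect_equal(length(eventOnsets(readEventsTsv(tf3, 250))), 0)
})

test_that("events TSV errors are explicit", {
  tf <- tempfile(fileext = ".tsv")
  writeLines(c("time\ttrial_type", "0.5\tx"), tf)
  expect_error(readEventsTsv(tf, 250), "missing column: onset")
  tf2 <- tempfile(fileext = ".tsv")
  writeLines(c("onset\ttrial_type", "1.0\tx", "0.5\ty"), tf2)
  expect_error(readEventsTsv(tf2, 250), "strictly increasing")
  expect_error(readEventsTsv(tf, NULL), "unknown srate")
})

test_that("container classes enforce their invariants", {
  expect_error(ContinuousRecording(matrix(c(1, NA), 1, 2), srate = 100),
               "NA/NaN/Inf")
  expect_error(ContinuousRecording(matrix(0, 1, 2), srate = -1), "positive")
  badPos <- matrix(c(2, 0, 0), 1, 3)
  expect_error(ContinuousRecording(matrix(0, 1, 2), srate = 100,
                                   channelPositions = badPos), "unit sphere")
  expect_error(EventTable(onsets = c(5L, 5L), labels = c("a", "b")),
               "strictly increasing")
  expect_error(EpochSet(array(0, c(1, 3, 1)), times = c(0, 0.1, 0.15),
                        srate = 10), "uniformly spaced")
  expect_error(EpochSet(array(0, c(1, 3, 1)), times = (0:2) / 10, srate = 10,
                        condition = ""), "non-empty")
})
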