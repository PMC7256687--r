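test_that("earlobe rereferencing subtracts the earlobe mean", {
  fs <- 500
  n <- 1000
  sig <- rbind(F3 = rep(10, n), C3 = rep(-2, n),
               A1 = rep(2, n), A2 = rep(4, n))
  rec <- eegRecording(sig, fs)
  out <- rereferenceAverageEarlobes(rec)
  expect_identical(out@channelNames, c("F3", "C3"))
  expect_equal(out@signal["F3", ], rep(7, n))
  expect_equal(out@signal["C3", ], rep(-5, n))
  expect_identical(out@reference, "linked-earlobes")

  # zero earlobes leave the signal unchanged
  sig0 <- rbind(F3 = rnorm(n), A1 = rep(0, n), A2 = rep(0, n))
  out0 <- rereferenceAverageEarlobes(eegRecording(sig0, fs))
  expect_equal(out0@signal["F3", ], sig0["F3", ])

  expect_error(rereferenceAverageEarlobes(
    eegRecording(rbind(F3 = rnorm(n), A1 = rnorm(n)), fs)), "A2")
})

test_that("a common-mode component is removed to numerical tolerance", {
  fs <- 500
  t <- seq_len(5000) / fs
  common <- 30 * sin(2 * pi * 7 * t)
  set.seed(1)
  own <- matrix(rnorm(2 * 5000), 2)
  sig <- rbind(F3 = own[1, ] + common, C3 = own[2, ] + common,
               A1 = common, A2 = common)
  out <- rereferenceAverageEarlobes(eegRecording(sig, fs))
  expect_lt(max(abs(out@signal["F3", ] - own[1, ])), 1e-9 * 30)
})

test_that("filtering removes DC, notches 50 Hz, and passes 10 Hz with zero phase", {
  fs <- 500
  n <- 20 * fs
  t <- seq_len(n) / fs
  x10 <- sin(2 * pi * 10 * t)
  x50 <- sin(2 * pi * 50 * t)
  rec <- eegRecording(rbind(5 + x10 + x50), fs)
  out <- filterEEG(rec)
  mid <- (5 * fs):(15 * fs)    # avoid edge transients
  y <- out@signal[1, mid]
  # DC attenuated far beyond 60 dB
  expect_lt(abs(mean(y)), 1e-3)
  # 50 Hz residual amplitude below 3% of the input tone (> 30 dB)
  a50 <- 2 * sqrt(mean(y * sin(2 * pi * 50 * t[mid]))^2 +
                    mean(y * cos(2 * pi * 50 * t[mid]))^2)
  expect_lt(a50, 0.03)
  # passband gain within 5%, zero phase: cross-correlation peak at lag 0
  ccf <- sapply(-3:3, function(l)
    sum(y * x10[mid + l]))
  expect_equal(which.max(ccf), 4L)
  gain <- 2 * mean(y * sin(2 * pi * 10 * t[mid]))
  expect_lt(abs(gain - 1), 0.05)
})

test_that("a pure DC offset is attenuated by more than 60 dB", {
  rec <- eegRecording(matrix(3, 1, 3000), 500)
  out <- filterEEG(rec)
  expect_lt(max(abs(out@signal[1, 500:2500])) / 3, 1e-3)
})

test_that("clean bounded noise produces an empty artifact mask", {
  set.seed(8)
  # SD 5 uV white noise cannot trip the 50 uV step or 200 uV range
  # rules, and its 100 ms range never drops under 0.5 uV
  rec <- eegRecording(matrix(rnorm(2 * 30 * 500, sd = 5), 2), 500)
  out <- detectArtifacts(rec)
  expect_false(any(out@artifactMask))
})

test_that("a voltage step marks +/- 100 ms around the jump", {
  fs <- 500
  x <- rnorm(10 * fs, sd = 3)
  t0 <- 5 * fs
  x[t0:length(x)] <- x[t0:length(x)] + 300
  rec <- detectArtifacts(eegRecording(rbind(x), fs))
  mask <- rec@artifactMask
  expect_true(all(mask[(t0 - 0.1 * fs):(t0 + 0.1 * fs)]))
  expect_false(any(mask[seq_len(t0 - 0.3 * fs)]))
})

test_that("a flat stretch is marked with a +/- 500 ms surround", {
  fs <- 500
  set.seed(3)
  x <- rnorm(10 * fs, sd = 5)
  t0 <- 5 * fs
  flat <- t0:(t0 + 0.15 * fs - 1)
  x[flat] <- x[t0]
  rec <- detectArtifacts(eegRecording(rbind(x), fs))
  mask <- rec@artifactMask
  marked <- range(which(mask))
  expect_lte(marked[1], t0 - 0.5 * fs + 1)
  expect_gte(marked[2], max(flat) + 0.5 * fs - 1)
  # total marked window at least 1100 ms
  expect_gte(diff(marked) + 1, 1.1 * fs)
})

test_that("high-amplitude excursions within 200 ms are caught", {
  fs <- 500
  set.seed(4)
  x <- rnorm(10 * fs, sd = 5)
  t0 <- 4 * fs
  len <- 0.15 * fs
  # smooth bump: no single-sample step above 50 uV, range > 200 uV
  x[t0:(t0 + len - 1)] <- x[t0:(t0 + len - 1)] +
    250 * sin(pi * seq_len(len) / len)^2
  expect_lt(max(abs(diff(x))), 50)
  rec <- detectArtifacts(eegRecording(rbind(x), fs))
  expect_true(any(rec@artifactMask[t0:(t0 + len)]))
})

test_that("rest segmentation yields one segment per clean second", {
  fs <- 500
  lay <- taskEventLayout(fs = fs, restDurationS = 180, nTrials = 1L,
                         conditions = "learning")
  set.seed(9)
  rec <- eegRecording(matrix(rnorm(2 * lay$durationS * fs, sd = 5), 2),
                      fs, events = lay$events)
  rec <- detectArtifacts(rec)
  segs <- segmentEEG(rec, "rest", participantId = "P1")
  expect_length(segs, 180L)
  expect_identical(ncol(segs[[1]]@data), 500L)
  expect_identical(segs[[1]]@condition, "rest")
})

test_that("event-locked segmentation yields one segment per clean event", {
  fs <- 500
  lay <- taskEventLayout(fs = fs, restDurationS = 2, nTrials = 72L,
                         conditions = "learning")
  set.seed(10)
  rec <- eegRecording(matrix(rnorm(lay$durationS * fs, sd = 5), 1), fs,
                      events = lay$events)
  rec <- detectArtifacts(rec)
  segs <- segmentEEG(rec, "event_locked", participantId = "P1")
  expect_length(segs, 72L)
  # window runs from -100 ms to +900 ms around onset
  ev1 <- rec@events$sample[rec@events$condition == "learning"][1]
  expect_identical(segs[[1]]@onsetSample, as.integer(ev1 - 0.1 * fs))

  # one masked sample inside one event window drops exactly that segment
  rec2 <- rec
  rec2@artifactMask[ev1 + 10L] <- TRUE
  segs2 <- segmentEEG(rec2, "event_locked")
  expect_length(segs2, 71L)
  expect_identical(attr(segs2, "skippedArtifact"), 1L)
})

test_that("events too close to the recording edge are skipped with a count", {
  fs <- 500
  ev <- data.frame(sample = c(10L, 2000L), condition = "recall",
                   session = 1L, duration = 0L)
  set.seed(2)
  rec <- eegRecording(matrix(rnorm(5 * fs, sd = 5), 1), fs, events = ev)
  rec <- detectArtifacts(rec)
  expect_message(segs <- segmentEEG(rec, "event_locked"), "edge")
  expect_length(segs, 1L)
  expect_identical(attr(segs, "skippedEdge"), 1L)
})

test_that("segment length follows the sampling rate", {
  fs <- 250
  lay <- taskEventLayout(fs = fs, restDurationS = 5, nTrials = 1L)
  set.seed(11)
  rec <- eegRecording(matrix(rnorm(lay$durationS * fs, sd = 5), 1), fs,
                      events = lay$events)
  rec <- detectArtifacts(rec)
  segs <- segmentEEG(rec, "rest")
  expect_identical(ncol(segs[[1]]@data), 250L)
})

test_that("rest segment count decreases monotonically with artifact rate", {
  fs <- 500
  lay <- taskEventLayout(fs = fs, restDurationS = 60, nTrials = 1L)
  base <- generateMVAREEG(NULL, nChannels = 2L, fs = fs,
                          durationS = lay$durationS, seed = 31,
                          events = lay$events)
  counts <- sapply(c(0, 2, 8), function(rate) {
    inj <- injectArtifacts(base, ratePerMin = rate, seed = 17)
    rec <- detectArtifacts(inj$recording)
    length(segmentEEG(rec, "rest"))
  })
  expect_true(all(diff(counts) <= 0))
  expect_identical(counts[1], 60L)
})
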