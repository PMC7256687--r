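test_that("identical spec and seed give a bit-identical cohort", {
  spec <- cohortSpec(groupSizes = c(MCI = 3L, HC = 3L),
                     modalities = "psy", seed = 5L)
  c1 <- generateCohort(spec)
  c2 <- generateCohort(spec)
  expect_identical(c1, c2)
  c3 <- generateCohort(cohortSpec(groupSizes = c(MCI = 3L, HC = 3L),
                                  modalities = "psy", seed = 6L))
  expect_false(identical(c1$neuropsych$raw, c3$neuropsych$raw))
})

test_that("uncoupled channels show no cross-channel coherence", {
  rec <- generateMVAREEG(NULL, nChannels = 2L, fs = 500,
                         durationS = 40, seed = 2)
  fit <- fitMVAR(rec@signal, order = 4L)
  coh <- bandAverage(computeMeasure(spectralSet(fit),
                                    "coherence_real"))
  expect_lt(max(abs(coh[, 1, 2])), 0.1)
})

test_that("planted coupling is recovered as directional PDC", {
  coup <- data.frame(from = 1L, to = 2L, lag = 1L, strength = 0.5)
  rec <- generateMVAREEG(coup, nChannels = 2L, fs = 500,
                         durationS = 200, seed = 3, obsNoiseSD = 0.1)
  fit <- fitMVAR(rec@signal, order = 4L)
  pdc <- bandAverage(computeMeasure(spectralSet(fit), "PDC"))
  # influence 1 -> 2 dominates around the oscillators' alpha resonance
  expect_gt(pdc["alpha", 2, 1], pdc["alpha", 1, 2])
})

test_that("a 3-minute rest recording yields 180 one-second epochs", {
  lay <- taskEventLayout(fs = 500, restDurationS = 180, nTrials = 1L,
                         conditions = "learning")
  rec <- generateMVAREEG(NULL, nChannels = 2L, fs = 500,
                         durationS = lay$durationS, seed = 4,
                         events = lay$events)
  rec <- detectArtifacts(rec)
  expect_length(segmentEEG(rec, "rest"), 180L)
})

test_that("unstable coupling specifications are rejected explicitly", {
  coup <- data.frame(from = c(1L, 2L), to = c(2L, 1L),
                     lag = 1L, strength = 2)
  expect_error(generateMVAREEG(coup, nChannels = 2L, fs = 500,
                               durationS = 1, seed = 1),
               "unstable")
})

test_that("zero artifact rate returns the recording unchanged", {
  rec <- generateMVAREEG(NULL, nChannels = 2L, fs = 500, durationS = 5,
                         seed = 6)
  out <- injectArtifacts(rec, ratePerMin = 0)
  expect_identical(out$recording@signal, rec@signal)
  expect_identical(nrow(out$truth), 0L)
})

test_that("injected steps are found by the detector at the right time", {
  rec <- generateMVAREEG(NULL, nChannels = 2L, fs = 500,
                         durationS = 30, seed = 7)
  inj <- injectArtifacts(rec, ratePerMin = 4, types = "step", seed = 8)
  expect_gt(nrow(inj$truth), 0L)
  det <- detectArtifacts(inj$recording)
  for (s in inj$truth$sample)
    expect_true(any(det@artifactMask[(s - 50):(s + 50)]))
})

test_that("injected flat stretches trigger the low-difference rule", {
  rec <- generateMVAREEG(NULL, nChannels = 2L, fs = 500,
                         durationS = 30, seed = 9)
  inj <- injectArtifacts(rec, ratePerMin = 2, types = "flat", seed = 10)
  det <- detectArtifacts(inj$recording)
  fs <- 500
  for (s in inj$truth$sample) {
    lo <- max(1L, s - 0.5 * fs)
    expect_true(all(det@artifactMask[lo:s]))
  }
})

test_that("sub-threshold artifact amplitudes warn about undetectability", {
  rec <- generateMVAREEG(NULL, nChannels = 1L, fs = 500, durationS = 10,
                         seed = 11)
  expect_warning(injectArtifacts(rec, ratePerMin = 2, stepAmplitude = 20,
                                 types = "step", seed = 1),
                 "undetectable")
})

test_that("region packing failures name the offending labels", {
  expect_error(generateLabeledVolume(
    mriSpec(dims = c(16, 16, 16), nRegions = 9L, grid = c(2L, 2L, 2L))),
    "9")
})

test_that("decliner participants get shifted volumes in effect regions", {
  spec <- mriSpec(dims = c(32, 32, 32), nRegions = 8L,
                  grid = c(2L, 2L, 2L), volumePerturbSD = 0.01)
  eff <- list(volumeScale = c("1" = 0.7, "2" = 0.7))
  v0 <- normalizedVolumetry(generateLabeledVolume(spec, seed = 1))
  v1 <- normalizedVolumetry(generateLabeledVolume(
    spec, participantEffect = eff, seed = 1))
  expect_lt(v1[["region1"]], v0[["region1"]])
  expect_lt(v1[["region2"]], v0[["region2"]])
  expect_gt(v1[["region5"]], v0[["region5"]])  # renormalization
})

test_that("zero decline fractions give all-zero labels downstream", {
  spec <- cohortSpec(groupSizes = c(HC = 6L), modalities = "psy",
                     decline = declineSpec(fractions = c(
                       executive = 0, visual_verbal_memory = 0,
                       divided_attention = 0, depression = 0)),
                     seed = 9L)
  co <- generateCohort(spec)
  lab <- declineLabels(zscoreTable(co$neuropsych))
  expect_true(all(lab$label == 0L))
})

test_that("planted improvements are not labelled as decline", {
  # dropSD < 0 plants an improvement on the target subscale
  asn <- makeAssign(4L, decliners = 1:2)
  np <- generateNeuropsych(asn, spec = declineSpec(dropSD = -1.2),
                           seed = 2)
  lab <- declineLabels(zscoreTable(np))
  expect_true(all(lab$label[lab$domain == "executive"] == 0L))
})

test_that("generator ground truth matches decline labels end to end", {
  spec <- cohortSpec(groupSizes = c(MCI = 10L, HC = 10L),
                     modalities = "psy", seed = 12L)
  co <- generateCohort(spec)
  lab <- declineLabels(zscoreTable(co$neuropsych))
  gt <- co$groundTruth$declineLabels
  for (d in c("executive", "visual_verbal_memory", "divided_attention",
              "depression")) {
    got <- lab$label[lab$domain == d][
      match(gt$participant_id, lab$participant_id[lab$domain == d])]
    expect_identical(got, gt[[d]], info = d)
  }
})

test_that("informative feature identifiers resolve to sample table columns", {
  spec <- cohortSpec(
    groupSizes = c(MCI = 3L, HC = 3L),
    eeg = list(restDurationS = 4, nTrials = 2L, conditions = "learning"),
    mri = list(dims = c(24L, 24L, 24L), nRegions = 6L,
               grid = c(2L, 2L, 2L), effectRegions = 1:2),
    seed = 13L)
  co <- generateCohort(spec)
  # EEG connectivity features per participant (rest segments)
  segs <- list()
  for (pid in names(co$eeg)) {
    rec <- detectArtifacts(filterEEG(co$eeg[[pid]]$recording))
    segs <- c(segs, segmentEEG(rec, "rest", participantId = pid))
  }
  eegF <- segmentFeatureMatrix(segs, measures = "PDC")
  mriF <- do.call(rbind, lapply(co$mri, function(v)
    mriFeatureVector(v, types = "volumetry")))
  psyF <- baselineFeatures(zscoreTable(co$neuropsych))
  labels <- data.frame(
    participant_id = co$participants$participant_id,
    label = co$participants$executive)
  st <- assembleSamples(eegFeatures = eegF, mriFeatures = mriF,
                        psyFeatures = psyF, labels = labels)
  feats <- rownames(SummarizedExperiment::assay(st))
  for (id in co$groundTruth$informativeFeatures)
    expect_true(id %in% feats, info = id)
})

test_that("cohort EEG recordings segment into the expected epoch counts", {
  spec <- cohortSpec(groupSizes = c(HC = 1L),
                     eeg = list(restDurationS = 20, nTrials = 5L,
                                conditions = c("learning", "recall")),
                     modalities = "eeg", seed = 14L)
  co <- generateCohort(spec)
  rec <- detectArtifacts(filterEEG(co$eeg[[1]]$recording))
  expect_length(segmentEEG(rec, "rest"), 20L)
  expect_length(segmentEEG(rec, "event_locked",
                           condition = "learning"), 5L)
})
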