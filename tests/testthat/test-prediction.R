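test_that("assembly replicates participant-constant blocks over segments", {
  eeg <- matrix(rnorm(6 * 4), 6,
                dimnames = list(NULL, paste0("e", 1:4)))
  attr(eeg, "participant_id") <- rep(c("P1", "P2"), each = 3)
  mri <- matrix(1:4, 2, dimnames = list(c("P1", "P2"), c("m1", "m2")))
  labels <- data.frame(participant_id = c("P1", "P2"), label = c(1L, 0L))
  st <- assembleSamples(eegFeatures = eeg, mriFeatures = mri,
                        labels = labels)
  x <- sampleMatrix(st)
  expect_identical(nrow(x), 6L)
  info <- sampleInfo(st)
  expect_true(all(x[info$participant_id == "P1", "m1"] == 1))
  expect_true(all(x[info$participant_id == "P2", "m2"] == 4))
  expect_identical(info$label, rep(c(1L, 0L), each = 3))
  mod <- SummarizedExperiment::rowData(st)$modality
  expect_identical(as.integer(table(mod)[c("eeg", "mri")]),
                   c(4L, 2L))
})

test_that("designs without EEG have one sample per participant", {
  mri <- matrix(rnorm(8), 4,
                dimnames = list(paste0("P", 1:4), c("m1", "m2")))
  labels <- data.frame(participant_id = paste0("P", 1:4),
                       label = c(1L, 1L, 0L, 0L))
  st <- assembleSamples(mriFeatures = mri, labels = labels)
  expect_identical(nrow(sampleMatrix(st)), 4L)
  expect_error(assembleSamples(labels = labels), "at least one")
})

test_that("class imbalance below 30% triggers a warning", {
  mri <- matrix(rnorm(20), 10,
                dimnames = list(paste0("P", 1:10), c("a", "b")))
  labels <- data.frame(participant_id = paste0("P", 1:10),
                       label = c(1L, rep(0L, 9)))
  expect_warning(assembleSamples(mriFeatures = mri, labels = labels),
                 "imbalance")
})

test_that("grouped folds keep participants whole and stratified", {
  pids <- paste0("P", 1:10)
  labs <- rep(c(0L, 1L), 5)
  f <- groupedFolds(pids, labs, 5L, seed = 3)
  expect_identical(sort(as.integer(table(f))), rep(2L, 5))
  # every fold holds one participant of each class
  for (k in 1:5)
    expect_setequal(labs[f == k], c(0L, 1L))
  expect_identical(f, groupedFolds(pids, labs, 5L, seed = 3))
  expect_error(groupedFolds(pids[1:3], labs[1:3], 5L), "3 participants")
})

test_that("the linear 2-norm SVM separates separable data", {
  set.seed(1)
  x <- rbind(matrix(rnorm(40, 3), 20), matrix(rnorm(40, -3), 20))
  y <- rep(c(1, 0), each = 20)
  fit <- l2svm(x, y)
  expect_identical(predict(fit, x)$predicted, as.integer(y))
  expect_error(l2svm(x, rep(1, 40)), "single class")
})

test_that("removing a non-support vector leaves the decision unchanged", {
  set.seed(2)
  x <- rbind(matrix(rnorm(30, 2.5), 15), matrix(rnorm(30, -2.5), 15))
  y <- rep(c(1, 0), each = 15)
  fit <- l2svm(x, y, cost = 1)
  dec <- predict(fit, x)$decision
  margin <- (2 * y - 1) * dec
  far <- which.max(margin)          # deepest zero-loss point
  expect_gt(margin[far], 1)
  fit2 <- l2svm(x[-far, ], y[-far], cost = 1)
  expect_equal(fit2$w, fit$w, tolerance = 1e-6)
  expect_equal(fit2$b, fit$b, tolerance = 1e-6)
})

test_that("the SVM agrees with an independent implementation on clean data", {
  set.seed(3)
  x <- rbind(matrix(rnorm(60, 2), 30), matrix(rnorm(60, -2), 30))
  y <- rep(c(1, 0), each = 30)
  fit <- l2svm(x, y)
  ours <- predict(fit, x)$predicted
  ref <- e1071::svm(x, factor(y), kernel = "linear", scale = FALSE)
  theirs <- as.integer(as.character(predict(ref, x)))
  expect_gt(mean(ours == theirs), 0.97)
})

test_that("label permutation yields chance-level cross-validated accuracy", {
  set.seed(4)
  accs <- replicate(20, {
    x <- matrix(rnorm(60 * 5), 60)
    y <- rep(c(1L, 0L), 30)
    tr <- sample(60, 40)
    te <- setdiff(seq_len(60), tr)
    fit <- l2svm(x[tr, ], y[tr])
    pr <- predict(fit, x[te, ])$predicted
    mean(c(mean(pr[y[te] == 1] == 1), mean(pr[y[te] == 0] == 0)),
         na.rm = TRUE)
  })
  expect_lt(abs(mean(accs) - 0.5), 0.1)
})

test_that("greedy selection finds a perfectly separating feature first", {
  hits <- 0
  for (seed in 1:20) {
    set.seed(seed)
    n <- 30
    y <- rep(c(1L, 0L), n / 2)
    x <- matrix(rnorm(n * 50), n)
    x[, 37] <- y * 6 + rnorm(n, sd = 0.3)   # planted separator
    colnames(x) <- paste0("f", 1:50)
    sel <- greedyFSS(x, y, groups = paste0("P", seq_len(n)), cap = 3L,
                     k = 3L, seed = seed)
    if (length(sel) && sel[1] == "f37") hits <- hits + 1
  }
  expect_gte(hits, 19)
})

test_that("selection respects the cap and survives constant features", {
  set.seed(5)
  n <- 20
  y <- rep(c(1L, 0L), n / 2)
  x <- matrix(rnorm(n * 40), n)
  colnames(x) <- paste0("f", 1:40)
  sel <- greedyFSS(x, y, groups = paste0("P", seq_len(n)), cap = 4L,
                   k = 3L, seed = 1)
  expect_lte(length(sel), 4L)
  xc <- matrix(1, n, 5, dimnames = list(NULL, paste0("c", 1:5)))
  selc <- greedyFSS(xc, y, groups = paste0("P", seq_len(n)), cap = 4L,
                    k = 3L, seed = 1)
  expect_lte(length(selc), 1L)
})

test_that("nested CV keeps train and test participants disjoint", {
  st <- plantedTable(nPer = 8L, nNoise = 10L, seed = 6)
  for (seed in c(1L, 2L, 3L)) {
    res <- nestedCV(st, cvConfig(featureCap = 3L, seed = seed))
    expect_length(intersect(res@folds$outerTest, res@folds$outerTrain),
                  0L)
    expect_true(all(res@predictions$participant_id %in%
                      res@folds$outerTest))
    expect_true(all(res@selectionFrequency <= 5L))
    expect_lte(length(res@finalSubset), 3L)
  }
})

test_that("planted informative features dominate selection and accuracy", {
  st <- plantedTable(nPer = 12L, nNoise = 30L, nInf = 2L, effect = 3,
                     seed = 7)
  res <- nestedCV(st, cvConfig(featureCap = 5L, seed = 11))
  sf <- res@selectionFrequency
  inf <- sf[grepl("^inf", names(sf))]
  expect_gte(max(inf), 4L)
  m <- cvMetrics(res)
  bal <- mean(c(m$participant["sensitivity"],
                m$participant["specificity"]))
  expect_gte(bal, 90)
})

test_that("pure-noise feature padding does not inflate held-out accuracy", {
  bal <- function(st, seed) {
    m <- cvMetrics(nestedCV(st, cvConfig(featureCap = 3L, seed = seed)))
    mean(c(m$participant["sensitivity"], m$participant["specificity"]))
  }
  diffs <- sapply(1:6, function(seed) {
    set.seed(seed)
    n <- 16L
    lab <- rep(c(1L, 0L), each = n / 2)
    base <- matrix(rnorm(n * 7), n,
                   dimnames = list(sprintf("P%03d", 1:n),
                                   c(paste0("inf", 1:2),
                                     paste0("noise", 1:5))))
    base[, 1:2] <- base[, 1:2] + 2.5 * lab
    pad <- matrix(rnorm(n * 40), n,
                  dimnames = list(rownames(base), paste0("pad", 1:40)))
    labels <- data.frame(participant_id = rownames(base), label = lab)
    lean <- assembleSamples(psyFeatures = base, labels = labels)
    fat <- assembleSamples(psyFeatures = cbind(base, pad),
                           labels = labels)
    bal(fat, seed) - bal(lean, seed)
  })
  expect_lte(mean(diffs) / 100, 0.05)
})

test_that("metrics follow the confusion arithmetic and the 70% benchmark", {
  mkres <- function(pred) {
    new("CVResult",
        predictions = pred,
        selectedSubsets = list(), finalSubset = "f",
        selectionFrequency = c(f = 1L),
        folds = list(), config = cvConfig())
  }
  # TP 9, FN 1, TN 8, FP 2 at participant level (one segment each)
  pred <- data.frame(
    sample = sprintf("s%02d", 1:20),
    participant_id = sprintf("P%02d", 1:20),
    label = rep(c(1L, 0L), each = 10),
    decision = 0,
    predicted = c(rep(1L, 9), 0L, rep(0L, 8), 1L, 1L))
  m <- cvMetrics(mkres(pred))
  expect_equal(unname(m$participant["sensitivity"]), 90)
  expect_equal(unname(m$participant["specificity"]), 80)
  expect_equal(unname(m$participant["accuracy"]), 85)
  expect_true(m$reportable)

  # all correct
  pred2 <- pred
  pred2$predicted <- pred2$label
  m2 <- cvMetrics(mkres(pred2))
  expect_equal(unname(m2$participant), c(100, 100, 100))

  # sens above, spec below the benchmark -> not reportable
  pred3 <- data.frame(
    sample = sprintf("s%03d", 1:100),
    participant_id = sprintf("P%03d", 1:100),
    label = rep(c(1L, 0L), each = 50),
    decision = 0,
    predicted = c(rep(1L, 36), rep(0L, 14), rep(0L, 34), rep(1L, 16)))
  m3 <- cvMetrics(mkres(pred3))
  expect_equal(unname(m3$participant["sensitivity"]), 72)
  expect_equal(unname(m3$participant["specificity"]), 68)
  expect_false(m3$reportable)
})

test_that("majority voting over segments resolves ties to the positive class", {
  pred <- data.frame(
    sample = sprintf("s%02d", 1:4),
    participant_id = rep("P1", 4),
    label = 1L,
    decision = 0,
    predicted = c(1L, 1L, 0L, 0L))
  res <- new("CVResult", predictions = pred, selectedSubsets = list(),
             finalSubset = "f", selectionFrequency = c(f = 1L),
             folds = list(), config = cvConfig())
  expect_message(m <- cvMetrics(res), "tie")
  expect_equal(unname(m$participant["sensitivity"]), 100)
})
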