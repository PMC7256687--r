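#' Nested cross-validation configuration
#'
#' @param outerTestFraction outer held-out participant fraction.
#' @param middleFolds,innerFolds fold counts of the two inner loops.
#' @param featureCap maximum selected feature subset size.
#' @param cost SVM cost C.
#' @param classWeights inverse-class-frequency weighting of C.
#' @param seed integer seed for all fold draws.
#' @return a \linkS4class{CVConfig}.
#' @export
cvConfig <- function(outerTestFraction = 0.2, middleFolds = 5L,
                     innerFolds = 5L, featureCap = 30L, cost = 1,
                     classWeights = FALSE, seed = 1L) {
  new("CVConfig", outerTestFraction = outerTestFraction,
      middleFolds = as.integer(middleFolds),
      innerFolds = as.integer(innerFolds),
      featureCap = as.integer(featureCap), cost = cost,
      classWeights = classWeights, seed = as.integer(seed))
}

#' Label-stratified participant-level fold assignment
#'
#' Participants (not samples) are dealt into k folds, shuffled within
#' each label class so folds are stratified; all samples of one
#' participant inherit the same fold.
#'
#' @param participants character vector of participant ids (unique).
#' @param labels 0/1 label per participant.
#' @param k number of folds.
#' @param seed integer seed.
#' @return named integer vector: fold (1..k) per participant.
#' @export
groupedFolds <- function(participants, labels, k, seed = 1L) {
  stopifnot(length(participants) == length(labels),
            !anyDuplicated(participants))
  if (length(participants) < k)
    stop(sprintf("only %d participants for %d folds",
                 length(participants), k))
  set.seed(seed)
  fold <- integer(length(participants))
  names(fold) <- participants
  for (cl in unique(labels)) {
    idx <- which(labels == cl)
    idx <- idx[sample.int(length(idx))]
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

# column standardization fitted on training rows only
fitStandardizer <- function(x) {
  mu <- colMeans(x)
  sdv <- apply(x, 2L, stats::sd)
  sdv[sdv < .Machine$double.eps] <- 1
  list(mu = mu, sd = sdv)
}

applyStandardizer <- function(x, st) {
  sweep(sweep(x, 2L, st$mu, "-"), 2L, st$sd, "/")
}

balancedAccuracy <- function(truth, predicted) {
  classes <- unique(truth)
  mean(vapply(classes, function(cl)
    mean(predicted[truth == cl] == cl), 0))
}

#' Greedy forward feature subset selection
#'
#' Starting from the empty set, repeatedly adds the feature whose
#' addition maximizes mean balanced accuracy over a participant-grouped,
#' label-stratified inner k-fold cross-validation of the linear 2-norm
#' SVM; stops at the cap or when no candidate improves the score by more
#' than \code{minImprovement}. Ties are broken toward the lower column
#' index. Standardization is fitted on each inner-fold training split.
#'
#' @param x samples x features matrix.
#' @param y 0/1 labels per sample.
#' @param groups participant id per sample.
#' @param cap maximum subset size (default 30).
#' @param k inner fold count.
#' @param cost,classWeights SVM parameters.
#' @param seed integer seed for the inner fold draw.
#' @param minImprovement minimum score gain to continue.
#' @return character vector of selected feature names, in selection
#'   order (may be empty).
#' @export
greedyFSS <- function(x, y, groups, cap = 30L, k = 5L, cost = 1,
                      classWeights = FALSE, seed = 1L,
                      minImprovement = 1e-4) {
  if (length(unique(y)) < 2L)
    stop("need both classes for feature selection")
  pids <- unique(groups)
  plab <- vapply(pids, function(p) y[match(p, groups)], 0)
  fold <- groupedFolds(pids, plab, k, seed = seed)
  foldOf <- fold[groups]

  # per-fold standardized matrices, computed once over all features
  folds <- lapply(seq_len(k), function(f) {
    tr <- foldOf != f
    te <- !tr
    if (length(unique(y[tr])) < 2L || !any(te)) return(NULL)
    st <- fitStandardizer(x[tr, , drop = FALSE])
    list(xtr = applyStandardizer(x[tr, , drop = FALSE], st),
         xte = applyStandardizer(x[te, , drop = FALSE], st),
         ytr = y[tr], yte = y[te])
  })
  folds <- Filter(Negate(is.null), folds)
  if (!length(folds)) stop("no usable inner folds")

  scoreSubset <- function(cols) {
    mean(vapply(folds, function(fd) {
      fit <- l2svm(fd$xtr[, cols, drop = FALSE], fd$ytr, cost = cost,
                   classWeights = classWeights)
      pr <- predict(fit, fd$xte[, cols, drop = FALSE])
      balancedAccuracy(fd$yte, pr$predicted)
    }, 0))
  }

  selected <- integer(0)
  best <- -Inf
  nfeat <- ncol(x)
  while (length(selected) < min(cap, nfeat)) {
    candidates <- setdiff(seq_len(nfeat), selected)
    scores <- vapply(candidates, function(j)
      scoreSubset(c(selected, j)), 0)
    jbest <- candidates[which.max(scores)]   # ties -> lower index
    sc <- max(scores)
    if (length(selected) > 0L && sc <= best + minImprovement)
      break
    selected <- c(selected, jbest)
    best <- sc
  }
  colnames(x)[selected]
}

#' Three-layer nested cross-validation with feature subset selection
#'
#' Outer layer: one participant-grouped, label-stratified split holding
#' out \code{outerTestFraction} of the participants for testing. Middle
#' layer: k-fold over the remaining participants; each middle run
#' performs greedy feature subset selection (which internally uses the
#' inner k-fold) on its training folds and records the selected subset,
#' measuring the consistency of selection. The final model uses the
#' frequency-ranked union of the middle-run subsets (every feature
#' selected at least once, ranked by how many runs chose it, truncated
#' to the cap), is retrained on the full outer training set and
#' evaluated once on the held-out participants. Any train/test
#' participant overlap is a hard assertion failure.
#'
#' @param table a \linkS4class{SampleTable}.
#' @param config a \linkS4class{CVConfig}.
#' @return a \linkS4class{CVResult}.
#' @export
nestedCV <- function(table, config = cvConfig()) {
  stopifnot(is(table, "SampleTable"))
  x <- sampleMatrix(table)
  info <- sampleInfo(table)
  y <- info$label
  groups <- info$participant_id
  pids <- unique(groups)
  plab <- vapply(pids, function(p) y[match(p, groups)], 0)

  # outer grouped stratified split
  set.seed(deriveSeed(config@seed, 1L))
  testPids <- character(0)
  for (cl in unique(plab)) {
    clp <- pids[plab == cl]
    nTest <- max(1L, round(config@outerTestFraction * length(clp)))
    testPids <- c(testPids, sample(clp, nTest))
  }
  trainPids <- setdiff(pids, testPids)
  if (length(intersect(trainPids, testPids)))
    stop("internal error: outer train/test participants overlap")

  trainRows <- groups %in% trainPids
  testRows <- groups %in% testPids
  stopifnot(!any(trainRows & testRows))

  middleFold <- groupedFolds(trainPids, plab[match(trainPids, pids)],
                             config@middleFolds,
                             seed = deriveSeed(config@seed, 2L))
  subsets <- vector("list", config@middleFolds)
  for (r in seq_len(config@middleFolds)) {
    runPids <- names(middleFold)[middleFold != r]
    rows <- groups %in% runPids
    stopifnot(!any(rows & testRows))
    subsets[[r]] <- greedyFSS(
      x[rows, , drop = FALSE], y[rows], groups[rows],
      cap = config@featureCap, k = config@innerFolds,
      cost = config@cost, classWeights = config@classWeights,
      seed = deriveSeed(config@seed, 3L, r))
  }

  selFreq <- table(unlist(subsets))
  selFreq <- sort(
    stats::setNames(as.integer(selFreq), names(selFreq)),
    decreasing = TRUE)
  finalSubset <- utils::head(names(selFreq), config@featureCap)
  if (!length(finalSubset))
    stop("feature selection returned an empty final subset")

  st <- fitStandardizer(x[trainRows, finalSubset, drop = FALSE])
  fit <- l2svm(applyStandardizer(x[trainRows, finalSubset, drop = FALSE],
                                 st),
               y[trainRows], cost = config@cost,
               classWeights = config@classWeights)
  pr <- predict(fit, applyStandardizer(
    x[testRows, finalSubset, drop = FALSE], st))

  predictions <- data.frame(
    sample = rownames(x)[testRows],
    participant_id = groups[testRows],
    label = y[testRows],
    decision = pr$decision,
    predicted = pr$predicted)

  new("CVResult",
      predictions = predictions,
      selectedSubsets = subsets,
      finalSubset = finalSubset,
      selectionFrequency = selFreq,
      folds = list(outerTest = testPids, outerTrain = trainPids,
                   middle = middleFold),
      config = config)
}

confusion <- function(truth, predicted) {
  c(TP = sum(truth == 1 & predicted == 1),
    FN = sum(truth == 1 & predicted == 0),
    TN = sum(truth == 0 & predicted == 0),
    FP = sum(truth == 0 & predicted == 1))
}

metricsFromConfusion <- function(cm) {
  sens <- if (cm["TP"] + cm["FN"] > 0)
    100 * cm["TP"] / (cm["TP"] + cm["FN"]) else NA_real_
  spec <- if (cm["TN"] + cm["FP"] > 0)
    100 * cm["TN"] / (cm["TN"] + cm["FP"]) else NA_real_
  acc <- 100 * (cm["TP"] + cm["TN"]) / sum(cm)
  c(accuracy = unname(acc), sensitivity = unname(sens),
    specificity = unname(spec))
}

#' Held-out performance metrics of a nested CV run
#'
#' Segment-level metrics count every held-out sample; participant-level
#' metrics aggregate each participant's segment predictions by majority
#' vote (ties go to the positive class, with a message). A result is
#' flagged reportable only when both sensitivity and specificity reach
#' the benchmark (default 70%) at the participant level; below that the
#' classifier is considered biased toward one group and the result a
#' statistical artifact.
#'
#' @param result a \linkS4class{CVResult}.
#' @param benchmark minimum sensitivity and specificity, percent.
#' @return list with \code{segment} and \code{participant} metric
#'   vectors (accuracy/sensitivity/specificity, percent), the confusion
#'   counts, and \code{reportable}.
#' @export
cvMetrics <- function(result, benchmark = 70) {
  pr <- result@predictions
  segCM <- confusion(pr$label, pr$predicted)
  agg <- stats::aggregate(predicted ~ participant_id + label, data = pr,
                          FUN = mean)
  ties <- sum(agg$predicted == 0.5)
  if (ties > 0)
    message(sprintf(
      "%d participant vote tie(s) resolved to the positive class", ties))
  partPred <- as.integer(agg$predicted >= 0.5)
  partCM <- confusion(agg$label, partPred)
  part <- metricsFromConfusion(partCM)
  list(segment = metricsFromConfusion(segCM),
       participant = part,
       segmentConfusion = segCM,
       participantConfusion = partCM,
       reportable = isTRUE(min(part["sensitivity"],
                               part["specificity"]) >= benchmark))
}
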