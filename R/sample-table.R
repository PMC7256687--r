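#' Per-segment connectivity feature matrix for a set of segments
#'
#' Applies [connectivityFeatures()] to every segment and stacks the
#' results into a samples x features matrix whose rows carry the
#' participant, condition and session of each segment.
#'
#' @param segments list of \linkS4class{Segment} objects.
#' @param ... passed to [connectivityFeatures()].
#' @return numeric matrix (one row per segment) with attributes
#'   \code{participant_id}, \code{condition}, \code{session}.
#' @export
segmentFeatureMatrix <- function(segments, ...) {
  stopifnot(length(segments) > 0L)
  rows <- lapply(segments, connectivityFeatures, ...)
  m <- do.call(rbind, rows)
  rownames(m) <- sprintf("seg%04d", seq_along(segments))
  attr(m, "participant_id") <-
    vapply(segments, function(s) s@participantId, "")
  attr(m, "condition") <- vapply(segments, function(s) s@condition, "")
  attr(m, "session") <- vapply(segments, function(s) s@session, 1L)
  m
}

#' Assemble the multimodal sample table
#'
#' Builds the samples-by-features table used by the nested
#' cross-validation. With EEG features present there is one sample per
#' EEG segment and the participant-constant MRI and/or neuropsychology
#' vectors are replicated onto each of that participant's segments;
#' without EEG there is one sample per participant. Columns are not
#' standardized here: standardization statistics are fitted on training
#' rows only, inside the cross-validation.
#'
#' @param eegFeatures matrix from [segmentFeatureMatrix()] (rows =
#'   segments, with the \code{participant_id} attribute), or NULL.
#' @param mriFeatures matrix, rows = participants (rownames =
#'   participant ids), e.g. stacked [mriFeatureVector()] outputs; or
#'   NULL.
#' @param psyFeatures matrix from [baselineFeatures()], or NULL.
#' @param labels data.frame with \code{participant_id} and \code{label}
#'   (0/1), e.g. one domain of [declineLabels()] output.
#' @return a \linkS4class{SampleTable}; columns (samples) are segments
#'   or participants, rows are features, \code{rowData$modality} records
#'   each feature's source modality.
#' @export
assembleSamples <- function(eegFeatures = NULL, mriFeatures = NULL,
                            psyFeatures = NULL, labels) {
  if (is.null(eegFeatures) && is.null(mriFeatures) &&
      is.null(psyFeatures))
    stop("at least one feature modality must be provided")
  stopifnot(all(c("participant_id", "label") %in% names(labels)))
  labmap <- stats::setNames(as.integer(labels$label),
                            labels$participant_id)

  participantOf <- function(m) rownames(m)
  blocks <- list()
  if (!is.null(mriFeatures))
    blocks$mri <- mriFeatures
  if (!is.null(psyFeatures))
    blocks$psy <- psyFeatures

  if (!is.null(eegFeatures)) {
    segPid <- attr(eegFeatures, "participant_id")
    if (is.null(segPid))
      stop("eegFeatures must carry a participant_id attribute")
    keep <- segPid %in% names(labmap)
    feat <- eegFeatures[keep, , drop = FALSE]
    segPid <- segPid[keep]
    mats <- list(eeg = feat)
    for (b in names(blocks)) {
      pm <- blocks[[b]]
      found <- segPid %in% rownames(pm)
      if (!all(found)) {
        drop <- unique(segPid[!found])
        message(sprintf(
          "participant(s) without %s features excluded: %s", b,
          paste(drop, collapse = ", ")))
        sel <- !(segPid %in% drop)
        mats <- lapply(mats, function(m) m[sel, , drop = FALSE])
        segPid <- segPid[sel]
      }
      mats[[b]] <- pm[segPid, , drop = FALSE]
    }
    full <- do.call(cbind, mats)
    modality <- rep(names(mats), vapply(mats, ncol, 0L))
    pid <- segPid
  } else {
    common <- Reduce(intersect, lapply(blocks, participantOf))
    common <- intersect(common, names(labmap))
    dropped <- setdiff(names(labmap),
                       Reduce(union, lapply(blocks, participantOf)))
    if (length(dropped))
      message(sprintf(
        "participant(s) with label but no features excluded: %s",
        paste(dropped, collapse = ", ")))
    mats <- lapply(blocks, function(m) m[common, , drop = FALSE])
    full <- do.call(cbind, mats)
    modality <- rep(names(mats), vapply(mats, ncol, 0L))
    pid <- common
  }
  if (!nrow(full)) stop("no samples left after matching labels")
  lab <- labmap[pid]
  rownames(full) <- sprintf("s%05d", seq_len(nrow(full)))
  pfrac <- mean(labmap[unique(pid)])
  if (min(pfrac, 1 - pfrac) < 0.3)
    warning(sprintf(
      "class imbalance: minority class is %s of participants",
      fmtPct(min(pfrac, 1 - pfrac))))
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(features = t(full)),
    colData = S4Vectors::DataFrame(participant_id = pid,
                                   label = unname(lab),
                                   row.names = sprintf(
                                     "s%05d", seq_len(nrow(full)))),
    rowData = S4Vectors::DataFrame(modality = modality))
  new("SampleTable", se)
}

#' Feature matrix of a sample table (samples x features)
#' @param table a \linkS4class{SampleTable}.
#' @export
sampleMatrix <- function(table) {
  t(SummarizedExperiment::assay(table, "features"))
}

#' Participant id and label of every sample
#' @param table a \linkS4class{SampleTable}.
#' @export
sampleInfo <- function(table) {
  as.data.frame(SummarizedExperiment::colData(table))
}
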