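#' @import methods
#' @importFrom stats sd var rnorm runif qnorm median mad quantile rgamma uniroot
NULL

#' Multichannel EEG recording
#'
#' Container for a continuous multichannel EEG signal in microvolts together
#' with its sampling rate, channel names, reference label, event markers and
#' (after artifact detection) a per-sample artifact mask.
#'
#' Events are stored as a data.frame with columns \code{sample} (1-based
#' sample index of the event onset), \code{condition} (one of \code{rest},
#' \code{learning}, \code{recall}, \code{recognition}), \code{session}
#' (1 or 2) and \code{duration} (event duration in samples; task stimuli
#' have duration 0, rest blocks span the whole block).
#'
#' @slot signal numeric matrix, channels x samples, microvolts.
#' @slot fs sampling rate in Hz.
#' @slot channelNames character vector, one per row of \code{signal}.
#' @slot reference label of the recording reference (e.g. "FCz",
#'   "linked-earlobes").
#' @slot events data.frame of event markers (see Details).
#' @slot artifactMask logical vector of length \code{ncol(signal)}, or
#'   length 0 before detection.
#'
#' @seealso [eegRecording()], [detectArtifacts()], [segmentEEG()]
#' @export
setClass("EEGRecording",
  representation(
    signal = "matrix",
    fs = "numeric",
    channelNames = "character",
    reference = "character",
    events = "data.frame",
    artifactMask = "logical"
  )
)

setValidity("EEGRecording", function(object) {
  msg <- NULL
  if (length(object@fs) != 1L || object@fs <= 0)
    msg <- c(msg, "fs must be a single positive number")
  if (nrow(object@signal) != length(object@channelNames))
    msg <- c(msg, "channelNames length must equal number of signal rows")
  if (length(object@artifactMask) > 0L &&
      length(object@artifactMask) != ncol(object@signal))
    msg <- c(msg, "artifactMask length must equal number of samples")
  if (nrow(object@events) > 0L) {
    need <- c("sample", "condition", "session", "duration")
    if (!all(need %in% names(object@events)))
      msg <- c(msg, paste("events must have columns:",
                          paste(need, collapse = ", ")))
    else if (any(object@events$sample < 1L) ||
             any(object@events$sample > ncol(object@signal)))
      msg <- c(msg, "event sample indices must lie within the recording")
  }
  if (is.null(msg)) TRUE else msg
})

#' One fixed-length EEG segment
#'
#' A single 1000 ms analysis epoch cut from a recording: a channels x
#' samples matrix plus the metadata needed to trace it back (condition,
#' session, participant, onset).
#'
#' @slot data numeric matrix channels x samples (exactly \code{fs} samples).
#' @slot fs sampling rate in Hz.
#' @slot channelNames character.
#' @slot condition task condition the segment belongs to.
#' @slot session session index (1 or 2).
#' @slot participantId participant identifier (may be \code{NA}).
#' @slot onsetSample 1-based index of the first sample in the source
#'   recording.
#' @export
setClass("Segment",
  representation(
    data = "matrix",
    fs = "numeric",
    channelNames = "character",
    condition = "character",
    session = "integer",
    participantId = "character",
    onsetSample = "integer"
  )
)

setValidity("Segment", function(object) {
  if (ncol(object@data) != round(object@fs))
    return("segment must contain exactly round(fs * 1 s) samples")
  if (nrow(object@data) != length(object@channelNames))
    return("channelNames length must match channel count")
  TRUE
})

#' Fitted multivariate autoregressive model
#'
#' An order-p MVAR model x_t = sum_k A_k x_{t-k} + e_t fitted to one
#' segment: coefficient matrices, residual covariance and sampling rate.
#'
#' @slot A numeric array channels x channels x order; \code{A[, , k]} is
#'   the lag-k coefficient matrix.
#' @slot Sigma residual covariance, microvolt^2.
#' @slot fs sampling rate in Hz.
#' @slot order model order p.
#' @slot stable logical; TRUE when the companion-matrix spectral radius
#'   is below 1.
#' @export
setClass("MVARModel",
  representation(
    A = "array",
    Sigma = "matrix",
    fs = "numeric",
    order = "integer",
    stable = "logical",
    channelNames = "character"
  )
)

setValidity("MVARModel", function(object) {
  d <- dim(object@A)
  if (length(d) != 3L || d[1] != d[2])
    return("A must be a channels x channels x order array")
  if (d[3] != object@order)
    return("third dimension of A must equal order")
  if (!isTRUE(all.equal(object@Sigma, t(object@Sigma),
                        tolerance = 1e-6)))
    return("Sigma must be symmetric")
  TRUE
})

#' Frequency-domain quantities of an MVAR model
#'
#' The coefficient polynomial \eqn{\bar A(f) = I - \sum_k A_k
#' e^{-i 2\pi f k / f_s}}, the transfer function \eqn{H(f) = \bar
#' A(f)^{-1}} and the cross-spectral matrix \eqn{S(f) = H(f) \Sigma
#' H(f)^H} evaluated on a frequency grid.
#'
#' @slot freqs numeric vector of frequencies in Hz.
#' @slot Abar complex array channels x channels x length(freqs).
#' @slot H complex array, same shape.
#' @slot S complex array, same shape (Hermitian at each frequency).
#' @slot Sigma residual covariance of the underlying model.
#' @slot channelNames character.
#' @export
setClass("SpectralSet",
  representation(
    freqs = "numeric",
    Abar = "array",
    H = "array",
    S = "array",
    Sigma = "matrix",
    channelNames = "character"
  )
)

#' Labeled intensity volume
#'
#' A 3D intensity image with a co-registered integer label image of the
#' same shape (0 = background) and a label dictionary mapping label ids
#' to region names.
#'
#' @slot intensity 3D numeric array.
#' @slot labels 3D integer array, same dimensions.
#' @slot voxelSize numeric length-3, mm.
#' @slot labelDict named character vector; names are label ids.
#' @export
setClass("LabeledVolume",
  representation(
    intensity = "array",
    labels = "array",
    voxelSize = "numeric",
    labelDict = "character"
  )
)

setValidity("LabeledVolume", function(object) {
  if (!identical(dim(object@intensity), dim(object@labels)))
    return("intensity and labels must have identical dimensions")
  if (length(dim(object@intensity)) != 3L)
    return("volumes must be 3-dimensional")
  if (any(object@labels < 0))
    return("labels must be non-negative (0 = background)")
  if (length(object@voxelSize) != 3L || any(object@voxelSize <= 0))
    return("voxelSize must be 3 positive numbers")
  TRUE
})

#' Per-segment multimodal sample table
#'
#' Thin wrapper around \linkS4class{SummarizedExperiment}: the assay
#' \code{features} holds a features x samples matrix (one column per EEG
#' segment, or per participant for designs without EEG); \code{colData}
#' carries \code{participant_id} and the binary decline \code{label};
#' \code{rowData} carries each feature's \code{modality}.
#'
#' @seealso [assembleSamples()], [nestedCV()]
#' @export
setClass("SampleTable", contains = "SummarizedExperiment")

setValidity("SampleTable", function(object) {
  cd <- SummarizedExperiment::colData(object)
  if (!all(c("participant_id", "label") %in% names(cd)))
    return("colData must contain participant_id and label")
  if (!all(cd$label %in% c(0L, 1L)))
    return("label must be 0/1")
  if (anyNA(SummarizedExperiment::assay(object)))
    return("feature matrix must not contain missing values")
  TRUE
})

#' Nested cross-validation configuration
#'
#' @slot outerTestFraction fraction of participants held out in the outer
#'   split (default 0.2).
#' @slot middleFolds number of middle-layer folds (default 5).
#' @slot innerFolds number of inner-layer folds used by feature subset
#'   selection (default 5).
#' @slot featureCap maximum selected subset size (default 30).
#' @slot cost SVM cost parameter C.
#' @slot classWeights logical; weight C by inverse class frequency.
#' @slot seed integer seed controlling all fold draws.
#' @export
setClass("CVConfig",
  representation(
    outerTestFraction = "numeric",
    middleFolds = "integer",
    innerFolds = "integer",
    featureCap = "integer",
    cost = "numeric",
    classWeights = "logical",
    seed = "integer"
  )
)

setValidity("CVConfig", function(object) {
  if (object@featureCap < 1L) return("featureCap must be >= 1")
  if (object@middleFolds < 2L || object@innerFolds < 2L)
    return("fold counts must be >= 2")
  if (object@outerTestFraction <= 0 || object@outerTestFraction >= 1)
    return("outerTestFraction must be in (0, 1)")
  TRUE
})

#' Result of one nested cross-validation run
#'
#' @slot predictions data.frame with one row per held-out sample:
#'   \code{sample}, \code{participant_id}, \code{label}, \code{decision},
#'   \code{predicted}.
#' @slot selectedSubsets list of character vectors, the ordered feature
#'   subset chosen in each middle-layer run.
#' @slot finalSubset character; frequency-ranked union used by the final
#'   model.
#' @slot selectionFrequency named integer vector: for every feature ever
#'   selected, the number of middle runs (0..middleFolds) that chose it.
#' @slot folds list with the outer split and middle fold assignment
#'   (participant level).
#' @slot config the \linkS4class{CVConfig} used.
#' @export
setClass("CVResult",
  representation(
    predictions = "data.frame",
    selectedSubsets = "list",
    finalSubset = "character",
    selectionFrequency = "integer",
    folds = "list",
    config = "CVConfig"
  )
)

setMethod("show", "EEGRecording", function(object) {
  cat(sprintf("EEGRecording: %d channels x %d samples @ %g Hz (%.1f s)\n",
              nrow(object@signal), ncol(object@signal), object@fs,
              ncol(object@signal) / object@fs))
  cat(sprintf("  reference: %s; events: %d; artifact mask: %s\n",
              object@reference, nrow(object@events),
              if (length(object@artifactMask))
                sprintf("%.2f%% marked",
                        100 * mean(object@artifactMask)) else "absent"))
})

setMethod("show", "MVARModel", function(object) {
  cat(sprintf("MVARModel: %d channels, order %d, %s\n",
              dim(object@A)[1], object@order,
              if (object@stable) "stable" else "UNSTABLE"))
})

setMethod("show", "LabeledVolume", function(object) {
  cat(sprintf("LabeledVolume: %s voxels, %d regions\n",
              paste(dim(object@intensity), collapse = " x "),
              length(object@labelDict)))
})

setMethod("show", "CVResult", function(object) {
  m <- cvMetrics(object)
  cat(sprintf(
    "CVResult: %d held-out samples, %d features in final model\n",
    nrow(object@predictions), length(object@finalSubset)))
  cat(sprintf(
    "  participant-level acc %.1f%%, sens %.1f%%, spec %.1f%% (%s)\n",
    m$participant["accuracy"], m$participant["sensitivity"],
    m$participant["specificity"],
    if (m$reportable) "reportable" else "not reportable"))
})
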