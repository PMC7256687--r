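#' Construct an EEG recording
#'
#' @param signal numeric matrix channels x samples, microvolts.
#' @param fs sampling rate in Hz.
#' @param channelNames character; defaults to rownames or ch1..chN.
#' @param reference reference label.
#' @param events data.frame with columns \code{sample}, \code{condition},
#'   \code{session}, \code{duration} (may be empty).
#' @param artifactMask optional logical per-sample mask.
#' @return an \linkS4class{EEGRecording}.
#' @export
eegRecording <- function(signal, fs, channelNames = NULL,
                         reference = "unknown", events = NULL,
                         artifactMask = NULL) {
  if (is.null(channelNames))
    channelNames <- rownames(signal) %||% paste0("ch", seq_len(nrow(signal)))
  rownames(signal) <- channelNames
  if (is.null(events))
    events <- data.frame(sample = integer(), condition = character(),
                         session = integer(), duration = integer())
  new("EEGRecording", signal = signal, fs = fs,
      channelNames = channelNames, reference = reference,
      events = events,
      artifactMask = if (is.null(artifactMask)) logical(0) else artifactMask)
}

#' The 17 scalp analysis channels used by default
#' @export
defaultAnalysisChannels <- function() {
  c("F3", "F4", "C3", "C4", "P3", "P4", "O1", "O2",
    "F7", "F8", "T7", "T8", "P7", "P8", "Fz", "Cz", "Pz")
}

#' Rereference to the average of the earlobe electrodes
#'
#' Builds a new reference as the mean of the two earlobe signals and
#' subtracts it from every analysis channel, removing the bias of the
#' original recording reference. The earlobe channels are dropped from
#' the analysis set.
#'
#' @param recording an \linkS4class{EEGRecording}.
#' @param earlobeChannels names of the two earlobe channels.
#' @return rereferenced \linkS4class{EEGRecording} without the earlobe
#'   channels.
#' @export
rereferenceAverageEarlobes <- function(recording,
                                       earlobeChannels = c("A1", "A2")) {
  stopifnot(is(recording, "EEGRecording"))
  missing <- setdiff(earlobeChannels, recording@channelNames)
  if (length(missing))
    stop(sprintf("earlobe channel(s) not present: %s",
                 paste(missing, collapse = ", ")))
  ear <- recording@signal[earlobeChannels, , drop = FALSE]
  ref <- colMeans(ear)
  keep <- setdiff(recording@channelNames, earlobeChannels)
  sig <- recording@signal[keep, , drop = FALSE] -
    matrix(ref, length(keep), length(ref), byrow = TRUE)
  eegRecording(sig, recording@fs, keep, reference = "linked-earlobes",
               events = recording@events,
               artifactMask = if (length(recording@artifactMask))
                 recording@artifactMask else NULL)
}

#' Zero-phase high-pass and notch filtering
#'
#' High-pass at 1 Hz with a 48 dB/oct rolloff, realized as an 8th-order
#' Butterworth applied forward-backward (zero phase, doubled effective
#' attenuation), plus a 2 Hz wide second-order Butterworth band-stop
#' centered on the mains frequency.
#'
#' @param recording an \linkS4class{EEGRecording} with fs >= 250 Hz.
#' @param highpass high-pass edge in Hz.
#' @param notch mains frequency in Hz (NULL disables the notch).
#' @param notchWidth full stop-band width in Hz.
#' @return filtered \linkS4class{EEGRecording}.
#' @export
filterEEG <- function(recording, highpass = 1, notch = 50,
                      notchWidth = 2) {
  stopifnot(is(recording, "EEGRecording"))
  fs <- recording@fs
  if (fs < 250) stop("sampling rate must be at least 250 Hz")
  sos <- butterHighpassSOS(8L, highpass, fs)
  pad <- min(ncol(recording@signal) - 1L, round(4 * fs))
  sig <- recording@signal
  for (i in seq_len(nrow(sig))) {
    xi <- sig[i, ]
    for (bq in sos)
      xi <- zeroPhaseFilter(bq$b, bq$a, xi, pad)
    sig[i, ] <- xi
  }
  if (!is.null(notch)) {
    bs <- signal::butter(2, c(notch - notchWidth / 2,
                              notch + notchWidth / 2) / (fs / 2),
                         type = "stop")
    for (i in seq_len(nrow(sig)))
      sig[i, ] <- zeroPhaseFilter(bs$b, bs$a, sig[i, ], pad)
  }
  eegRecording(sig, fs, recording@channelNames,
               reference = recording@reference, events = recording@events)
}

# forward-backward filtering with odd-reflection end padding, so that
# boundary transients of slow (near-DC) poles die inside the pad and
# never reach the data
zeroPhaseFilter <- function(b, a, x, pad) {
  n <- length(x)
  pad <- min(pad, n - 1L)
  xp <- c(2 * x[1] - x[(pad + 1L):2L], x,
          2 * x[n] - x[(n - 1L):(n - pad)])
  yp <- signal::filtfilt(signal::Arma(b = b, a = a), xp)
  yp[pad + seq_len(n)]
}

# Butterworth high-pass as a cascade of second-order sections.
# The polynomial (b, a) form of a high-order Butterworth with a cutoff
# near 0 is numerically unusable; the biquad cascade is exact and
# stable. Poles are derived analytically: normalized analog prototype
# poles on the unit circle, low-pass-to-high-pass transform, bilinear
# transform with pre-warping; each conjugate pole pair forms one biquad
# with zeros at z = 1, gain normalized at Nyquist.
butterHighpassSOS <- function(n, fc, fs) {
  stopifnot(n %% 2L == 0L)
  wc <- 2 * fs * tan(pi * fc / fs)     # pre-warped edge, rad/s
  k <- seq_len(n / 2L)
  q <- exp(1i * pi * (2 * k + n - 1) / (2 * n))  # upper-half LHP poles
  pa <- wc / q                          # analog high-pass poles
  pz <- (2 * fs + pa) / (2 * fs - pa)   # bilinear transform
  lapply(seq_along(pz), function(j) {
    a <- c(1, -2 * Re(pz[j]), Mod(pz[j])^2)
    g <- sum(a * c(1, -1, 1)) / 4       # unit gain at z = -1
    list(b = g * c(1, -2, 1), a = a)
  })
}

#' Amplitude-rule artifact detection
#'
#' Marks samples where any of three rules fires on any channel:
#' \enumerate{
#'   \item voltage step: |x[t] - x[t-1]| > \code{maxStep} microvolts marks
#'     t +/- 100 ms;
#'   \item high amplitude: max - min over any 200 ms window >
#'     \code{maxRange} microvolts marks that window;
#'   \item flatline: max - min over any 100 ms window < \code{minRange}
#'     microvolts marks the window +/- 500 ms.
#' }
#' Windows slide with 1-sample stride; marks are unioned over channels
#' and rules.
#'
#' @param recording a filtered \linkS4class{EEGRecording}.
#' @param maxStep step threshold, microvolts per sample (default 50).
#' @param maxRange amplitude range threshold over 200 ms (default 200).
#' @param minRange flatline range threshold over 100 ms (default 0.5).
#' @return the recording with its \code{artifactMask} slot filled.
#' @export
detectArtifacts <- function(recording, maxStep = 50, maxRange = 200,
                            minRange = 0.5) {
  stopifnot(is(recording, "EEGRecording"))
  fs <- recording@fs
  n <- ncol(recording@signal)
  mask <- logical(n)
  pad100 <- round(0.1 * fs)
  pad500 <- round(0.5 * fs)
  w200 <- round(0.2 * fs)
  w100 <- round(0.1 * fs)

  # union of [from, to] intervals in O(n + hits) via a difference array
  markRange <- function(mask, from, to) {
    from <- pmax(from, 1L)
    to <- pmin(to, n)
    keep <- from <= to
    if (!any(keep)) return(mask)
    d <- tabulate(from[keep], nbins = n + 1L) -
      tabulate(to[keep] + 1L, nbins = n + 1L)
    mask | (cumsum(d[seq_len(n)]) > 0L)
  }

  for (i in seq_len(nrow(recording@signal))) {
    x <- recording@signal[i, ]
    # rule (a): voltage step
    jump <- which(abs(diff(x)) > maxStep) + 1L
    if (length(jump))
      mask <- markRange(mask, jump - pad100, jump + pad100)
    # rule (b): range over 200 ms windows
    if (n >= w200) {
      rng <- rollExtreme(x, w200, "max") - rollExtreme(x, w200, "min")
      hit <- which(rng > maxRange)
      if (length(hit))
        mask <- markRange(mask, hit, hit + w200 - 1L)
    }
    # rule (c): flat stretches over 100 ms windows
    if (n >= w100) {
      rng <- rollExtreme(x, w100, "max") - rollExtreme(x, w100, "min")
      hit <- which(rng < minRange)
      if (length(hit))
        mask <- markRange(mask, hit - pad500, hit + w100 - 1L + pad500)
    }
  }
  recording@artifactMask <- mask
  validObject(recording)
  recording
}

#' Cut 1000 ms analysis segments
#'
#' Event-locked mode cuts one segment per (non-rest) event from 100 ms
#' before to 900 ms after stimulus onset; rest mode cuts consecutive
#' non-overlapping 1 s windows from each rest block, starting at the
#' block onset. Segments overlapping a marked artifact sample, or
#' extending past the recording edge, are dropped (counted in the
#' \code{skipped} attribute).
#'
#' @param recording an \linkS4class{EEGRecording} whose artifact mask has
#'   been computed (see [detectArtifacts()]).
#' @param mode \code{"rest"} or \code{"event_locked"}.
#' @param session restrict to one session (NULL = all).
#' @param condition restrict event-locked cutting to one condition
#'   (NULL = all non-rest conditions).
#' @param participantId carried into each segment's metadata.
#' @return list of \linkS4class{Segment} objects with attributes
#'   \code{skippedArtifact} and \code{skippedEdge}.
#' @export
segmentEEG <- function(recording, mode = c("rest", "event_locked"),
                       session = NULL, condition = NULL,
                       participantId = NA_character_) {
  mode <- match.arg(mode)
  stopifnot(is(recording, "EEGRecording"))
  if (!length(recording@artifactMask))
    stop("artifact mask absent: run detectArtifacts() first")
  fs <- recording@fs
  len <- round(fs)
  n <- ncol(recording@signal)
  mask <- recording@artifactMask
  ev <- recording@events
  if (!is.null(session)) ev <- ev[ev$session == session, , drop = FALSE]

  starts <- integer(0)
  meta <- list()
  if (mode == "rest") {
    ev <- ev[ev$condition == "rest", , drop = FALSE]
    for (r in seq_len(nrow(ev))) {
      blockEnd <- min(ev$sample[r] + ev$duration[r] - 1L, n)
      s <- seq(from = ev$sample[r], by = len,
               length.out = max(0L, (blockEnd - ev$sample[r] + 1L) %/% len))
      starts <- c(starts, s)
      meta <- c(meta, rep(list(list(condition = "rest",
                                    session = ev$session[r])), length(s)))
    }
  } else {
    if (is.null(condition)) {
      ev <- ev[ev$condition != "rest", , drop = FALSE]
    } else {
      ev <- ev[ev$condition %in% condition, , drop = FALSE]
    }
    pre <- round(0.1 * fs)
    starts <- ev$sample - pre
    meta <- lapply(seq_len(nrow(ev)), function(r)
      list(condition = ev$condition[r], session = ev$session[r]))
  }

  skippedEdge <- 0L
  skippedArtifact <- 0L
  segs <- list()
  for (k in seq_along(starts)) {
    s <- starts[k]
    e <- s + len - 1L
    if (s < 1L || e > n) {
      skippedEdge <- skippedEdge + 1L
      next
    }
    if (any(mask[s:e])) {
      skippedArtifact <- skippedArtifact + 1L
      next
    }
    segs[[length(segs) + 1L]] <- new("Segment",
      data = recording@signal[, s:e, drop = FALSE],
      fs = fs, channelNames = recording@channelNames,
      condition = meta[[k]]$condition,
      session = as.integer(meta[[k]]$session),
      participantId = as.character(participantId),
      onsetSample = as.integer(s))
  }
  if (skippedEdge > 0L)
    message(sprintf("%d segment(s) skipped at recording edge", skippedEdge))
  attr(segs, "skippedArtifact") <- skippedArtifact
  attr(segs, "skippedEdge") <- skippedEdge
  segs
}
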