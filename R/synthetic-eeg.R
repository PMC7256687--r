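#' Build MVAR coefficients from a coupling graph
#'
#' Each channel is an AR(2) oscillator with pole radius \code{r} at its
#' resonant frequency; directed coupling entries are added at the given
#' lags. Resonant frequencies default to the alpha range, spread evenly
#' over 9-11 Hz across channels so that coupled power concentrates in a
#' physiologically typical band.
#'
#' @param coupling data.frame with columns \code{from}, \code{to},
#'   \code{lag}, \code{strength} (may have zero rows).
#' @param nChannels number of channels.
#' @param fs sampling rate Hz.
#' @param f0 resonant frequency (scalar or per channel).
#' @param r pole radius (0 < r < 1).
#' @param order model order of the returned array (>= max coupling lag,
#'   >= 2).
#' @return coefficient array nChannels x nChannels x order.
#' @export
couplingToMVAR <- function(coupling = NULL, nChannels, fs = 500,
                           f0 = NULL, r = 0.9, order = NULL) {
  if (is.null(f0))
    f0 <- seq(9, 11, length.out = nChannels)
  f0 <- rep_len(f0, nChannels)
  maxLag <- if (!is.null(coupling) && nrow(coupling)) max(coupling$lag) else 1L
  if (is.null(order)) order <- max(2L, maxLag)
  A <- array(0, dim = c(nChannels, nChannels, order))
  for (i in seq_len(nChannels)) {
    A[i, i, 1] <- 2 * r * cos(2 * pi * f0[i] / fs)
    A[i, i, 2] <- -r^2
  }
  if (!is.null(coupling) && nrow(coupling)) {
    for (k in seq_len(nrow(coupling)))
      A[coupling$to[k], coupling$from[k], coupling$lag[k]] <-
        A[coupling$to[k], coupling$from[k], coupling$lag[k]] +
        coupling$strength[k]
  }
  A
}

#' Generate a synthetic multichannel EEG recording
#'
#' Realizes the MVAR process defined by the coupling graph (stable by
#' precondition; an unstable coefficient set raises an explicit error),
#' scales it to a typical scalp amplitude, adds white observation noise,
#' and attaches the requested event markers. The signal is zero-mean and
#' stationary.
#'
#' @param coupling data.frame (\code{from}, \code{to}, \code{lag},
#'   \code{strength}) or NULL for uncoupled channels.
#' @param nChannels number of channels (default 17).
#' @param fs sampling rate (default 500 Hz).
#' @param durationS recording length in seconds.
#' @param seed integer seed.
#' @param channelNames defaults to the 17 standard scalp channels when
#'   \code{nChannels == 17}.
#' @param events optional event data.frame (see
#'   \linkS4class{EEGRecording}).
#' @param targetSD per-channel signal standard deviation, microvolts.
#' @param obsNoiseSD observation white noise SD, microvolts.
#' @param r,f0 oscillator pole radius and resonant frequency passed to
#'   [couplingToMVAR()].
#' @return an \linkS4class{EEGRecording}.
#' @export
generateMVAREEG <- function(coupling = NULL, nChannels = 17L, fs = 500,
                            durationS, seed = 1L, channelNames = NULL,
                            events = NULL, targetSD = 10, obsNoiseSD = 1,
                            r = 0.9, f0 = NULL) {
  A <- couplingToMVAR(coupling, nChannels, fs = fs, r = r, f0 = f0)
  rad <- companionRadius(A)
  if (rad >= 1)
    stop(sprintf(
      "coupling graph yields an unstable MVAR process (radius %.4f >= 1)",
      rad))
  n <- round(durationS * fs)
  x <- simulateMVAR(A, diag(nChannels), n = n, seed = seed)
  sdnow <- apply(x, 1L, stats::sd)
  x <- x * (targetSD / sdnow)
  set.seed(deriveSeed(seed, 7L))
  x <- x + matrix(rnorm(length(x), sd = obsNoiseSD), nrow(x), ncol(x))
  if (is.null(channelNames))
    channelNames <- if (nChannels == 17L) defaultAnalysisChannels()
      else paste0("ch", seq_len(nChannels))
  eegRecording(x, fs, channelNames, reference = "synthetic",
               events = events)
}

#' Standard task event layout for one synthetic session
#'
#' A rest block at the start followed by blocks of stimulus events for
#' each task condition, with a fixed stimulus-to-stimulus interval.
#'
#' @param fs sampling rate.
#' @param restDurationS rest block length in seconds (default 180).
#' @param nTrials trials per task condition (default 72).
#' @param conditions task conditions in presentation order.
#' @param session session index.
#' @param trialIntervalS seconds between consecutive stimulus onsets
#'   (1 s segment + response + intertrial interval).
#' @return list with \code{events} (data.frame) and \code{durationS},
#'   the total recording length needed.
#' @export
taskEventLayout <- function(fs = 500, restDurationS = 180, nTrials = 72L,
                            conditions = c("learning", "recall",
                                           "recognition"),
                            session = 1L, trialIntervalS = 2.5) {
  restSamples <- round(restDurationS * fs)
  ev <- data.frame(sample = 1L, condition = "rest",
                   session = as.integer(session),
                   duration = restSamples)
  cursor <- restSamples + round(fs)  # 1 s gap after rest
  for (cond in conditions) {
    onsets <- cursor + round((seq_len(nTrials) - 1L) * trialIntervalS * fs) +
      round(0.1 * fs)  # leave room for the 100 ms pre-stimulus window
    ev <- rbind(ev, data.frame(sample = as.integer(onsets),
                               condition = cond,
                               session = as.integer(session),
                               duration = 0L))
    cursor <- max(onsets) + round(trialIntervalS * fs)
  }
  list(events = ev, durationS = ceiling(cursor / fs) + 2)
}

#' Inject amplitude artifacts with known ground truth
#'
#' Adds, at random times drawn from the given rate, the three artifact
#' types the amplitude rules are designed to catch: step offsets (jump
#' above the step threshold), high-amplitude excursions (smooth bumps
#' exceeding the 200 ms range rule) and flat stretches (signal replaced
#' by a constant). Events injected with amplitudes below the detection
#' thresholds trigger a warning (undetectable by design).
#'
#' @param recording an \linkS4class{EEGRecording}.
#' @param ratePerMin expected artifact events per minute (0 = none).
#' @param stepAmplitude step height, microvolts (default 300).
#' @param excursionAmplitude bump height, microvolts (default 300).
#' @param flatDurationS flat stretch length, seconds (default 0.15).
#' @param types subset of c("step", "excursion", "flat").
#' @param seed integer seed.
#' @return list with \code{recording} (signal with artifacts added) and
#'   \code{truth}, a data.frame of injected events (\code{sample},
#'   \code{type}, \code{channel}).
#' @export
injectArtifacts <- function(recording, ratePerMin = 2,
                            stepAmplitude = 300,
                            excursionAmplitude = 300,
                            flatDurationS = 0.15,
                            types = c("step", "excursion", "flat"),
                            seed = 1L) {
  stopifnot(is(recording, "EEGRecording"))
  types <- match.arg(types, several.ok = TRUE)
  fs <- recording@fs
  n <- ncol(recording@signal)
  truth <- data.frame(sample = integer(), type = character(),
                      channel = character())
  if (ratePerMin <= 0)
    return(list(recording = recording, truth = truth))
  if (stepAmplitude <= 50 && "step" %in% types)
    warning("step amplitude below the 50 uV/sample rule: undetectable")
  if (excursionAmplitude <= 200 && "excursion" %in% types)
    warning("excursion amplitude below the 200 uV range rule: undetectable")
  set.seed(seed)
  nEvents <- stats::rpois(1L, ratePerMin * n / fs / 60)
  if (nEvents == 0)
    return(list(recording = recording, truth = truth))
  margin <- round(1.5 * fs)
  at <- sort(sample(margin:(n - margin), nEvents))
  kind <- sample(types, nEvents, replace = TRUE)
  chIdx <- sample(nrow(recording@signal), nEvents, replace = TRUE)
  sig <- recording@signal
  for (k in seq_len(nEvents)) {
    t0 <- at[k]
    i <- chIdx[k]
    if (kind[k] == "step") {
      len <- round(0.2 * fs)
      sig[i, t0:(t0 + len)] <- sig[i, t0:(t0 + len)] + stepAmplitude
    } else if (kind[k] == "excursion") {
      len <- round(0.15 * fs)
      bump <- excursionAmplitude * sin(pi * seq_len(len) / len)^2
      sig[i, t0:(t0 + len - 1L)] <- sig[i, t0:(t0 + len - 1L)] + bump
    } else {
      len <- round(flatDurationS * fs)
      sig[i, t0:(t0 + len - 1L)] <- sig[i, t0]
    }
  }
  out <- recording
  out@signal <- sig
  list(recording = out,
       truth = data.frame(sample = at, type = kind,
                          channel = recording@channelNames[chIdx]))
}
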