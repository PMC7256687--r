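#' Decline-planting settings
#'
#' Per-domain fraction of decliners and the construction of the planted
#' effect. Default fractions mirror a cohort in which roughly half the
#' participants decline in the cognitive domains while depression
#' worsens in about 15%. Each domain plants its drop on one designated
#' subscale that belongs to no other domain, so domain labels stay
#' independent; decliners also receive a baseline deficit on that
#' subscale so that baseline neuropsychology carries a recoverable
#' signal.
#'
#' @param fractions named numeric, fraction of decliners per domain.
#' @param dropSD planted follow-up drop in normative SD units (>= 1).
#' @param baselineShiftSD baseline deficit of decliners, SD units.
#' @param targetSubscale named character, the subscale carrying each
#'   domain's planted drop.
#' @return list of settings.
#' @export
declineSpec <- function(fractions = c(executive = 0.54,
                                      visual_verbal_memory = 0.46,
                                      divided_attention = 0.49,
                                      depression = 0.15),
                        dropSD = 1.2, baselineShiftSD = 1,
                        targetSubscale = c(
                          executive = "matrices",
                          visual_verbal_memory = "vlmt_learning",
                          divided_attention = "visual_reaction_2",
                          depression = "bdi")) {
  if (any(fractions < 0 | fractions > 1))
    stop("decline fractions must lie in [0, 1]")
  list(fractions = fractions, dropSD = dropSD,
       baselineShiftSD = baselineShiftSD,
       targetSubscale = targetSubscale)
}

#' Generate baseline and follow-up neuropsychological tables
#'
#' Baseline raw scores are drawn around the normative means; planted
#' decliners receive a baseline deficit and a follow-up drop of
#' \code{dropSD} normative SDs on their domain's target subscale, while
#' every other change (including all changes of non-decliners) is drawn
#' uniformly within \code{[-maxBenignSD, maxBenignSD]} SDs, strictly
#' below the 1 SD decline criterion. Raw-score directions follow the
#' battery's direction column, so a planted depression decline is an
#' increase in the BDI raw score.
#'
#' @param assign data.frame: \code{participant_id}, \code{group}, plus
#'   one 0/1 column per domain with the planted decline assignment.
#' @param spec settings from [declineSpec()].
#' @param norms battery from [defaultBattery()].
#' @param domains domain definitions from [defaultDomains()].
#' @param maxBenignSD bound on benign changes in SD units (< 1).
#' @param seed integer seed.
#' @return long data.frame with both sessions (columns
#'   \code{participant_id}, \code{group}, \code{session},
#'   \code{subscale}, \code{raw}).
#' @export
generateNeuropsych <- function(assign, spec = declineSpec(),
                               norms = defaultBattery(),
                               domains = defaultDomains(),
                               maxBenignSD = 0.5, seed = 1L) {
  stopifnot(maxBenignSD < 1)
  unknown <- setdiff(unname(spec$targetSubscale), norms$subscale)
  if (length(unknown))
    stop(sprintf("decline spec references unknown subscale(s): %s",
                 paste(unknown, collapse = ", ")))
  doms <- intersect(names(domains), names(assign))
  rows <- list()
  for (k in seq_len(nrow(assign))) {
    pid <- assign$participant_id[k]
    set.seed(deriveSeed(seed, k, 3L))
    # baseline z per subscale (performance-scale: higher = better)
    zb <- rnorm(nrow(norms), 0, 0.8)
    names(zb) <- norms$subscale
    dz <- runif(nrow(norms), -maxBenignSD, maxBenignSD)
    names(dz) <- norms$subscale
    for (d in doms) {
      if (assign[[d]][k] == 1L) {
        tgt <- spec$targetSubscale[[d]]
        zb[tgt] <- zb[tgt] - spec$baselineShiftSD
        dz[tgt] <- -spec$dropSD
      }
    }
    zf <- zb + dz
    # map performance z back to raw scores, honouring scale direction
    sgn <- ifelse(norms$direction == "higher_worse", -1, 1)
    rawb <- norms$norm_mean + sgn * zb * norms$norm_sd
    rawf <- norms$norm_mean + sgn * zf * norms$norm_sd
    rows[[length(rows) + 1L]] <- data.frame(
      participant_id = pid, group = assign$group[k],
      session = rep(c("baseline", "followup"), each = nrow(norms)),
      subscale = rep(norms$subscale, 2L),
      raw = c(rawb, rawf))
  }
  do.call(rbind, rows)
}

#' Full synthetic cohort specification
#'
#' Defaults mirror the study conditions: five diagnostic groups of sizes
#' 19/4/6/3/18, 17-channel EEG at 500 Hz with a 3 min rest block and 72
#' trials per task condition, an 83-region labeled volume, and the
#' decline fractions of [declineSpec()].
#'
#' @param groupSizes named integer vector of participants per group.
#' @param decline settings from [declineSpec()].
#' @param eeg list: nChannels, fs, restDurationS, nTrials, conditions,
#'   coupling graph, couplingScale (decliner multiplier), effectDomain
#'   (domain whose decliners carry the EEG signature), targetSD,
#'   obsNoiseSD.
#' @param mri settings from [mriSpec()] plus effect fields:
#'   effectDomain, effectRegions, volumeScale, textureShift.
#' @param artifact list: ratePerMin (0 disables injection).
#' @param modalities subset of c("eeg", "mri", "psy") to generate.
#' @param seed root seed; every participant and modality derives its own
#'   substream deterministically from it.
#' @return list of settings for [generateCohort()].
#' @export
cohortSpec <- function(groupSizes = c(MCI = 19L, SCC = 4L, TLEr = 6L,
                                      TLEl = 3L, HC = 18L),
                       decline = declineSpec(),
                       eeg = list(), mri = list(), artifact = list(),
                       modalities = c("eeg", "mri", "psy"),
                       seed = 1L) {
  eegDefaults <- list(
    nChannels = 17L, fs = 500, restDurationS = 180, nTrials = 72L,
    conditions = c("learning", "recall", "recognition"),
    coupling = data.frame(
      from = c(15L, 1L, 2L), to = c(17L, 5L, 6L),
      lag = c(1L, 1L, 1L), strength = c(0.25, 0.25, 0.25)),
    couplingScale = 2, effectDomain = "executive",
    targetSD = 10, obsNoiseSD = 1)
  eeg <- utils::modifyList(eegDefaults, eeg)
  if (eeg$fs <= 2 * 125)
    stop("fs must exceed twice the maximum analysis frequency (125 Hz)")
  if (eeg$nTrials < 1L) stop("nTrials must be >= 1")
  mriDefaults <- c(mriSpec(), list(
    effectDomain = "executive", effectRegions = 1:4,
    volumeScale = 0.8, textureShift = 5))
  mri <- utils::modifyList(mriDefaults, mri)
  artifact <- utils::modifyList(list(ratePerMin = 0), artifact)
  list(groupSizes = groupSizes, decline = decline, eeg = eeg, mri = mri,
       artifact = artifact, modalities = modalities,
       seed = as.integer(seed))
}

#' Generate a synthetic multimodal cohort with known ground truth
#'
#' Draws participants by group, assigns decliners per domain at the
#' specified fractions, and generates the requested modalities:
#' neuropsychological tables with planted >= 1 SD declines, labeled MRI
#' volumes with volume/texture shifts in designated regions for the MRI
#' effect domain's decliners, and MVAR EEG in which the planted coupling
#' strengths are scaled for the EEG effect domain's decliners. Identical
#' spec and seed give a bit-identical cohort.
#'
#' @param spec a [cohortSpec()].
#' @return list with \code{participants} (data.frame with group and the
#'   per-domain 0/1 decline assignment), \code{neuropsych} (long table),
#'   \code{mri} (named list of \linkS4class{LabeledVolume}), \code{eeg}
#'   (named list; each element has the recording and, when artifacts are
#'   injected, the ground-truth event table) and \code{groundTruth}
#'   (decline labels, informative feature identifiers, coupling graph).
#' @export
generateCohort <- function(spec = cohortSpec()) {
  n <- sum(spec$groupSizes)
  participants <- data.frame(
    participant_id = sprintf("P%03d", seq_len(n)),
    group = rep(names(spec$groupSizes), spec$groupSizes))
  domains <- names(spec$decline$fractions)
  set.seed(deriveSeed(spec$seed, 1L))
  for (d in domains) {
    k <- round(spec$decline$fractions[[d]] * n)
    participants[[d]] <- 0L
    if (k > 0)
      participants[[d]][sample(n, k)] <- 1L
  }

  out <- list(participants = participants)
  informative <- character(0)

  if ("psy" %in% spec$modalities) {
    out$neuropsych <- generateNeuropsych(
      participants, spec = spec$decline,
      seed = deriveSeed(spec$seed, 2L))
    informative <- c(informative,
                     paste0("psy:", unname(spec$decline$targetSubscale)))
  }

  if ("mri" %in% spec$modalities) {
    mriCfg <- spec$mri
    out$mri <- vector("list", n)
    names(out$mri) <- participants$participant_id
    base <- mriSpec(dims = mriCfg$dims, nRegions = mriCfg$nRegions,
                    grid = mriCfg$grid,
                    semiAxisFrac = mriCfg$semiAxisFrac,
                    jitterFrac = mriCfg$jitterFrac,
                    baseIntensity = mriCfg$baseIntensity,
                    regionMeanSD = mriCfg$regionMeanSD,
                    noiseSD = mriCfg$noiseSD,
                    textureContrast = mriCfg$textureContrast,
                    volumePerturbSD = mriCfg$volumePerturbSD)
    for (k in seq_len(n)) {
      eff <- NULL
      if (participants[[mriCfg$effectDomain]][k] == 1L) {
        rgn <- as.character(mriCfg$effectRegions)
        eff <- list(
          volumeScale = stats::setNames(
            rep(mriCfg$volumeScale, length(rgn)), rgn),
          textureShift = stats::setNames(
            rep(mriCfg$textureShift, length(rgn)), rgn))
      }
      out$mri[[k]] <- generateLabeledVolume(
        base, participantEffect = eff,
        seed = deriveSeed(spec$seed, k, 4L),
        atlasSeed = deriveSeed(spec$seed, 5L))
    }
    informative <- c(informative,
                     paste0("vol:region", spec$mri$effectRegions))
  }

  if ("eeg" %in% spec$modalities) {
    eegCfg <- spec$eeg
    layout <- taskEventLayout(fs = eegCfg$fs,
                              restDurationS = eegCfg$restDurationS,
                              nTrials = eegCfg$nTrials,
                              conditions = eegCfg$conditions)
    out$eeg <- vector("list", n)
    names(out$eeg) <- participants$participant_id
    for (k in seq_len(n)) {
      coup <- eegCfg$coupling
      if (participants[[eegCfg$effectDomain]][k] == 1L)
        coup$strength <- coup$strength * eegCfg$couplingScale
      rec <- generateMVAREEG(
        coupling = coup, nChannels = eegCfg$nChannels, fs = eegCfg$fs,
        durationS = layout$durationS,
        seed = deriveSeed(spec$seed, k, 5L),
        events = layout$events, targetSD = eegCfg$targetSD,
        obsNoiseSD = eegCfg$obsNoiseSD)
      if (spec$artifact$ratePerMin > 0) {
        inj <- injectArtifacts(rec,
                               ratePerMin = spec$artifact$ratePerMin,
                               seed = deriveSeed(spec$seed, k, 6L))
        out$eeg[[k]] <- inj
      } else {
        out$eeg[[k]] <- list(recording = rec,
                             truth = data.frame(sample = integer(),
                                                type = character(),
                                                channel = character()))
      }
    }
    ch <- if (eegCfg$nChannels == 17L) defaultAnalysisChannels()
      else paste0("ch", seq_len(eegCfg$nChannels))
    informative <- c(informative, paste0(
      "PDC:alpha:", ch[spec$eeg$coupling$from], "->",
      ch[spec$eeg$coupling$to]))
  }

  out$groundTruth <- list(
    declineLabels = participants[, c("participant_id", domains)],
    informativeFeatures = informative,
    coupling = spec$eeg$coupling)
  out
}
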