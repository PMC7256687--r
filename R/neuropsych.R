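#' Default neuropsychological battery with normative values
#'
#' The 23-subscale battery: three Wechsler intelligence subscales (IQ
#' norms 100/15), four verbal fluency T-scores (50/10), four verbal
#' learning and memory T-scores (50/10), nine attentional performance
#' scales (T-scores 50/10 for reaction/flexibility, error and miss
#' counts 4/2.5), a multiple-choice lexical IQ (100/15), the cerebral
#' damage test percentile rank (50/25) and the Beck Depression Inventory
#' sum score (8/7). \code{direction} marks scales where a larger raw
#' score means worse performance (depression, errors, misses); z-scoring
#' flips these so that a larger z is always better. All values are
#' editable defaults, not estimates of any cohort.
#'
#' @return data.frame with columns \code{subscale}, \code{norm_mean},
#'   \code{norm_sd}, \code{direction}.
#' @export
defaultBattery <- function() {
  sub <- c("matrices", "mosaics", "repeating_numbers",
           "verbal_fluency", "categorical_fluency", "semantic_fluency",
           "category_transition",
           "vlmt_learning", "vlmt_consolidation", "vlmt_recall",
           "vlmt_recognition",
           "tap_flexibility", "acoustic_reaction_1", "visual_reaction_1",
           "errors_1", "misses_1", "acoustic_reaction_2",
           "visual_reaction_2", "errors_2", "misses_2",
           "mwt_iq", "dcs_percentile", "bdi")
  mean <- c(100, 100, 100, 50, 50, 50, 50, 50, 50, 50, 50,
            50, 50, 50, 4, 4, 50, 50, 4, 4, 100, 50, 8)
  sd <- c(15, 15, 15, 10, 10, 10, 10, 10, 10, 10, 10,
          10, 10, 10, 2.5, 2.5, 10, 10, 2.5, 2.5, 15, 25, 7)
  dir <- rep("higher_better", length(sub))
  dir[sub %in% c("errors_1", "misses_1", "errors_2", "misses_2", "bdi")] <-
    "higher_worse"
  data.frame(subscale = sub, norm_mean = mean, norm_sd = sd,
             direction = dir, stringsAsFactors = FALSE)
}

#' Default cognitive domain definitions
#'
#' Executive functions (7 subscales), visual-verbal memory (5), divided
#' attention (3) and depression (BDI sum). Overlap between domains is
#' allowed. The divided-attention membership is an explicit editable
#' choice, as the underlying task summary scores admit more than one
#' reading.
#'
#' @return named list of character vectors of subscale ids.
#' @export
defaultDomains <- function() {
  list(
    executive = c("matrices", "repeating_numbers", "verbal_fluency",
                  "categorical_fluency", "semantic_fluency",
                  "category_transition", "tap_flexibility"),
    visual_verbal_memory = c("vlmt_learning", "vlmt_consolidation",
                             "vlmt_recall", "vlmt_recognition",
                             "dcs_percentile"),
    divided_attention = c("tap_flexibility", "acoustic_reaction_2",
                          "visual_reaction_2"),
    depression = "bdi"
  )
}

#' Normative z-scores for a neuropsychological score table
#'
#' z = (raw - norm_mean) / norm_sd per subscale; for higher-worse scales
#' the sign is flipped, so that a larger z is uniformly better and a
#' decline is uniformly a decrease in z (including worsening of
#' depressive symptoms).
#'
#' @param table data.frame with columns \code{participant_id},
#'   \code{group}, \code{session} ("baseline"/"followup"),
#'   \code{subscale}, \code{raw}.
#' @param norms battery data.frame as from [defaultBattery()].
#' @return the table with an added \code{z} column.
#' @export
zscoreTable <- function(table, norms = defaultBattery()) {
  need <- c("participant_id", "session", "subscale", "raw")
  stopifnot(all(need %in% names(table)))
  miss <- setdiff(unique(table$subscale), norms$subscale)
  if (length(miss))
    stop(sprintf("no norms for subscale(s): %s",
                 paste(miss, collapse = ", ")))
  i <- match(table$subscale, norms$subscale)
  z <- (table$raw - norms$norm_mean[i]) / norms$norm_sd[i]
  flip <- norms$direction[i] == "higher_worse"
  z[flip] <- -z[flip]
  table$z <- z
  table
}

#' Composite domain decline labels
#'
#' A participant is labelled 1 (decline) in a domain iff the follow-up
#' z-score dropped by at least one normative standard deviation
#' (z_followup - z_baseline <= -1) on at least one member subscale.
#' Improvements and sub-threshold changes yield 0. Because z-scoring
#' flips higher-worse scales, an increase of >= 1 SD in depressive
#' symptoms is a drop of >= 1 in z and is labelled identically.
#' Participants missing the follow-up session are excluded with a
#' message.
#'
#' @param ztable z-scored long table (see [zscoreTable()]) with both
#'   sessions.
#' @param domains named list of member subscales
#'   (default [defaultDomains()]).
#' @param threshold decline threshold in normative SD units (default 1).
#' @return data.frame with columns \code{participant_id}, \code{domain},
#'   \code{label}.
#' @export
declineLabels <- function(ztable, domains = defaultDomains(),
                          threshold = 1) {
  stopifnot("z" %in% names(ztable))
  unknown <- setdiff(unlist(domains), unique(ztable$subscale))
  if (length(unknown))
    stop(sprintf("domain definition references unknown subscale(s): %s",
                 paste(unknown, collapse = ", ")))
  base <- ztable[ztable$session == "baseline", ]
  fup <- ztable[ztable$session == "followup", ]
  ids <- unique(base$participant_id)
  noFup <- setdiff(ids, unique(fup$participant_id))
  if (length(noFup)) {
    message(sprintf("%d participant(s) without follow-up excluded: %s",
                    length(noFup), paste(noFup, collapse = ", ")))
    ids <- setdiff(ids, noFup)
  }
  out <- expand.grid(participant_id = ids, domain = names(domains),
                     stringsAsFactors = FALSE)
  out$label <- NA_integer_
  for (r in seq_len(nrow(out))) {
    pid <- out$participant_id[r]
    subs <- domains[[out$domain[r]]]
    zb <- base$z[base$participant_id == pid][
      match(subs, base$subscale[base$participant_id == pid])]
    zf <- fup$z[fup$participant_id == pid][
      match(subs, fup$subscale[fup$participant_id == pid])]
    ok <- !is.na(zb) & !is.na(zf)
    out$label[r] <- as.integer(any((zf - zb)[ok] <= -threshold))
  }
  out
}

#' Baseline neuropsychological feature matrix
#'
#' One row per participant, one column per subscale, values are the
#' baseline z-scores, column identifiers \code{"psy:<subscale>"}.
#'
#' @param ztable z-scored long table.
#' @return numeric matrix with participant ids as rownames.
#' @export
baselineFeatures <- function(ztable) {
  stopifnot("z" %in% names(ztable))
  base <- ztable[ztable$session == "baseline", ]
  subs <- unique(base$subscale)
  ids <- unique(base$participant_id)
  m <- matrix(NA_real_, length(ids), length(subs),
              dimnames = list(ids, paste0("psy:", subs)))
  for (k in seq_along(ids)) {
    rowsk <- base[base$participant_id == ids[k], ]
    m[k, paste0("psy:", rowsk$subscale)] <- rowsk$z
  }
  m
}
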