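# Transition classification and dwell-time kinetics. A fluorescent state is
# assigned to an open conformation and a fluorescence-quenched state to a
# closed conformation of the probed clamp element; same-direction steps in
# the two colour channels within the synchronicity window are one concerted
# conformational transition.

.dirQuench <- function(direction) ifelse(direction == "down", "quench",
                                         "recovery")

#' Pair same-direction steps across the two colour channels
#'
#' Candidate pairs are same-direction steps within
#' \code{syncWindowFrames}; they are matched greedily, one-to-one, by
#' ascending |frame difference| (ties: earlier green frame). Unmatched steps
#' are non-synchronous; an unmatched terminal quench with no later recovery
#' in its channel is a bleach candidate.
#'
#' @param stepsGreen,stepsRed data.frames for one molecule with columns
#'   \code{frame} (0-based) and \code{direction} ("down"/"up").
#' @param config an \linkS4class{AnalysisConfig}.
#' @return data.frame with columns \code{channel}, \code{frame},
#'   \code{direction} ("quench"/"recovery"), \code{class} ("synchronous",
#'   "non_synchronous" or "bleach_candidate") and \code{partner_frame} (NA
#'   when unmatched).
#' @examples
#' g <- data.frame(frame = 100L, direction = "down")
#' r <- data.frame(frame = 104L, direction = "down")
#' pairSynchronous(g, r, AnalysisConfig())
#' @export
pairSynchronous <- function(stepsGreen, stepsRed,
                            config = AnalysisConfig()) {
  validObject(config)
  mk <- function(df, ch) {
    if (is.null(df) || !nrow(df))
      return(data.frame(channel = character(0), frame = integer(0),
                        direction = character(0), class = character(0),
                        partner_frame = integer(0)))
    data.frame(channel = ch, frame = as.integer(df$frame),
               direction = .dirQuench(df$direction),
               class = "non_synchronous", partner_frame = NA_integer_,
               stringsAsFactors = FALSE)
  }
  g <- mk(stepsGreen, "green"); r <- mk(stepsRed, "red")
  if (nrow(g) && nrow(r)) {
    cand <- expand.grid(i = seq_len(nrow(g)), j = seq_len(nrow(r)))
    cand$dd <- abs(g$frame[cand$i] - r$frame[cand$j])
    cand$sameDir <- g$direction[cand$i] == r$direction[cand$j]
    cand <- cand[cand$sameDir & cand$dd <= config@syncWindowFrames, ,
                 drop = FALSE]
    cand <- cand[order(cand$dd, g$frame[cand$i]), , drop = FALSE]
    usedG <- logical(nrow(g)); usedR <- logical(nrow(r))
    for (k in seq_len(nrow(cand))) {
      i <- cand$i[k]; j <- cand$j[k]
      if (usedG[i] || usedR[j]) next
      usedG[i] <- TRUE; usedR[j] <- TRUE
      g$class[i] <- r$class[j] <- "synchronous"
      g$partner_frame[i] <- r$frame[j]
      r$partner_frame[j] <- g$frame[i]
    }
  }
  ev <- rbind(g, r)
  # terminal unmatched quench with no subsequent recovery -> bleach candidate
  for (ch in c("green", "red")) {
    sel <- ev$channel == ch
    if (!any(sel)) next
    chev <- ev[sel, ]
    for (k in seq_len(nrow(chev))) {
      if (chev$class[k] != "non_synchronous" ||
          chev$direction[k] != "quench") next
      later <- chev$frame > chev$frame[k] & chev$direction == "recovery"
      if (!any(later)) chev$class[k] <- "bleach_candidate"
    }
    ev[sel, ] <- chev
  }
  rownames(ev) <- NULL
  ev[order(ev$frame, ev$channel), ]
}

#' Classify all molecules of a two-colour step table
#'
#' Runs \code{\link{pairSynchronous}} per molecule and, because bleaching
#' ends the usable part of a recording, marks every event after a
#' molecule's first bleach candidate (in either channel) as
#' \code{post_bleach} so it is excluded from transition counts.
#'
#' @param steps data.frame with columns \code{molecule_id}, \code{channel},
#'   \code{frame}, \code{direction}.
#' @param config an \linkS4class{AnalysisConfig}.
#' @return data.frame of classified \code{TransitionEvent} rows with
#'   \code{molecule_id} prepended.
#' @export
classifyTransitions <- function(steps, config = AnalysisConfig()) {
  out <- list()
  for (m in unique(steps$molecule_id)) {
    sm <- steps[steps$molecule_id == m, ]
    ev <- pairSynchronous(sm[sm$channel == "green", ],
                          sm[sm$channel == "red", ], config)
    if (!nrow(ev)) next
    bl <- ev$frame[ev$class == "bleach_candidate"]
    if (length(bl)) {
      post <- ev$frame > min(bl)
      ev$class[post & ev$class != "bleach_candidate"] <- "post_bleach"
    }
    out[[length(out) + 1L]] <- cbind(data.frame(molecule_id = m), ev)
  }
  if (!length(out))
    return(data.frame(molecule_id = integer(0), channel = character(0),
                      frame = integer(0), direction = character(0),
                      class = character(0), partner_frame = integer(0)))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Extract dwell records from step tables
#'
#' Intervals between consecutive steps of one channel become dwell records;
#' the state is closed after a down (quench) step and open after an up
#' (recovery) step. Intervals abutting the trace start or end are flagged
#' censored; open dwells terminated by a bleach candidate are censored (or
#' the whole trace dropped, per \code{bleachTailPolicy}).
#'
#' @param steps data.frame (molecule_id, channel, frame, direction).
#' @param nFrames number of frames in each trace.
#' @param config an \linkS4class{AnalysisConfig}.
#' @param events optional classified event table from
#'   \code{\link{classifyTransitions}}, used for censoring at bleach
#'   candidates and for dwell provenance.
#' @return data.frame with molecule_id, channel, state ("open"/"closed"),
#'   duration_s, left_censored, right_censored, provenance.
#' @export
extractDwells <- function(steps, nFrames, config = AnalysisConfig(),
                          events = NULL) {
  validObject(config)
  dt <- config@frameIntervalS
  rows <- list()
  for (m in unique(steps$molecule_id)) {
    for (ch in unique(steps$channel[steps$molecule_id == m])) {
      s <- steps[steps$molecule_id == m & steps$channel == ch, ]
      s <- s[order(s$frame), ]
      if (nrow(s) < 1L) next
      if (any(diff(s$frame) <= 0))
        stop("overlapping steps for molecule ", m,
             " (upstream step-detection bug)")
      bleachFrames <- integer(0)
      classOf <- function(frame) {
        if (is.null(events)) return(NA_character_)
        k <- which(events$molecule_id == m & events$channel == ch &
                   events$frame == frame)
        if (length(k)) events$class[k[1L]] else NA_character_
      }
      if (!is.null(events))
        bleachFrames <- events$frame[events$molecule_id == m &
                                     events$channel == ch &
                                     events$class == "bleach_candidate"]
      bounds <- c(0L, s$frame, nFrames)
      states <- c(NA_character_,
                  ifelse(s$direction == "down", "closed", "open"))
      for (k in seq_len(length(bounds) - 1L)) {
        if (k == 1L) next                     # leading segment: no start step
        state <- states[k]
        startF <- bounds[k]; endF <- bounds[k + 1L]
        leftC <- FALSE
        rightC <- k == length(bounds) - 1L    # abuts trace end
        endsInBleach <- (k < length(bounds) - 1L) &&
          (bounds[k + 1L] %in% bleachFrames)
        if (endsInBleach) rightC <- TRUE
        startClass <- classOf(startF)
        prov <- if (is.na(startClass)) NA_character_
                else if (startClass == "synchronous") "synchronous"
                else "non_synchronous"
        rows[[length(rows) + 1L]] <- data.frame(
          molecule_id = m, channel = ch, state = state,
          duration_s = (endF - startF) * dt,
          left_censored = leftC, right_censored = rightC,
          provenance = prov, stringsAsFactors = FALSE)
      }
      if (!is.null(events) && config@bleachTailPolicy == "drop_trace" &&
          length(bleachFrames)) {
        drop <- vapply(rows, function(r)
          r$molecule_id[1L] == m && r$channel[1L] == ch, logical(1L))
        rows <- rows[!drop]
      }
    }
  }
  if (!length(rows))
    return(data.frame(molecule_id = integer(0), channel = character(0),
                      state = character(0), duration_s = numeric(0),
                      left_censored = logical(0), right_censored = logical(0),
                      provenance = character(0)))
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}

#' Count synchronous and non-synchronous transitions
#'
#' A synchronous pair counts as one transition. The non-synchronous
#' percentage is reported under both conventions: relative to the
#' synchronous count (100 N_ns / N_s, the headline convention) and as a
#' fraction of all transitions (100 N_ns / (N_s + N_ns)). Bleach candidates,
#' post-bleach events and DSPO recoveries are excluded.
#'
#' @param events classified event table (\code{\link{classifyTransitions}}),
#'   or a list/data.frame with columns \code{class}.
#' @return list with nSynchronous, nNonSynchronous, percentNonSyncRatio,
#'   percentNonSyncTotal.
#' @examples
#' synchronicityPercent(322, 57)   # the two conventions from raw counts
#' @export
summarizeSynchronicity <- function(events) {
  ns <- sum(events$class == "synchronous") / 2
  nn <- sum(events$class == "non_synchronous")
  c(list(nSynchronous = as.integer(ns), nNonSynchronous = as.integer(nn)),
    synchronicityPercent(ns, nn))
}

#' @rdname summarizeSynchronicity
#' @param nSynchronous,nNonSynchronous transition counts.
#' @export
synchronicityPercent <- function(nSynchronous, nNonSynchronous) {
  ratio <- if (nSynchronous > 0) 100 * nNonSynchronous / nSynchronous
           else if (nNonSynchronous == 0) 0 else Inf
  total <- if (nSynchronous + nNonSynchronous > 0)
             100 * nNonSynchronous / (nSynchronous + nNonSynchronous) else 0
  list(percentNonSyncRatio = ratio, percentNonSyncTotal = total)
}

#' Confirm PET quenching events by DSPO fluorescence recovery
#'
#' In one-colour AMP-PNP experiments, application of oxygen-rich solution
#' triggers dye-sensitized photo-oxidation of the tryptophan in dye/Trp
#' complexes and recovers the fluorescence of PET-quenched molecules; a
#' quench event is therefore PET-confirmed if and only if the same trace
#' shows a recovery step at or after the oxygen application time. Quench
#' events without recovery are indistinguishable from photobleaching and
#' stay unconfirmed; recoveries before oxygen application are flagged
#' anomalous.
#'
#' @param steps data.frame (molecule_id, frame, direction) from one-colour
#'   traces; a \code{channel} column is ignored.
#' @param o2ApplicationS oxygen application time, seconds.
#' @param frameIntervalS frame interval, seconds.
#' @param durationS trace duration, seconds (for validating the O2 time).
#' @return data.frame of quench events with columns \code{molecule_id},
#'   \code{frame}, \code{time_s}, \code{pet_confirmed}, plus an
#'   \code{anomalous_recovery} attribute table of pre-O2 recoveries.
#' @export
identifyPetEvents <- function(steps, o2ApplicationS, frameIntervalS,
                              durationS) {
  if (o2ApplicationS < 0 || o2ApplicationS > durationS)
    stop(sprintf("o2ApplicationS = %g lies outside the trace span [0, %g]",
                 o2ApplicationS, durationS))
  out <- list(); anom <- list()
  for (m in unique(steps$molecule_id)) {
    s <- steps[steps$molecule_id == m, ]
    s$time_s <- s$frame * frameIntervalS
    rec <- s[s$direction == "up", ]
    quench <- s[s$direction == "down", ]
    pre <- rec[rec$time_s < o2ApplicationS, ]
    if (nrow(pre))
      anom[[length(anom) + 1L]] <-
        data.frame(molecule_id = m, frame = pre$frame, time_s = pre$time_s)
    if (nrow(quench)) {
      confirmed <- vapply(quench$time_s, function(tq)
        any(rec$time_s >= o2ApplicationS & rec$time_s > tq), logical(1L))
      out[[length(out) + 1L]] <-
        data.frame(molecule_id = m, frame = quench$frame,
                   time_s = quench$time_s, pet_confirmed = confirmed)
    }
  }
  res <- if (length(out)) do.call(rbind, out)
         else data.frame(molecule_id = integer(0), frame = integer(0),
                         time_s = numeric(0), pet_confirmed = logical(0))
  rownames(res) <- NULL
  attr(res, "anomalous_recovery") <-
    if (length(anom)) do.call(rbind, anom)
    else data.frame(molecule_id = integer(0), frame = integer(0),
                    time_s = numeric(0))
  res
}

.fitDwellSet <- function(durations, modelSelection) {
  if (length(durations) < 10L) return(NULL)
  tryCatch(fitExponentialCdf(dwellCumSum(durations), modelSelection,
                             timeUnit = "s"),
           error = function(e) NULL)
}

#' Full kinetic analysis of a two-colour step table
#'
#' Classifies transitions, extracts dwell times per colour channel, fits
#' cumulative dwell-time curves (open dwells give the closure kinetics,
#' closed dwells the opening kinetics) and reports amplitude-weighted mean
#' rate constants together with the synchronicity counts.
#'
#' @param steps data.frame (molecule_id, channel, frame, direction), e.g.
#'   from \code{\link{idealizeTraces}}.
#' @param nFrames trace length in frames.
#' @param config an \linkS4class{AnalysisConfig}.
#' @param flagged optional data.frame (molecule_id, channel, flagged) from
#'   \code{\link{idealizeTraces}}: molecules with any flagged (single-level,
#'   no usable signal) channel are excluded, mirroring the experimental
#'   selection of molecules that show fluorescence in both colours.
#' @return a \linkS4class{KineticResult}.
#' @export
analyzeKinetics <- function(steps, nFrames, config = AnalysisConfig(),
                            flagged = NULL) {
  if (!is.null(flagged) && any(flagged$flagged)) {
    bad <- unique(flagged$molecule_id[flagged$flagged])
    steps <- steps[!steps$molecule_id %in% bad, , drop = FALSE]
  }
  events <- classifyTransitions(steps, config)
  counts <- summarizeSynchronicity(events)
  dwells <- extractDwells(steps, nFrames, config, events)
  ok <- !dwells$left_censored & !dwells$right_censored
  perChannel <- list()
  for (ch in unique(steps$channel)) {
    dOpen <- dwells$duration_s[ok & dwells$channel == ch &
                               dwells$state == "open"]
    dClosed <- dwells$duration_s[ok & dwells$channel == ch &
                                 dwells$state == "closed"]
    fOpen <- .fitDwellSet(dOpen, config@modelSelection)
    fClosed <- .fitDwellSet(dClosed, config@modelSelection)
    perChannel[[ch]] <- list(
      openFit = fOpen, closedFit = fClosed,
      kC = if (!is.null(fOpen)) meanRate(fOpen) else NA_real_,
      kO = if (!is.null(fClosed)) meanRate(fClosed) else NA_real_,
      nOpen = length(dOpen), nClosed = length(dClosed))
  }
  kCs <- vapply(perChannel, function(x) x$kC, numeric(1L))
  kOs <- vapply(perChannel, function(x) x$kO, numeric(1L))
  new("KineticResult",
      nSynchronous = counts$nSynchronous,
      nNonSynchronous = counts$nNonSynchronous,
      percentNonSyncRatio = counts$percentNonSyncRatio,
      percentNonSyncTotal = counts$percentNonSyncTotal,
      perChannel = perChannel,
      kC = mean(kCs, na.rm = TRUE), kO = mean(kOs, na.rm = TRUE))
}
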