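#' @rdname TraceSet-class
#' @param x,object an object.
#' @export
setGeneric("frameInterval", function(x) standardGeneric("frameInterval"))

#' @rdname TraceSet-class
#' @export
setGeneric("channelNames", function(x) standardGeneric("channelNames"))

#' @rdname TraceSet-class
#' @param channel channel name, e.g. \code{"green"} or \code{"red"}.
#' @export
setGeneric("traceMatrix", function(x, channel) standardGeneric("traceMatrix"))

#' @rdname TraceSet-class
#' @export
setGeneric("frameTimes", function(x) standardGeneric("frameTimes"))

#' @rdname TraceSet-class
#' @export
setGeneric("groundTruth", function(x) standardGeneric("groundTruth"))

#' @rdname ClampTrajectorySet-class
#' @param x an object with a generative event log.
#' @export
setGeneric("eventLog", function(x) standardGeneric("eventLog"))

#' @rdname ClampTrajectorySet-class
#' @export
setGeneric("stateMatrix", function(x, channel) standardGeneric("stateMatrix"))

#' Amplitude-weighted mean rate constant of an exponential fit
#'
#' The mean rate is the inverse of the amplitude-weighted sum of fitted time
#' constants, 1 / sum(a_i * tau_i), reported per minute. Amplitudes must be
#' normalized to sum to 1.
#'
#' @param fit an \linkS4class{ExponentialFit}.
#' @return rate constant in min^-1.
#' @examples
#' f <- new("ExponentialFit", amplitudes = 1, taus = 0.2, nComponents = 1L,
#'          rss = 0, bic = NA_real_, nDwells = 0L, timeUnit = "min",
#'          converged = TRUE)
#' meanRate(f)  # 5 min^-1
#' @export
setGeneric("meanRate", function(fit) standardGeneric("meanRate"))

# ---- accessors ----

#' @rdname ClampTrajectorySet-class
#' @export
setMethod("eventLog", "ClampTrajectorySet", function(x) x@events)

#' @rdname ClampTrajectorySet-class
#' @export
setMethod("stateMatrix", "ClampTrajectorySet", function(x, channel) {
  idx <- match(channel, x@channelNames)
  if (is.na(idx)) stop("unknown channel: ", channel)
  m <- x@states[, , idx, drop = FALSE]
  dim(m) <- dim(x@states)[1:2]
  m
})

#' @rdname ClampTrajectorySet-class
#' @export
setMethod("channelNames", "ClampTrajectorySet", function(x) x@channelNames)

#' @rdname ClampTrajectorySet-class
#' @export
setMethod("frameInterval", "ClampTrajectorySet",
          function(x) x@config@frameIntervalS)

#' @rdname TraceSet-class
#' @export
setMethod("frameInterval", "TraceSet",
          function(x) S4Vectors::metadata(x)$frameIntervalS)

#' @rdname TraceSet-class
#' @export
setMethod("channelNames", "TraceSet",
          function(x) SummarizedExperiment::assayNames(x))

#' @rdname TraceSet-class
#' @export
setMethod("traceMatrix", "TraceSet", function(x, channel) {
  if (!channel %in% channelNames(x)) stop("unknown channel: ", channel)
  SummarizedExperiment::assay(x, channel)
})

#' @rdname TraceSet-class
#' @export
setMethod("frameTimes", "TraceSet", function(x) x$time_s)

#' @rdname TraceSet-class
#' @export
setMethod("groundTruth", "TraceSet",
          function(x) S4Vectors::metadata(x)$groundTruth)

#' @rdname TraceSet-class
#' @export
setMethod("eventLog", "TraceSet", function(x) {
  gt <- groundTruth(x)
  if (is.null(gt)) stop("TraceSet carries no ground truth")
  eventLog(gt)
})

# ---- show methods ----

setMethod("show", "SimulationConfig", function(object) {
  cat("SimulationConfig:", object@mode, "\n",
      sprintf("  %d molecules, %.0f s at %.2g s/frame\n", object@nMolecules,
              object@durationS, object@frameIntervalS),
      sprintf("  k_close %.3g min^-1, k_open %.3g min^-1, p_uncoupled %.3g\n",
              object@kClose, object@kOpen, object@pUncoupled),
      sprintf("  bleach (green, red) = (%.3g, %.3g) min^-1, seed %d\n",
              object@kBleachGreen, object@kBleachRed, object@seed), sep = "")
})

setMethod("show", "ClampTrajectorySet", function(object) {
  d <- dim(object@states)
  cat(sprintf("ClampTrajectorySet: %d molecules x %d frames x %d channel(s)\n",
              d[1], d[2], d[3]))
  cat(sprintf("  mode %s, %d ground-truth events\n", object@config@mode,
              nrow(object@events)))
})

setMethod("show", "ChannelTransform", function(object) {
  cat("ChannelTransform (channel 2 -> channel 1)\n  linear:\n")
  print(round(object@linear, 6))
  cat(sprintf("  offset: (%.4f, %.4f) px; residual RMS %.4g px (%d beads)\n",
              object@offset[1], object@offset[2], object@residualRms,
              object@nBeads))
})

setMethod("show", "IdealizedTrace", function(object) {
  cat(sprintf("IdealizedTrace: %d frames, %d step(s)%s\n",
              length(object@labels), nrow(object@steps),
              if (object@flagged) " [flagged single-level]" else ""))
})

setMethod("show", "ExponentialFit", function(object) {
  comp <- paste(sprintf("a=%.3f tau=%.4g %s", object@amplitudes, object@taus,
                        object@timeUnit), collapse = "; ")
  cat(sprintf("ExponentialFit (%d component%s): %s\n", object@nComponents,
              if (object@nComponents > 1L) "s" else "", comp))
  cat(sprintf("  n = %d dwells, RSS %.4g, BIC %.4g\n", object@nDwells,
              object@rss, object@bic))
})

setMethod("show", "KineticResult", function(object) {
  cat("KineticResult\n")
  cat(sprintf("  synchronous pairs: %d, non-synchronous: %d\n",
              object@nSynchronous, object@nNonSynchronous))
  cat(sprintf("  %% non-synchronous: %.1f (ratio to sync) / %.1f (of total)\n",
              object@percentNonSyncRatio, object@percentNonSyncTotal))
  cat(sprintf("  k_c = %.3g min^-1, k_o = %.3g min^-1\n", object@kC, object@kO))
})
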