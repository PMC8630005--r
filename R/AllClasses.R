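#' @import methods
#' @importFrom stats rexp rpois rnorm runif median mad quantile kmeans sd
#'   ks.test optim coef resid setNames complete.cases rbinom
#' @importFrom utils head tail read.csv write.csv
NULL

.modes <- c("atp_cycling", "ampnp_onecolour", "apo")

#' Simulation settings for the coupled-clamp trace simulator
#'
#' Holds the generative parameters of the two-state (telegraph) clamp model:
#' a shared clamp coordinate switches between an open (fluorescent) and a
#' closed (PET-quenched) conformation with exponential sojourn times, driving
#' both colour channels in concert; a minority of closures are re-assigned as
#' channel-independent (non-synchronous) quench-only excursions. Rates are in
#' events per minute, durations in seconds.
#'
#' @slot nMolecules number of molecules to simulate.
#' @slot durationS trace duration in seconds (default 540 s, i.e. 9 min).
#' @slot frameIntervalS camera integration time per frame in seconds
#'   (0.3 s for two-colour acquisition, 1 s for one-colour).
#' @slot mode one of \code{"atp_cycling"} (reversible cycling, two channels),
#'   \code{"ampnp_onecolour"} (irreversible closure, single channel, DSPO
#'   fluorescence recovery after oxygen application) or \code{"apo"}
#'   (no coupled cycling; only rare uncoupled closures and bleaching).
#' @slot kClose rate of clamp closure, per minute.
#' @slot kOpen rate of clamp opening, per minute.
#' @slot pUncoupled probability that a closure event is channel-independent.
#' @slot syncJitterFrames maximum |frame offset| applied to the red channel
#'   for a coupled event (integer, default 0).
#' @slot kBleachGreen,kBleachRed irreversible photobleach rates per minute,
#'   active while the channel is fluorescent.
#' @slot o2ApplicationS time of oxygen application (ampnp mode), seconds.
#' @slot dspoMeanDelayS mean delay of DSPO fluorescence recovery after
#'   oxygen application, seconds.
#' @slot seed integer RNG seed; identical config + seed gives bit-identical
#'   output.
#' @export
setClass("SimulationConfig",
  representation(
    nMolecules = "integer", durationS = "numeric", frameIntervalS = "numeric",
    mode = "character", kClose = "numeric", kOpen = "numeric",
    pUncoupled = "numeric", syncJitterFrames = "integer",
    kBleachGreen = "numeric", kBleachRed = "numeric",
    o2ApplicationS = "numeric", dspoMeanDelayS = "numeric", seed = "integer"))

setValidity("SimulationConfig", function(object) {
  msg <- character()
  rates <- c(kClose = object@kClose, kOpen = object@kOpen,
             kBleachGreen = object@kBleachGreen, kBleachRed = object@kBleachRed)
  if (any(!is.finite(rates)) || any(rates < 0))
    msg <- c(msg, "all rates must be finite and >= 0")
  if (!is.finite(object@pUncoupled) ||
      object@pUncoupled < 0 || object@pUncoupled > 1)
    msg <- c(msg, "pUncoupled must lie in [0, 1]")
  if (!is.finite(object@frameIntervalS) || object@frameIntervalS <= 0)
    msg <- c(msg, "frameIntervalS must be > 0")
  if (!is.finite(object@durationS) || object@durationS < object@frameIntervalS)
    msg <- c(msg, "durationS must be >= frameIntervalS")
  if (!object@mode %in% .modes)
    msg <- c(msg, paste("mode must be one of:", paste(.modes, collapse = ", ")))
  if (object@nMolecules < 0L) msg <- c(msg, "nMolecules must be >= 0")
  if (object@syncJitterFrames < 0L) msg <- c(msg, "syncJitterFrames must be >= 0")
  if (length(msg)) msg else TRUE
})

#' @param nMolecules,durationS,frameIntervalS,mode,kClose,kOpen,pUncoupled
#'   see slot documentation.
#' @param syncJitterFrames,kBleachGreen,kBleachRed,o2ApplicationS see slots.
#' @param dspoMeanDelayS,seed see slot documentation.
#' @return A validated \code{SimulationConfig}.
#' @examples
#' cfg <- SimulationConfig(nMolecules = 10, seed = 1L)
#' @rdname SimulationConfig-class
#' @export
SimulationConfig <- function(nMolecules = 50L, durationS = 540,
    frameIntervalS = 0.3, mode = "atp_cycling", kClose = 1.0, kOpen = 5.0,
    pUncoupled = 0.12, syncJitterFrames = 0L, kBleachGreen = 0.05,
    kBleachRed = 0.05, o2ApplicationS = 600, dspoMeanDelayS = 30,
    seed = 1L) {
  new("SimulationConfig", nMolecules = as.integer(nMolecules),
      durationS = durationS, frameIntervalS = frameIntervalS, mode = mode,
      kClose = kClose, kOpen = kOpen, pUncoupled = pUncoupled,
      syncJitterFrames = as.integer(syncJitterFrames),
      kBleachGreen = kBleachGreen, kBleachRed = kBleachRed,
      o2ApplicationS = o2ApplicationS, dspoMeanDelayS = dspoMeanDelayS,
      seed = as.integer(seed))
}

#' Camera and optics model for synthetic TIRF frames
#'
#' Diffraction-limited spots are rendered as 2-D Gaussians on a uniform
#' background; pixel counts follow a Poisson (shot) model scaled by the
#' camera gain plus Gaussian read noise. Defaults mimic a 512 x 512 px EMCCD
#' field at 130 nm/px.
#'
#' @slot imageSize integer length-2, frame size in pixels (rows, cols).
#' @slot pixelSizeNm pixel pitch in nm (informational; all distances are in
#'   pixel units).
#' @slot psfSigmaPx Gaussian PSF standard deviation in pixels.
#' @slot photonsPerFrameOpen expected integrated signal photons per frame for
#'   an open-state (fluorescent) molecule.
#' @slot backgroundPhotons expected background photons per pixel per frame.
#' @slot readNoise rms read noise in counts.
#' @slot gain camera gain, counts per photon.
#' @export
setClass("CameraModel",
  representation(imageSize = "integer", pixelSizeNm = "numeric",
    psfSigmaPx = "numeric", photonsPerFrameOpen = "numeric",
    backgroundPhotons = "numeric", readNoise = "numeric", gain = "numeric"))

setValidity("CameraModel", function(object) {
  msg <- character()
  if (length(object@imageSize) != 2L || any(object@imageSize < 8L))
    msg <- c(msg, "imageSize must be two integers >= 8")
  if (object@psfSigmaPx <= 0) msg <- c(msg, "psfSigmaPx must be > 0")
  if (object@photonsPerFrameOpen <= 0 || object@backgroundPhotons < 0 ||
      object@readNoise < 0 || object@gain <= 0)
    msg <- c(msg, "photon levels must be > 0, noise terms >= 0, gain > 0")
  # detectability: open-state peak must rise >= 3 read-noise sigmas above bg
  peak <- object@gain * object@photonsPerFrameOpen /
    (2 * pi * object@psfSigmaPx^2)
  if (object@readNoise > 0 && peak < 3 * object@readNoise)
    msg <- c(msg, "open-state spot peak is below 3x read noise (undetectable)")
  if (length(msg)) msg else TRUE
})

#' @param imageSize,pixelSizeNm,psfSigmaPx,photonsPerFrameOpen see slots.
#' @param backgroundPhotons,readNoise,gain see slot documentation.
#' @return A validated \code{CameraModel}.
#' @rdname CameraModel-class
#' @export
CameraModel <- function(imageSize = c(512L, 512L), pixelSizeNm = 130,
    psfSigmaPx = 1.3, photonsPerFrameOpen = 400, backgroundPhotons = 20,
    readNoise = 2, gain = 1) {
  new("CameraModel", imageSize = as.integer(imageSize),
      pixelSizeNm = pixelSizeNm, psfSigmaPx = psfSigmaPx,
      photonsPerFrameOpen = photonsPerFrameOpen,
      backgroundPhotons = backgroundPhotons, readNoise = readNoise,
      gain = gain)
}

#' Step-detection settings
#'
#' Parameters of the trace idealizer: Gaussian pre-smoothing followed by the
#' multiscale product of first-derivative-of-Gaussian detail signals at
#' dyadic scales; candidate steps are thresholded against a robust
#' (MAD-based) noise floor of the product signal and filtered by a minimum
#' relative amplitude.
#'
#' @slot smoothSigmaFrames Gaussian pre-smoothing sigma, frames (default 1.5).
#' @slot scales strictly increasing dyadic scales, frames (default 1, 2, 4).
#' @slot thresholdC multiplier on the MAD-calibrated product noise floor.
#' @slot minSeparationFrames minimum separation between reported steps.
#' @slot minRelativeAmplitude minimum step amplitude as a fraction of the
#'   trace 5-95 percentile dynamic range.
#' @export
setClass("StepDetectionConfig",
  representation(smoothSigmaFrames = "numeric", scales = "numeric",
    thresholdC = "numeric", minSeparationFrames = "integer",
    minRelativeAmplitude = "numeric"))

setValidity("StepDetectionConfig", function(object) {
  msg <- character()
  if (object@smoothSigmaFrames <= 0) msg <- c(msg, "smoothSigmaFrames must be > 0")
  if (length(object@scales) < 1L || any(object@scales <= 0) ||
      is.unsorted(object@scales, strictly = TRUE))
    msg <- c(msg, "scales must be positive and strictly increasing")
  if (object@thresholdC <= 0) msg <- c(msg, "thresholdC must be > 0")
  if (object@minSeparationFrames < 1L) msg <- c(msg, "minSeparationFrames must be >= 1")
  if (object@minRelativeAmplitude < 0 || object@minRelativeAmplitude >= 1)
    msg <- c(msg, "minRelativeAmplitude must lie in [0, 1)")
  if (length(msg)) msg else TRUE
})

#' @param smoothSigmaFrames,scales,thresholdC see slot documentation.
#' @param minSeparationFrames,minRelativeAmplitude see slot documentation.
#' @return A validated \code{StepDetectionConfig}.
#' @rdname StepDetectionConfig-class
#' @export
StepDetectionConfig <- function(smoothSigmaFrames = 1.5, scales = c(1, 2, 4),
    thresholdC = 3.0, minSeparationFrames = 3L, minRelativeAmplitude = 0.25) {
  new("StepDetectionConfig", smoothSigmaFrames = smoothSigmaFrames,
      scales = as.numeric(scales), thresholdC = thresholdC,
      minSeparationFrames = as.integer(minSeparationFrames),
      minRelativeAmplitude = minRelativeAmplitude)
}

#' Kinetic-analysis settings
#'
#' @slot syncWindowFrames two-channel steps of the same direction within this
#'   many frames are classed synchronous (default 6, i.e. 1.8 s at 0.3
#'   s/frame).
#' @slot frameIntervalS frame interval in seconds, used to convert frame
#'   counts to dwell times.
#' @slot bleachTailPolicy \code{"censor"} (default) excludes dwells ending in
#'   a bleach candidate; \code{"drop_trace"} drops the whole trace.
#' @slot modelSelection \code{"bic"}, \code{"fixed_mono"} or \code{"fixed_bi"}.
#' @slot o2ApplicationS oxygen application time for one-colour mode, seconds
#'   (NA when not applicable).
#' @export
setClass("AnalysisConfig",
  representation(syncWindowFrames = "integer", frameIntervalS = "numeric",
    bleachTailPolicy = "character", modelSelection = "character",
    o2ApplicationS = "numeric"))

setValidity("AnalysisConfig", function(object) {
  msg <- character()
  if (object@syncWindowFrames < 0L) msg <- c(msg, "syncWindowFrames must be >= 0")
  if (object@frameIntervalS <= 0) msg <- c(msg, "frameIntervalS must be > 0")
  if (!object@bleachTailPolicy %in% c("censor", "drop_trace"))
    msg <- c(msg, "bleachTailPolicy must be 'censor' or 'drop_trace'")
  if (!object@modelSelection %in% c("bic", "fixed_mono", "fixed_bi"))
    msg <- c(msg, "modelSelection must be 'bic', 'fixed_mono' or 'fixed_bi'")
  if (length(msg)) msg else TRUE
})

#' @param syncWindowFrames,frameIntervalS,bleachTailPolicy see slots.
#' @param modelSelection,o2ApplicationS see slot documentation.
#' @return A validated \code{AnalysisConfig}.
#' @rdname AnalysisConfig-class
#' @export
AnalysisConfig <- function(syncWindowFrames = 6L, frameIntervalS = 0.3,
    bleachTailPolicy = "censor", modelSelection = "bic",
    o2ApplicationS = NA_real_) {
  new("AnalysisConfig", syncWindowFrames = as.integer(syncWindowFrames),
      frameIntervalS = frameIntervalS, bleachTailPolicy = bleachTailPolicy,
      modelSelection = modelSelection, o2ApplicationS = o2ApplicationS)
}

#' Ground-truth clamp trajectories
#'
#' Hidden per-molecule, per-channel state sequences on the camera frame grid
#' (1 = open/fluorescent, 2 = closed/quenched, 3 = bleached) together with
#' the generative event log.
#'
#' @slot states integer array [molecule, frame, channel].
#' @slot events data.frame with columns \code{molecule_id}, \code{channel},
#'   \code{frame} (0-based), \code{kind} (coupled_close, coupled_open,
#'   uncoupled_close, uncoupled_open, bleach, dspo_recovery).
#' @slot config the \code{SimulationConfig} that generated the object.
#' @slot channelNames character vector of channel names.
#' @export
setClass("ClampTrajectorySet",
  representation(states = "array", events = "data.frame",
    config = "SimulationConfig", channelNames = "character"))

setValidity("ClampTrajectorySet", function(object) {
  msg <- character()
  d <- dim(object@states)
  if (length(d) != 3L) msg <- c(msg, "states must be a 3-d array")
  else if (d[3] != length(object@channelNames))
    msg <- c(msg, "third dimension must match channelNames")
  if (!all(object@states %in% c(1L, 2L, 3L)))
    msg <- c(msg, "state codes must be 1 (open), 2 (closed) or 3 (bleached)")
  need <- c("molecule_id", "channel", "frame", "kind")
  if (!all(need %in% names(object@events)))
    msg <- c(msg, "event log must have molecule_id, channel, frame, kind")
  if (length(msg)) msg else TRUE
})

#' Per-molecule two-channel intensity time traces
#'
#' A thin extension of \linkS4class{SummarizedExperiment}: one assay matrix
#' (molecules x frames) per colour channel, frame times in \code{colData},
#' acquisition metadata and (for simulated data) the ground-truth
#' \linkS4class{ClampTrajectorySet} in \code{metadata}.
#'
#' @export
setClass("TraceSet", contains = "SummarizedExperiment")

setValidity("TraceSet", function(object) {
  msg <- character()
  if (length(SummarizedExperiment::assayNames(object)) < 1L)
    msg <- c(msg, "at least one channel assay is required")
  md <- S4Vectors::metadata(object)
  if (is.null(md$frameIntervalS) || md$frameIntervalS <= 0)
    msg <- c(msg, "metadata$frameIntervalS must be a positive number")
  if (length(msg)) msg else TRUE
})

#' Affine mapping between detection channels
#'
#' Maps channel-2 (red) coordinates into the channel-1 (green) frame:
#' \code{x1 = linear \%*\% x2 + offset}.
#'
#' @slot linear invertible 2 x 2 matrix.
#' @slot offset numeric length-2 translation, pixels.
#' @slot residualRms root-mean-square fit residual over the beads, pixels.
#' @slot nBeads number of matched bead pairs used for the fit.
#' @export
setClass("ChannelTransform",
  representation(linear = "matrix", offset = "numeric",
    residualRms = "numeric", nBeads = "integer"))

setValidity("ChannelTransform", function(object) {
  msg <- character()
  if (!all(dim(object@linear) == c(2L, 2L)) ||
      abs(det(object@linear)) < 1e-12)
    msg <- c(msg, "linear part must be an invertible 2 x 2 matrix")
  if (length(object@offset) != 2L) msg <- c(msg, "offset must have length 2")
  if (object@residualRms < 0) msg <- c(msg, "residualRms must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Idealized two-level trace
#'
#' @slot labels integer per-frame level label: 1 fluorescent, 2 quenched.
#' @slot steps data.frame with columns \code{frame} (0-based), \code{direction}
#'   ("down" = quench, "up" = recovery), \code{amplitude}, \code{product}.
#' @slot levelMeans numeric length-2: fitted fluorescent and quenched level
#'   means.
#' @slot flagged TRUE when the two levels were statistically
#'   indistinguishable and the trace was labeled single-level.
#' @export
setClass("IdealizedTrace",
  representation(labels = "integer", steps = "data.frame",
    levelMeans = "numeric", flagged = "logical"))

#' Mono-/bi-exponential fit to a cumulative dwell-time curve
#'
#' @slot amplitudes component amplitudes, normalized to sum to 1.
#' @slot taus component time constants, ascending, in \code{timeUnit}.
#' @slot nComponents 1 or 2.
#' @slot rss residual sum of squares of the cumulative-curve fit.
#' @slot bic Bayesian information criterion of the selected model.
#' @slot nDwells number of dwells fitted.
#' @slot timeUnit "s" or "min".
#' @slot converged logical.
#' @export
setClass("ExponentialFit",
  representation(amplitudes = "numeric", taus = "numeric",
    nComponents = "integer", rss = "numeric", bic = "numeric",
    nDwells = "integer", timeUnit = "character", converged = "logical"))

setValidity("ExponentialFit", function(object) {
  msg <- character()
  if (any(object@amplitudes < -1e-9)) msg <- c(msg, "amplitudes must be >= 0")
  if (abs(sum(object@amplitudes) - 1) > 1e-6)
    msg <- c(msg, "amplitudes must sum to 1")
  if (any(object@taus <= 0)) msg <- c(msg, "time constants must be > 0")
  if (is.unsorted(object@taus)) msg <- c(msg, "taus must be ascending")
  if (!object@timeUnit %in% c("s", "min")) msg <- c(msg, "timeUnit must be 's' or 'min'")
  if (length(msg)) msg else TRUE
})

#' Kinetic summary of a two-colour data set
#'
#' @slot nSynchronous number of synchronous transition pairs.
#' @slot nNonSynchronous number of unmatched (non-synchronous) transitions.
#' @slot percentNonSyncRatio 100 * N_ns / N_s (headline convention).
#' @slot percentNonSyncTotal 100 * N_ns / (N_s + N_ns).
#' @slot perChannel named list; per channel a list with elements
#'   \code{openFit}, \code{closedFit} (\linkS4class{ExponentialFit} or NULL),
#'   \code{kC}, \code{kO} (per-minute rates).
#' @slot kC,kO headline closure/opening rate constants (channel means),
#'   per minute.
#' @export
setClass("KineticResult",
  representation(nSynchronous = "integer", nNonSynchronous = "integer",
    percentNonSyncRatio = "numeric", percentNonSyncTotal = "numeric",
    perChannel = "list", kC = "numeric", kO = "numeric"))
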