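# Coupled-clamp (telegraph) trajectory simulator.
#
# A single hidden clamp coordinate alternates between open and closed with
# exponential sojourn times (rates kClose, kOpen, per minute). A coupled
# closure quenches both reporters; with probability pUncoupled a closure is
# re-assigned as a channel-independent quench-only excursion of one randomly
# chosen reporter, which reopens after an Exp(1/kOpen) sojourn of its own.
# Photobleaching is irreversible. Everything is generated in continuous time
# and then sampled on the camera frame grid, so sub-frame sojourns alias
# away exactly as they would in a recorded movie.

.rexp1 <- function(rate) if (rate <= 0) Inf else stats::rexp(1L, rate)

# run expr under a private RNG stream, restoring the caller's stream
.withSeed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (has) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  force(expr)
}

# continuous-time description of one molecule: per-channel quench intervals
# (start, end, tag) and a bleach time (Inf = never)
.simMoleculeCycling <- function(cfg, nChannels, allUncoupled = FALSE) {
  kcS <- cfg@kClose / 60; koS <- cfg@kOpen / 60
  dur <- cfg@durationS; dt <- cfg@frameIntervalS; j <- cfg@syncJitterFrames
  iv <- vector("list", nChannels)   # each: list of c(start, end, tagCode)
  t <- 0
  excursionEnd <- 0                 # end of the latest uncoupled excursion
  repeat {
    tClose <- t + .rexp1(kcS)
    if (!is.finite(tClose) || tClose >= dur) break
    if (tClose < excursionEnd) {
      # an uncoupled excursion is still running in one channel: a coupled
      # event now would be invisible there, so restart the (memoryless)
      # closure clock when the excursion ends
      t <- excursionEnd
      next
    }
    uncoupled <- allUncoupled || (cfg@pUncoupled > 0 &&
                                  stats::runif(1L) < cfg@pUncoupled)
    d <- .rexp1(koS)
    if (uncoupled) {
      ch <- if (nChannels == 1L) 1L else sample.int(nChannels, 1L)
      iv[[ch]] <- c(iv[[ch]], list(c(tClose, tClose + d, 2)))
      excursionEnd <- max(excursionEnd, tClose + d)
      t <- tClose                       # clamp itself stays open
    } else {
      jit <- if (j > 0L) sample.int(2L * j + 1L, 2L) - j - 1L else c(0L, 0L)
      iv[[1L]] <- c(iv[[1L]], list(c(tClose, tClose + d, 1)))
      if (nChannels > 1L)
        iv[[2L]] <- c(iv[[2L]], list(c(tClose + jit[1L] * dt,
                                       tClose + d + jit[2L] * dt, 1)))
      t <- tClose + d
    }
  }
  bleachRates <- c(cfg@kBleachGreen, cfg@kBleachRed)[seq_len(nChannels)] / 60
  # photobleaching consumes fluorescent (excited-state) time only: a
  # PET-quenched dye is dark and protected, so every bleach is a visible
  # terminal intensity loss
  bleach <- vapply(seq_len(nChannels), function(ch) {
    budget <- .rexp1(bleachRates[ch])
    if (!is.finite(budget)) return(Inf)
    .fluorescentTimeToWall(iv[[ch]], budget, dur)
  }, numeric(1L))
  list(intervals = iv, bleach = bleach)
}

# map a fluorescent-time budget to wall-clock time given quenched intervals
.fluorescentTimeToWall <- function(iv, budget, dur) {
  if (!length(iv)) return(budget)
  m <- do.call(rbind, iv)
  m <- m[order(m[, 1L]), , drop = FALSE]
  # merge overlapping quenched intervals
  merged <- list(); cur <- m[1L, 1:2]
  for (k in seq_len(nrow(m))[-1L]) {
    if (m[k, 1L] <= cur[2L]) cur[2L] <- max(cur[2L], m[k, 2L])
    else { merged[[length(merged) + 1L]] <- cur; cur <- m[k, 1:2] }
  }
  merged[[length(merged) + 1L]] <- cur
  t <- 0
  for (seg in merged) {
    gap <- max(0, seg[1L] - t)
    if (budget <= gap) return(t + budget)
    budget <- budget - gap
    t <- max(t, seg[2L])
  }
  t + budget
}

# one-colour AMP-PNP molecule: irreversible closure; recovery by DSPO after
# oxygen application; bleaching competes only while the dye is fluorescent
.simMoleculeAmpnp <- function(cfg) {
  kcS <- cfg@kClose / 60; kbS <- cfg@kBleachGreen / 60
  tClose <- .rexp1(kcS)
  tb <- .rexp1(kbS)
  iv <- list()
  if (tb < tClose) {
    bleach <- tb                              # bleached while fluorescent
  } else if (tClose < cfg@o2ApplicationS) {
    tRec <- cfg@o2ApplicationS + .rexp1(1 / cfg@dspoMeanDelayS)
    iv <- list(c(tClose, tRec, 3))            # tag 3 = ampnp/DSPO cycle
    tb2 <- tRec + .rexp1(kbS)                 # bleaching resumes after recovery
    bleach <- tb2
  } else {
    bleach <- tClose + .rexp1(kbS)            # O2-rich: no stable PET quench
  }
  list(intervals = list(iv), bleach = bleach)
}

.tagClose <- c("coupled_close", "uncoupled_close", "coupled_close")
.tagOpen  <- c("coupled_open", "uncoupled_open", "dspo_recovery")

# discretize one channel of one molecule to the frame grid and emit events
.discretizeChannel <- function(iv, bleach, nFrames, dt, moleculeId, channel) {
  tf <- (seq_len(nFrames) - 1L) * dt
  quenched <- rep(FALSE, nFrames)
  if (length(iv)) {
    m <- do.call(rbind, iv)
    for (k in seq_len(nrow(m)))
      quenched <- quenched | (tf >= m[k, 1L] & tf < m[k, 2L])
  }
  state <- ifelse(quenched, 2L, 1L)
  state[tf >= bleach] <- 3L
  ev <- NULL
  chg <- which(diff(state) != 0L) + 1L        # 1-based frame index of change
  if (length(chg)) {
    kinds <- character(length(chg))
    for (i in seq_along(chg)) {
      f <- chg[i]; s <- state[f]
      if (s == 3L) { kinds[i] <- "bleach"; next }
      tNow <- tf[f]; tPrev <- tf[f - 1L]
      m <- if (length(iv)) do.call(rbind, iv) else matrix(0, 0L, 3L)
      if (s == 2L) {                          # became quenched
        cov <- which(m[, 1L] <= tNow & m[, 2L] > tNow)
        tag <- if (length(cov)) m[cov[which.max(m[cov, 1L])], 3L] else 1
        kinds[i] <- .tagClose[tag]
      } else {                                # became fluorescent
        cov <- which(m[, 1L] <= tPrev & m[, 2L] > tPrev)
        tag <- if (length(cov)) m[cov[which.max(m[cov, 2L])], 3L] else 1
        kinds[i] <- .tagOpen[tag]
      }
    }
    ev <- data.frame(molecule_id = moleculeId, channel = channel,
                     frame = chg - 1L, kind = kinds,
                     stringsAsFactors = FALSE)
  }
  list(state = state, events = ev)
}

#' Simulate ground-truth clamp trajectories
#'
#' Draws continuous-time state trajectories of the coupled two-state clamp
#' model described in \linkS4class{SimulationConfig}, samples them on the
#' camera frame grid, and returns per-channel state sequences together with
#' the generative event log.
#'
#' @param config a \linkS4class{SimulationConfig}.
#' @return A \linkS4class{ClampTrajectorySet}.
#' @examples
#' traj <- simulateClampTrajectories(SimulationConfig(nMolecules = 5,
#'   seed = 7L))
#' head(eventLog(traj))
#' @export
simulateClampTrajectories <- function(config) {
  validObject(config)
  chans <- if (config@mode == "ampnp_onecolour") "green" else c("green", "red")
  nCh <- length(chans)
  nFrames <- max(1L, floor(config@durationS / config@frameIntervalS))
  states <- array(1L, dim = c(config@nMolecules, nFrames, nCh))
  evs <- vector("list", config@nMolecules)
  .withSeed(config@seed, {
    for (m in seq_len(config@nMolecules)) {
      sim <- switch(config@mode,
        atp_cycling = .simMoleculeCycling(config, nCh),
        apo = .simMoleculeCycling(config, nCh, allUncoupled = TRUE),
        ampnp_onecolour = .simMoleculeAmpnp(config))
      mev <- vector("list", nCh)
      for (ch in seq_len(nCh)) {
        dc <- .discretizeChannel(sim$intervals[[ch]], sim$bleach[ch], nFrames,
                                 config@frameIntervalS, m, chans[ch])
        states[m, , ch] <- dc$state
        mev[[ch]] <- dc$events
      }
      evs[[m]] <- do.call(rbind, mev)
    }
  })
  events <- do.call(rbind, evs)
  if (is.null(events))
    events <- data.frame(molecule_id = integer(), channel = character(),
                         frame = integer(), kind = character(),
                         stringsAsFactors = FALSE)
  new("ClampTrajectorySet", states = states, events = events,
      config = config, channelNames = chans)
}

#' Render intensity time traces from trajectories
#'
#' Trace-level shortcut that bypasses image rendering: an open (fluorescent)
#' state maps to a high level, closed/bleached states to the background
#' level. Shot noise (Poisson, variance proportional to the photon level)
#' and additive Gaussian read noise follow the camera model; explicit
#' \code{signalLevel}/\code{backgroundLevel}/\code{readNoiseSd} override the
#' camera-derived peak-pixel levels, which is convenient for controlled-SNR
#' experiments.
#'
#' @param trajectories a \linkS4class{ClampTrajectorySet}.
#' @param camera a \linkS4class{CameraModel}; the open-state trace level is
#'   the PSF peak-pixel photon count above background.
#' @param seed RNG seed for the noise realization.
#' @param shotNoise logical; apply Poisson noise to the photon level.
#' @param signalLevel,backgroundLevel optional explicit levels (photons).
#' @param readNoiseSd optional explicit Gaussian noise sd (counts).
#' @return A \linkS4class{TraceSet} carrying the trajectories as ground
#'   truth.
#' @examples
#' traj <- simulateClampTrajectories(SimulationConfig(nMolecules = 3,
#'   seed = 2L))
#' ts <- renderTraces(traj, seed = 2L)
#' dim(traceMatrix(ts, "green"))
#' @export
renderTraces <- function(trajectories, camera = CameraModel(), seed = 1L,
                         shotNoise = TRUE, signalLevel = NULL,
                         backgroundLevel = NULL, readNoiseSd = NULL) {
  stopifnot(is(trajectories, "ClampTrajectorySet"))
  if (is.null(signalLevel))
    signalLevel <- camera@photonsPerFrameOpen / (2 * pi * camera@psfSigmaPx^2)
  if (is.null(backgroundLevel)) backgroundLevel <- camera@backgroundPhotons
  if (is.null(readNoiseSd)) readNoiseSd <- camera@readNoise
  gain <- camera@gain
  d <- dim(trajectories@states)
  assays <- list()
  .withSeed(seed, {
    for (ch in seq_len(d[3])) {
      s <- trajectories@states[, , ch]
      dim(s) <- d[1:2]
      lambda <- ifelse(s == 1L, signalLevel + backgroundLevel, backgroundLevel)
      counts <- if (shotNoise) stats::rpois(length(lambda), lambda) else lambda
      vals <- gain * counts +
        (if (readNoiseSd > 0) stats::rnorm(length(lambda), 0, readNoiseSd) else 0)
      m <- matrix(vals, nrow = d[1], ncol = d[2])
      rownames(m) <- paste0("mol", seq_len(d[1]))
      assays[[trajectories@channelNames[ch]]] <- m
    }
  })
  dt <- trajectories@config@frameIntervalS
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = assays,
    rowData = S4Vectors::DataFrame(molecule_id = seq_len(d[1])),
    colData = S4Vectors::DataFrame(frame = seq_len(d[2]) - 1L,
                                   time_s = (seq_len(d[2]) - 1L) * dt),
    metadata = list(frameIntervalS = dt, mode = trajectories@config@mode,
                    groundTruth = trajectories))
  new("TraceSet", se)
}

#' Construct a TraceSet from raw intensity matrices
#'
#' @param channels named list of molecules-by-frames matrices (e.g.
#'   \code{list(green = ..., red = ...)}).
#' @param frameIntervalS frame interval in seconds.
#' @param groundTruth optional \linkS4class{ClampTrajectorySet}.
#' @return A \linkS4class{TraceSet}.
#' @export
TraceSet <- function(channels, frameIntervalS, groundTruth = NULL) {
  stopifnot(length(channels) >= 1L, !is.null(names(channels)))
  nf <- ncol(channels[[1L]])
  nm <- nrow(channels[[1L]])
  channels <- lapply(channels, function(m) {
    rownames(m) <- paste0("mol", seq_len(nrow(m))); m
  })
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = channels,
    rowData = S4Vectors::DataFrame(molecule_id = seq_len(nm)),
    colData = S4Vectors::DataFrame(frame = seq_len(nf) - 1L,
                                   time_s = (seq_len(nf) - 1L) * frameIntervalS),
    metadata = list(frameIntervalS = frameIntervalS,
                    groundTruth = groundTruth))
  new("TraceSet", se)
}
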