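# Trace idealization: Gaussian smoothing followed by the multiscale product
# of first-derivative-of-Gaussian detail signals at dyadic scales. The
# product sharpens step localization (true steps respond coherently at all
# scales) while noise, which decorrelates across scales, is suppressed; with
# an odd number of scales the sign of the product at a step matches the step
# direction.

# dispatch-free median for tight loops
.fastMedian <- function(x) {
  n <- length(x)
  half <- (n + 1L) %/% 2L
  if (n %% 2L == 1L) sort(x, partial = half)[half]
  else {
    s <- sort(x, partial = c(half, half + 1L))
    (s[half] + s[half + 1L]) / 2
  }
}

.reflectPad <- function(x, k) {
  n <- length(x)
  k <- min(k, n)
  c(x[k:1], x, x[n:(n - k + 1L)])
}

.convSame <- function(x, kernel) {
  # kernel indexed j = -R..R; y[t] = sum_j kernel[j] * x[t + j]
  R <- (length(kernel) - 1L) %/% 2L
  xp <- .reflectPad(x, R)
  y <- stats::filter(xp, rev(kernel), method = "convolution", sides = 2L)
  as.numeric(y[(R + 1L):(R + length(x))])
}

#' Gaussian smoothing of an intensity trace
#'
#' Convolution with a unit-sum Gaussian kernel truncated at 4 sigma, with
#' reflective boundary handling.
#'
#' @param trace numeric vector of intensities.
#' @param sigmaFrames kernel standard deviation in frames (> 0).
#' @return smoothed numeric vector of the same length.
#' @examples
#' gaussianSmooth(rep(5, 20), 1.5)  # constant in, constant out
#' @export
gaussianSmooth <- function(trace, sigmaFrames) {
  stopifnot(sigmaFrames > 0)
  if (any(!is.finite(trace))) stop("trace contains non-finite samples")
  R <- ceiling(4 * sigmaFrames)
  kernel <- exp(-((-R:R)^2) / (2 * sigmaFrames^2))
  kernel <- kernel / sum(kernel)
  .convSame(trace, kernel)
}

.dogKernel <- function(scale) {
  R <- ceiling(4 * scale)
  j <- -R:R
  w <- j * exp(-j^2 / (2 * scale^2))
  w / sum(w[j > 0])      # unit response to a unit step
}

#' Multiscale-product step-detection signal
#'
#' For each scale the trace is convolved with a first-derivative-of-Gaussian
#' (edge-detector) kernel of that width; the detection signal is the
#' pointwise product of the detail signals across scales. With an odd number
#' of scales the sign of the product at a true step matches the step
#' direction (negative = down).
#'
#' @param trace numeric vector; must be longer than 8 x the largest scale.
#' @param scales strictly increasing positive scales in frames.
#' @return numeric detection signal, same length as \code{trace}.
#' @export
multiscaleProduct <- function(trace, scales = c(1, 2, 4)) {
  stopifnot(length(scales) >= 1L, all(scales > 0))
  minLen <- 8 * max(scales)
  if (length(trace) <= minLen)
    stop(sprintf("trace too short: need length > %g for scales up to %g",
                 minLen, max(scales)))
  prod <- rep(1, length(trace))
  for (s in scales) prod <- prod * .convSame(trace, .dogKernel(s))
  prod
}

# robust per-frame noise sigma of a trace (successive differences are
# insensitive to the steps themselves)
.traceNoiseSigma <- function(x) {
  d <- diff(x)
  stats::mad(d, center = 0) / sqrt(2)
}

# deterministic, length-weighted 2-means on segment medians
.twoLevelSplit <- function(segMedian, segLen) {
  lo <- min(segMedian); hi <- max(segMedian)
  if (hi == lo) return(list(lo = lo, hi = hi,
                            assign = rep(1L, length(segMedian))))
  for (it in 1:50) {
    mid <- (lo + hi) / 2
    isHi <- segMedian > mid
    if (!any(isHi) || all(isHi)) break
    hi2 <- sum(segMedian[isHi] * segLen[isHi]) / sum(segLen[isHi])
    lo2 <- sum(segMedian[!isHi] * segLen[!isHi]) / sum(segLen[!isHi])
    if (hi2 == hi && lo2 == lo) break
    hi <- hi2; lo <- lo2
  }
  list(lo = lo, hi = hi, assign = ifelse(segMedian > (lo + hi) / 2, 2L, 1L))
}

#' Idealize a trace into a two-level step sequence
#'
#' The trace is Gaussian-smoothed, the multiscale product computed, and
#' candidate steps taken as local extrema of the |product| above
#' \code{thresholdC} times the robust noise floor of the product signal
#' (1.4826 x its median absolute deviation). Candidates closer than
#' \code{minSeparationFrames} are pruned keeping the larger |product| (tie:
#' earlier frame); step amplitudes are the difference of level medians over
#' the flanking windows, and candidates below \code{minRelativeAmplitude} of
#' the trace 5-95 percentile range are dropped. Surviving steps define the
#' two-level (fluorescent/quenched) labeling. Traces whose two fitted levels
#' are statistically indistinguishable (closer than two noise sigma, the
#' separation a two-means split produces on a single noise population) are
#' labeled single-level and flagged.
#'
#' @param trace numeric intensity trace.
#' @param config a \linkS4class{StepDetectionConfig}.
#' @return an \linkS4class{IdealizedTrace}; step frames are 0-based.
#' @examples
#' x <- c(rep(100, 60), rep(10, 60), rep(100, 60))
#' detectSteps(x, StepDetectionConfig())
#' @export
detectSteps <- function(trace, config = StepDetectionConfig()) {
  validObject(config)
  if (any(!is.finite(trace))) stop("trace contains non-finite samples")
  n <- length(trace)
  maxScale <- max(config@scales)
  if (n <= 8 * maxScale)
    stop(sprintf("trace too short: need length > %g", 8 * maxScale))

  noFit <- function(flag) {
    lev <- mean(trace)
    new("IdealizedTrace", labels = rep(1L, n),
        steps = data.frame(frame = integer(0), direction = character(0),
                           amplitude = numeric(0), product = numeric(0)),
        levelMeans = c(lev, NA_real_), flagged = flag)
  }
  rng <- as.numeric(diff(stats::quantile(trace, c(0.05, 0.95), names = FALSE)))
  if (rng == 0) return(noFit(FALSE))     # constant trace: nothing to detect

  sm <- gaussianSmooth(trace, config@smoothSigmaFrames)
  p <- multiscaleProduct(sm, config@scales)
  absP <- abs(p)
  floorP <- stats::mad(p, center = 0)    # 1.4826 * MAD about zero
  if (floorP <= 0) floorP <- 1e-12 * max(absP, .Machine$double.xmin)
  thr <- config@thresholdC * floorP

  # signed local extrema of the product above threshold (minima of p are
  # down-step candidates, maxima up-step candidates: adjacent steps of
  # opposite direction keep distinct extrema), away from the boundary guard
  guard <- ceiling(maxScale)
  localExtrema <- function(v) {
    idx <- which(v > thr)
    idx <- idx[idx > guard & idx <= n - guard]
    idx[vapply(idx, function(i)
      v[i] >= v[i - 1L] && v[i] >= v[i + 1L], logical(1L))]
  }
  cand <- sort(unique(c(localExtrema(p), localExtrema(-p))))
  # collapse plateaus of equal |p| to their earliest frame
  if (length(cand) > 1L) {
    keepPl <- c(TRUE, !(diff(cand) == 1L &
                        absP[cand[-1L]] == absP[cand[-length(cand)]]))
    cand <- cand[keepPl]
  }
  if (!length(cand)) return(noFit(FALSE))

  # localize each candidate at the finest-scale detail extremum within
  # +/- 2 frames (the product is detected at coarse scales but localized
  # best at the finest one), then dedupe
  d1 <- .convSame(sm, .dogKernel(min(config@scales)))
  snapped <- vapply(cand, function(i) {
    win <- max(guard + 1L, i - 2L):min(n - guard, i + 2L)
    win[which.max(sign(p[i]) * d1[win])]
  }, integer(1L))
  strength <- absP[cand]                  # detection strength at the product
  candSign <- sign(p[cand])
  keep <- !duplicated(snapped)
  cand <- snapped[keep]; strength <- strength[keep]
  candSign <- candSign[keep]
  ord0 <- order(cand)
  cand <- cand[ord0]; strength <- strength[ord0]; candSign <- candSign[ord0]

  # an opposite-direction pair below the separation limit is a dwell too
  # short to resolve: its earlier edge is the transition time, so keep that
  # one deterministically (both colour channels then agree on it)
  if (length(cand) > 1L) {
    i <- 1L; del <- logical(length(cand))
    while (i < length(cand)) {
      if (!del[i] && cand[i + 1L] - cand[i] < config@minSeparationFrames &&
          candSign[i] != candSign[i + 1L]) {
        strength[i] <- max(strength[i], strength[i + 1L])
        del[i + 1L] <- TRUE
        i <- i + 2L
      } else i <- i + 1L
    }
    cand <- cand[!del]; strength <- strength[!del]
  }

  # min-separation pruning, larger |product| wins, ties to the earlier frame
  ord <- order(-strength, cand)
  kept <- integer(0)
  for (i in cand[ord])
    if (!length(kept) || min(abs(kept - i)) >= config@minSeparationFrames)
      kept <- c(kept, i)
  cand <- sort(kept)

  # iterative amplitude filtering: medians over flanking inter-step windows;
  # the weakest offending candidate is removed and only its neighbours
  # re-measured
  minAmp <- config@minRelativeAmplitude * rng
  maxWin <- 50L
  ampOf <- function(k, cand) {
    prevB <- if (k == 1L) 1L else cand[k - 1L]
    nextB <- if (k == length(cand)) n + 1L else cand[k + 1L]
    lo <- max(prevB, cand[k] - maxWin)
    hi <- min(nextB - 1L, cand[k] + maxWin - 1L)
    .fastMedian(trace[cand[k]:hi]) - .fastMedian(trace[lo:(cand[k] - 1L)])
  }
  amp <- vapply(seq_along(cand), ampOf, numeric(1L), cand = cand)
  repeat {
    drop <- which(abs(amp) < minAmp)
    if (!length(drop)) break
    j <- drop[which.min(abs(amp[drop]))]
    cand <- cand[-j]; amp <- amp[-j]
    if (!length(cand)) return(noFit(FALSE))
    for (k in unique(pmin(pmax(c(j - 1L, j), 1L), length(cand))))
      amp[k] <- ampOf(k, cand)
  }

  # two-level assignment from segment medians
  bounds <- c(1L, cand, n + 1L)
  nSeg <- length(cand) + 1L
  segMed <- segLen <- numeric(nSeg)
  for (k in seq_len(nSeg)) {
    seg <- trace[bounds[k]:(bounds[k + 1L] - 1L)]
    segMed[k] <- .fastMedian(seg); segLen[k] <- length(seg)
  }
  split <- .twoLevelSplit(segMed, segLen)
  sigma <- .traceNoiseSigma(trace)
  if ((split$hi - split$lo) < 2 * sigma) return(noFit(TRUE))  # 2-means on pure noise separates by ~1.6 sigma

  # two-level consistency: a short segment whose median is far from BOTH
  # fitted levels is not a PET transition (mid-level noise or FRET-like
  # artifact); drop its bounding steps and re-segment. Noise is assessed
  # per level because shot noise scales with the intensity level.
  levelSigma <- function(cand, assign) {
    bnds <- c(1L, cand, n + 1L)
    out <- c(sigma, sigma)
    for (lv in 1:2) {
      segs <- which(assign == lv)
      d <- unlist(lapply(segs, function(k) {
        s <- bnds[k]:(bnds[k + 1L] - 1L)
        if (length(s) > 1L) diff(trace[s]) else numeric(0)
      }))
      if (length(d) >= 8L) out[lv] <- stats::mad(d, center = 0) / sqrt(2)
    }
    out     # c(sigma of lo level [assign 1], sigma of hi level [assign 2])
  }
  if (sigma > 0) {
    repeat {
      nSeg <- length(cand) + 1L
      sigLv <- levelSigma(cand, split$assign)
      bad <- integer(0)
      for (k in seq_len(nSeg)) {
        if (segLen[k] > 8L || (k == 1L) || (k == nSeg)) next
        dists <- abs(segMed[k] - c(split$lo, split$hi))
        z <- dists[which.min(dists)] * sqrt(segLen[k]) /
          max(sigLv[which.min(dists)], 1e-12)
        if (z > 4) bad <- c(bad, k)
      }
      if (!length(bad)) break
      dropSteps <- integer(0)
      mid <- (split$lo + split$hi) / 2
      for (k in bad) {
        sameSide <- (segMed[k - 1L] > mid) == (segMed[k + 1L] > mid)
        if (sameSide) {
          # genuine brief excursion or a noise dip/spike? look for any short
          # run inside the segment that truly reaches the opposite level
          seg <- trace[bounds[k]:(bounds[k + 1L] - 1L)]
          otherIsLo <- segMed[k - 1L] > mid
          other <- if (otherIsLo) split$lo else split$hi
          sigOther <- max(sigLv[if (otherIsLo) 1L else 2L], 1e-12)
          zOpp <- if (length(seg) >= 2L)
            min(abs(vapply(seq_len(length(seg) - 1L), function(i)
              mean(seg[i:(i + 1L)]), numeric(1L)) - other)) * sqrt(2) /
              sigOther
          else abs(seg - other) / sigOther
          if (zOpp <= 3) next                 # reaches the other level: keep
          # noise dip/spike between equal levels: both bounding steps spurious
          dropSteps <- c(dropSteps, k - 1L, k)
        } else {
          # smeared true transition: keep the boundary on the dissimilar side
          closerLeft <- abs(segMed[k] - segMed[k - 1L]) <=
            abs(segMed[k] - segMed[k + 1L])
          dropSteps <- c(dropSteps, if (closerLeft) k - 1L else k)
        }
      }
      dropSteps <- sort(unique(dropSteps))
      dropSteps <- dropSteps[dropSteps >= 1L & dropSteps <= length(cand)]
      if (!length(dropSteps)) break
      cand <- cand[-dropSteps]
      if (!length(cand)) return(noFit(FALSE))
      bounds <- c(1L, cand, n + 1L)
      nSeg <- length(cand) + 1L
      segMed <- segLen <- numeric(nSeg)
      for (k in seq_len(nSeg)) {
        seg <- trace[bounds[k]:(bounds[k + 1L] - 1L)]
        segMed[k] <- .fastMedian(seg); segLen[k] <- length(seg)
      }
      split <- .twoLevelSplit(segMed, segLen)
      if ((split$hi - split$lo) < 2 * sigma) return(noFit(TRUE))  # 2-means on pure noise separates by ~1.6 sigma
    }
  }

  labels <- rep.int(ifelse(split$assign == 2L, 1L, 2L), segLen)  # 1=fluor
  # drop steps with no label change (e.g. noise doubles), if any
  change <- which(split$assign[-1L] != split$assign[-nSeg])
  if (length(change) < length(cand)) {
    cand <- cand[change]
    if (!length(cand)) return(noFit(TRUE))
    bounds <- c(1L, cand, n + 1L)
  }
  dirs <- ifelse(labels[cand] == 2L, "down", "up")
  amp <- numeric(length(cand))
  for (k in seq_along(cand)) {
    lo <- max(bounds[k], cand[k] - maxWin)
    hi <- min(bounds[k + 2L] - 1L, cand[k] + maxWin - 1L)
    amp[k] <- .fastMedian(trace[cand[k]:hi]) -
      .fastMedian(trace[lo:(cand[k] - 1L)])
  }
  fl <- labels == 1L
  levelMeans <- c(mean(trace[fl]), mean(trace[!fl]))
  new("IdealizedTrace", labels = labels,
      steps = data.frame(frame = cand - 1L, direction = dirs,
                         amplitude = amp, product = p[cand]),
      levelMeans = levelMeans, flagged = FALSE)
}

#' Idealize every trace of a TraceSet
#'
#' Runs \code{\link{detectSteps}} on each molecule and channel and collects
#' all detected steps.
#'
#' @param traces a \linkS4class{TraceSet}.
#' @param config a \linkS4class{StepDetectionConfig}.
#' @return list with \code{steps}, a data.frame (molecule_id, channel,
#'   frame, direction, amplitude), and \code{idealized}, a nested list of
#'   \linkS4class{IdealizedTrace} objects indexed by channel then molecule.
#' @export
idealizeTraces <- function(traces, config = StepDetectionConfig()) {
  chans <- channelNames(traces)
  idealized <- list()
  rows <- list()
  for (ch in chans) {
    m <- traceMatrix(traces, ch)
    idealized[[ch]] <- vector("list", nrow(m))
    for (i in seq_len(nrow(m))) {
      it <- detectSteps(as.numeric(m[i, ]), config)
      idealized[[ch]][[i]] <- it
      if (nrow(it@steps))
        rows[[length(rows) + 1L]] <-
          cbind(data.frame(molecule_id = i, channel = ch,
                           stringsAsFactors = FALSE),
                it@steps[, c("frame", "direction", "amplitude")])
    }
  }
  steps <- if (length(rows)) do.call(rbind, rows)
           else data.frame(molecule_id = integer(0), channel = character(0),
                           frame = integer(0), direction = character(0),
                           amplitude = numeric(0))
  rownames(steps) <- NULL
  flagged <- do.call(rbind, lapply(chans, function(ch)
    data.frame(molecule_id = seq_along(idealized[[ch]]), channel = ch,
               flagged = vapply(idealized[[ch]], slot, logical(1L),
                                "flagged"))))
  list(steps = steps, idealized = idealized, flagged = flagged,
       nFrames = ncol(traceMatrix(traces, chans[1L])))
}
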