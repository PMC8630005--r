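# Image-to-trace pipeline: spot localization, bead-based channel
# registration, co-localization and ROI read-out. All coordinates are
# 0-based pixel units, pixel centres at integers.

#' Detect diffraction-limited spots in a single frame
#'
#' Local maxima above a robust background threshold (median + threshold_k
#' robust sigmas, sigma = 1.4826 MAD) are refined to sub-pixel accuracy by a
#' background-subtracted intensity-weighted centroid in a window of
#' half-width ceil(3 psf sigma). Maxima closer than 4 PSF sigmas are merged,
#' keeping the brighter one.
#'
#' @param image numeric matrix (one frame).
#' @param thresholdK threshold in robust background sigmas (> 0).
#' @param psfSigmaPx PSF standard deviation, pixels.
#' @return data.frame with columns \code{x}, \code{y} (sub-pixel, 0-based),
#'   \code{intensity} (background-subtracted integral over the window) and
#'   \code{peak}.
#' @examples
#' img <- matrix(0, 32, 32); img[16, 16] <- 100
#' detectSpots(img, thresholdK = 5, psfSigmaPx = 1.3)
#' @export
detectSpots <- function(image, thresholdK = 5, psfSigmaPx = 1.3) {
  stopifnot(is.matrix(image), thresholdK > 0, psfSigmaPx > 0)
  if (any(!is.finite(image))) stop("image contains non-finite pixels")
  empty <- data.frame(x = numeric(0), y = numeric(0),
                      intensity = numeric(0), peak = numeric(0))
  if (!length(image)) return(empty)
  bg <- stats::median(image)
  sigma <- stats::mad(image)
  if (sigma == 0) sigma <- max(stats::sd(image), .Machine$double.eps)
  thr <- bg + thresholdK * sigma
  nr <- nrow(image); nc <- ncol(image)
  cand <- which(image > thr, arr.ind = TRUE)
  if (!nrow(cand)) return(empty)
  # strict local maxima over the 3 x 3 neighbourhood
  keep <- logical(nrow(cand))
  for (k in seq_len(nrow(cand))) {
    r <- cand[k, 1L]; c <- cand[k, 2L]
    nb <- image[max(1L, r - 1L):min(nr, r + 1L),
                max(1L, c - 1L):min(nc, c + 1L)]
    keep[k] <- image[r, c] == max(nb) && sum(nb == max(nb)) == 1L
  }
  cand <- cand[keep, , drop = FALSE]
  if (!nrow(cand)) return(empty)
  # merge maxima closer than 4 sigma, keeping the brighter one
  ord <- order(image[cand], decreasing = TRUE)
  cand <- cand[ord, , drop = FALSE]
  merged <- logical(nrow(cand))
  for (k in seq_len(nrow(cand))) {
    if (merged[k]) next
    if (k < nrow(cand)) {
      d <- sqrt((cand[(k + 1):nrow(cand), 1L] - cand[k, 1L])^2 +
                (cand[(k + 1):nrow(cand), 2L] - cand[k, 2L])^2)
      merged[(k + 1):nrow(cand)][d < 4 * psfSigmaPx] <- TRUE
    }
  }
  cand <- cand[!merged, , drop = FALSE]
  # centroid refinement
  hw <- ceiling(3 * psfSigmaPx)
  res <- lapply(seq_len(nrow(cand)), function(k) {
    r <- cand[k, 1L]; c <- cand[k, 2L]
    rows <- max(1L, r - hw):min(nr, r + hw)
    cols <- max(1L, c - hw):min(nc, c + hw)
    w <- pmax(image[rows, cols, drop = FALSE] - bg, 0)
    tot <- sum(w)
    if (tot <= 0) return(NULL)
    yc <- sum((rows - 1L) * rowSums(w)) / tot
    xc <- sum((cols - 1L) * colSums(w)) / tot
    data.frame(x = xc, y = yc, intensity = tot, peak = image[r, c])
  })
  out <- do.call(rbind, res)
  if (is.null(out)) empty else out[order(-out$intensity), , drop = FALSE]
}

#' Estimate the affine transform between detection channels from beads
#'
#' Bead centroids detected in the two channels are matched by mutual nearest
#' neighbour within \code{matchRadiusPx}; a least-squares affine transform
#' mapping channel-2 coordinates into the channel-1 frame is then fitted.
#'
#' @param beadsCh1,beadsCh2 data.frames (or matrices) with \code{x},
#'   \code{y} columns of bead positions in each channel.
#' @param matchRadiusPx coarse matching radius, pixels.
#' @return a \linkS4class{ChannelTransform}; warns when the residual RMS
#'   exceeds 1 px.
#' @examples
#' b <- data.frame(x = c(5, 20, 9, 30), y = c(7, 3, 25, 28))
#' registerChannels(b, transform(b, x = x + 3.2, y = y - 1.5))
#' @export
registerChannels <- function(beadsCh1, beadsCh2, matchRadiusPx = 10) {
  p1 <- as.matrix(as.data.frame(beadsCh1)[, c("x", "y")])
  p2 <- as.matrix(as.data.frame(beadsCh2)[, c("x", "y")])
  if (!nrow(p1) || !nrow(p2)) stop("empty bead coordinate set")
  dmat <- outer(p1[, 1L], p2[, 1L], "-")^2 + outer(p1[, 2L], p2[, 2L], "-")^2
  nn12 <- apply(dmat, 1L, which.min)
  nn21 <- apply(dmat, 2L, which.min)
  mutual <- which(nn21[nn12] == seq_len(nrow(p1)) &
                  sqrt(dmat[cbind(seq_len(nrow(p1)), nn12)]) <= matchRadiusPx)
  if (length(mutual) < 3L)
    stop("fewer than 3 matched bead pairs; cannot fit an affine transform")
  q1 <- p1[mutual, , drop = FALSE]
  q2 <- p2[nn12[mutual], , drop = FALSE]
  if (.collinear(q2[, 1L], q2[, 2L], tol = 1e-9))
    stop("matched beads are collinear; affine transform is degenerate")
  X <- cbind(q2, 1)                      # [x2 y2 1] %*% B = [x1 y1]
  B <- qr.solve(X, q1)
  linear <- unname(t(B[1:2, , drop = FALSE]))
  offset <- unname(as.numeric(B[3L, ]))
  fitted <- X %*% B
  rms <- sqrt(mean(rowSums((q1 - fitted)^2)))
  if (rms > 1)
    warning(sprintf("registration residual RMS %.2f px exceeds 1 px", rms))
  new("ChannelTransform", linear = linear, offset = offset,
      residualRms = rms, nBeads = length(mutual))
}

#' Apply a channel transform to coordinates
#'
#' @param transform a \linkS4class{ChannelTransform}.
#' @param xy matrix/data.frame of channel-2 (x, y) coordinates.
#' @return matrix of coordinates in the channel-1 frame.
#' @export
applyTransform <- function(transform, xy) {
  xy <- as.matrix(as.data.frame(xy)[, 1:2])
  out <- t(transform@linear %*% t(xy) + transform@offset)
  colnames(out) <- c("x", "y")
  out
}

#' Identity channel transform
#' @return a \linkS4class{ChannelTransform} with identity linear part.
#' @export
identityTransform <- function()
  new("ChannelTransform", linear = diag(2), offset = c(0, 0),
      residualRms = 0, nBeads = 0L)

#' Pair spots across channels by co-localization
#'
#' Channel-2 spots are mapped into the channel-1 frame through the
#' registration transform; spots are then matched one-to-one greedily by
#' ascending distance, keeping pairs within \code{tolPx}.
#'
#' @param spotsCh1,spotsCh2 data.frames with \code{x}, \code{y} columns
#'   (typically from \code{\link{detectSpots}} on a reference frame or a
#'   temporal maximum projection).
#' @param transform a \linkS4class{ChannelTransform}.
#' @param tolPx matching tolerance in pixels (default 2).
#' @return data.frame with columns \code{molecule_id}, \code{x1}, \code{y1},
#'   \code{x2}, \code{y2} (original channel-2 coordinates) and
#'   \code{distance_px} (in the registered frame).
#' @export
colocalize <- function(spotsCh1, spotsCh2, transform = identityTransform(),
                       tolPx = 2) {
  stopifnot(tolPx > 0)
  empty <- data.frame(molecule_id = integer(0), x1 = numeric(0),
                      y1 = numeric(0), x2 = numeric(0), y2 = numeric(0),
                      distance_px = numeric(0))
  s1 <- as.data.frame(spotsCh1); s2 <- as.data.frame(spotsCh2)
  if (!nrow(s1) || !nrow(s2)) return(empty)
  mapped <- applyTransform(transform, s2[, c("x", "y")])
  dmat <- sqrt(outer(s1$x, mapped[, 1L], "-")^2 +
               outer(s1$y, mapped[, 2L], "-")^2)
  idx <- which(dmat <= tolPx, arr.ind = TRUE)
  if (!nrow(idx)) return(empty)
  ord <- order(dmat[idx])
  used1 <- logical(nrow(s1)); used2 <- logical(nrow(s2))
  rows <- list()
  for (k in ord) {
    i <- idx[k, 1L]; j <- idx[k, 2L]
    if (used1[i] || used2[j]) next
    used1[i] <- TRUE; used2[j] <- TRUE
    rows[[length(rows) + 1L]] <-
      data.frame(molecule_id = length(rows) + 1L, x1 = s1$x[i], y1 = s1$y[i],
                 x2 = s2$x[j], y2 = s2$y[j], distance_px = dmat[i, j])
  }
  do.call(rbind, rows)
}

#' Maximum-intensity projection of the leading frames of a stack
#'
#' @param stack [row, col, frame] array.
#' @param nFrames number of leading frames to project (default 10).
#' @return matrix.
#' @export
maxProjection <- function(stack, nFrames = 10L) {
  nFrames <- min(nFrames, dim(stack)[3L])
  apply(stack[, , seq_len(nFrames), drop = FALSE], c(1L, 2L), max)
}

#' Read out per-molecule traces from a registered stack pair
#'
#' For every ROI and frame, the trace value is the maximum pixel intensity
#' in a square window of half-width \code{roiHalfWidthPx} around the ROI
#' centre of that channel (the conventional max-pixel read-out);
#' \code{method = "integrated"} sums the window instead.
#'
#' @param stacks named list of [row, col, frame] arrays (e.g. green, red).
#' @param rois data.frame from \code{\link{colocalize}} (columns
#'   \code{molecule_id}, \code{x1}, \code{y1}, \code{x2}, \code{y2}); for a
#'   single channel a data.frame with \code{molecule_id}, \code{x1},
#'   \code{y1}.
#' @param roiHalfWidthPx ROI half-width in pixels (default 3).
#' @param frameIntervalS frame interval in seconds.
#' @param method "max" (default) or "integrated".
#' @return a \linkS4class{TraceSet}.
#' @export
extractTraces <- function(stacks, rois, roiHalfWidthPx = 3L,
                          frameIntervalS = 0.3, method = c("max", "integrated")) {
  method <- match.arg(method)
  hw <- as.integer(roiHalfWidthPx)
  centres <- list(c("x1", "y1"), c("x2", "y2"))
  channels <- list()
  for (ci in seq_along(stacks)) {
    stack <- stacks[[ci]]
    nr <- dim(stack)[1L]; nc <- dim(stack)[2L]; nf <- dim(stack)[3L]
    cc <- centres[[min(ci, length(centres))]]
    if (!all(cc %in% names(rois))) cc <- c("x1", "y1")
    cx <- round(rois[[cc[1L]]]); cy <- round(rois[[cc[2L]]])
    bad <- rois$molecule_id[cx - hw < 0 | cx + hw > nc - 1L |
                            cy - hw < 0 | cy + hw > nr - 1L]
    if (length(bad))
      stop("ROI touches the image border for molecule_id: ",
           paste(bad, collapse = ", "))
    tr <- matrix(0, nrow(rois), nf)
    for (m in seq_len(nrow(rois))) {
      rows <- (cy[m] - hw):(cy[m] + hw) + 1L
      cols <- (cx[m] - hw):(cx[m] + hw) + 1L
      win <- stack[rows, cols, , drop = FALSE]
      tr[m, ] <- if (method == "max") apply(win, 3L, max)
                 else apply(win, 3L, sum)
    }
    channels[[names(stacks)[ci]]] <- tr
  }
  TraceSet(channels, frameIntervalS = frameIntervalS)
}
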