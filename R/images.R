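# Synthetic TIRF frame rendering. Coordinates are 0-based pixel units with
# pixel centres at integers: pixel [row i, col j] (1-based array indices) has
# centre (x, y) = (j - 1, i - 1).

.renderSpots <- function(nrow, ncol, x, y, photons, sigma) {
  img <- matrix(0, nrow, ncol)
  if (!length(x)) return(img)
  R <- ceiling(4 * sigma)
  norm <- 1 / (2 * pi * sigma^2)
  for (k in seq_along(x)) {
    if (photons[k] <= 0) next
    ci <- round(x[k]); ri <- round(y[k])
    cols <- max(0L, ci - R):min(ncol - 1L, ci + R)
    rows <- max(0L, ri - R):min(nrow - 1L, ri + R)
    gx <- exp(-((cols - x[k])^2) / (2 * sigma^2))
    gy <- exp(-((rows - y[k])^2) / (2 * sigma^2))
    img[rows + 1L, cols + 1L] <- img[rows + 1L, cols + 1L] +
      photons[k] * norm * outer(gy, gx)
  }
  img
}

.applyCameraNoise <- function(photons, camera) {
  counts <- stats::rpois(length(photons), pmax(photons, 0))
  vals <- camera@gain * counts
  if (camera@readNoise > 0)
    vals <- vals + stats::rnorm(length(photons), 0, camera@readNoise)
  matrix(vals, nrow = nrow(photons))
}

.collinear <- function(x, y, tol = 1e-6) {
  if (length(x) < 3L) return(TRUE)
  m <- cbind(x - mean(x), y - mean(y))
  sv <- svd(m, nu = 0, nv = 0)$d
  sv[2L] < tol * max(sv[1L], 1)
}

.placeSpots <- function(n, nrow, ncol, margin, minSep, maxAttempts = 1e4L) {
  xs <- numeric(0); ys <- numeric(0); attempts <- 0L
  while (length(xs) < n) {
    attempts <- attempts + 1L
    if (attempts > maxAttempts)
      stop(sprintf(
        "could not place %d spots with separation >= %.1f px in %d attempts",
        n, minSep, maxAttempts))
    x <- stats::runif(1L, margin, ncol - 1 - margin)
    y <- stats::runif(1L, margin, nrow - 1 - margin)
    if (!length(xs) || min(sqrt((xs - x)^2 + (ys - y)^2)) >= minSep) {
      xs <- c(xs, x); ys <- c(ys, y)
    }
  }
  cbind(x = xs, y = ys)
}

#' Affine channel misalignment
#'
#' Builds the forward warp applied to channel-2 spot positions in the
#' simulator: \code{x2 = linear \%*\% x1 + offset}. A rotation is taken
#' about \code{center}.
#'
#' @param shift numeric length-2 translation in pixels.
#' @param angleDeg rotation angle in degrees.
#' @param center rotation centre (pixels).
#' @param scale isotropic scale factor.
#' @return list with elements \code{linear} (2 x 2) and \code{offset}.
#' @examples
#' w <- affineMisalignment(shift = c(3.2, -1.5), angleDeg = 0.5,
#'                         center = c(32, 32))
#' @export
affineMisalignment <- function(shift = c(0, 0), angleDeg = 0,
                               center = c(0, 0), scale = 1) {
  th <- angleDeg * pi / 180
  A <- scale * matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2L, 2L)
  list(linear = A, offset = as.numeric(center - A %*% center + shift))
}

.warpPoints <- function(xy, warp) {
  if (is.null(warp)) return(xy)
  t(warp$linear %*% t(xy) + warp$offset)
}

#' Render a two-channel image stack from clamp trajectories
#'
#' Each molecule is a diffraction-limited 2-D Gaussian spot whose integrated
#' intensity tracks its hidden state (open = \code{photonsPerFrameOpen},
#' closed/bleached = 0) on a uniform background. Channel-2 positions are
#' optionally warped by an affine misalignment, for registration tests.
#' Poisson shot noise plus Gaussian read noise is applied per pixel.
#'
#' @param trajectories a \linkS4class{ClampTrajectorySet}.
#' @param camera a \linkS4class{CameraModel}.
#' @param misalignment \code{NULL} (aligned channels) or the result of
#'   \code{\link{affineMisalignment}}.
#' @param minSeparationPx minimum centre-to-centre spot distance (default
#'   4 PSF sigmas).
#' @param seed RNG seed for placement and noise.
#' @param noise logical; \code{FALSE} renders noiseless expectation images.
#' @return list with \code{stacks} (named list of [row, col, frame] arrays),
#'   \code{positions} (data.frame molecule_id, x1, y1, x2, y2) and
#'   \code{camera}.
#' @export
renderImageStack <- function(trajectories, camera = CameraModel(),
                             misalignment = NULL,
                             minSeparationPx = 4 * camera@psfSigmaPx,
                             seed = 1L, noise = TRUE) {
  stopifnot(is(trajectories, "ClampTrajectorySet"))
  d <- dim(trajectories@states)
  nr <- camera@imageSize[1L]; nc <- camera@imageSize[2L]
  margin <- ceiling(4 * camera@psfSigmaPx) + 4
  out <- .withSeed(seed, {
    pos1 <- if (d[1] > 0)
      .placeSpots(d[1], nr, nc, margin, minSeparationPx)
    else cbind(x = numeric(0), y = numeric(0))
    pos2 <- .warpPoints(pos1, misalignment)
    stacks <- list()
    for (ch in seq_len(d[3])) {
      pos <- if (ch == 1L) pos1 else pos2
      arr <- array(0, dim = c(nr, nc, d[2]))
      for (f in seq_len(d[2])) {
        st <- trajectories@states[, f, ch]
        phot <- ifelse(st == 1L, camera@photonsPerFrameOpen, 0)
        img <- camera@backgroundPhotons +
          .renderSpots(nr, nc, pos[, 1L], pos[, 2L], phot, camera@psfSigmaPx)
        arr[, , f] <- if (noise) .applyCameraNoise(img, camera)
                      else camera@gain * img
      }
      stacks[[trajectories@channelNames[ch]]] <- arr
    }
    list(stacks = stacks,
         positions = data.frame(molecule_id = seq_len(d[1]),
                                x1 = pos1[, 1L], y1 = pos1[, 2L],
                                x2 = pos2[, 1L], y2 = pos2[, 2L]))
  })
  out$camera <- camera
  out
}

#' Render fiducial-bead registration frames
#'
#' An identical field of bright beads is rendered in both channels, the
#' second channel under the injected misalignment — the synthetic analogue
#' of multi-colour microsphere reference images used to align detection
#' channels.
#'
#' @param nBeads number of beads (>= 3; affine estimation needs three
#'   non-collinear points).
#' @param camera a \linkS4class{CameraModel}.
#' @param misalignment \code{NULL} or an \code{\link{affineMisalignment}}.
#' @param seed RNG seed.
#' @param beadPhotons integrated photons per bead (bright, high-SNR).
#' @param positions optional matrix/data.frame of bead (x, y) positions;
#'   collinear layouts are rejected.
#' @param noise logical; \code{FALSE} gives noiseless frames.
#' @return list with \code{green}, \code{red} (matrices) and
#'   \code{positions} (data.frame x1, y1, x2, y2).
#' @export
makeBeadFrames <- function(nBeads, camera = CameraModel(),
                           misalignment = NULL, seed = 1L,
                           beadPhotons = 2e4, positions = NULL,
                           noise = TRUE) {
  if (!is.null(positions)) {
    positions <- as.matrix(positions)[, 1:2, drop = FALSE]
    nBeads <- nrow(positions)
  }
  if (nBeads < 3L) stop("nBeads must be >= 3 for affine registration")
  nr <- camera@imageSize[1L]; nc <- camera@imageSize[2L]
  margin <- ceiling(4 * camera@psfSigmaPx) + 4
  .withSeed(seed, {
    if (is.null(positions)) {
      repeat {
        positions <- .placeSpots(nBeads, nr, nc, margin,
                                 8 * camera@psfSigmaPx)
        if (!.collinear(positions[, 1L], positions[, 2L])) break
      }
    } else if (.collinear(positions[, 1L], positions[, 2L])) {
      stop("bead layout is collinear; affine registration is degenerate")
    }
    pos2 <- .warpPoints(positions, misalignment)
    render <- function(pos) {
      img <- camera@backgroundPhotons +
        .renderSpots(nr, nc, pos[, 1L], pos[, 2L],
                     rep(beadPhotons, nrow(pos)), camera@psfSigmaPx)
      if (noise) .applyCameraNoise(img, camera) else camera@gain * img
    }
    list(green = render(positions), red = render(pos2),
         positions = data.frame(x1 = positions[, 1L], y1 = positions[, 2L],
                                x2 = pos2[, 1L], y2 = pos2[, 2L]))
  })
}
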