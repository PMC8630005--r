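# Image pipeline: spot localization, bead registration, co-localization,
# ROI trace read-out. Small 64 x 64 crops keep rendering cheap.

smallCamera <- function(...) CameraModel(imageSize = c(64L, 64L), ...)

test_that("spot detection handles blank images and centroid accuracy", {
  expect_identical(nrow(detectSpots(matrix(0, 32, 32))), 0L)
  expect_error(detectSpots(matrix(c(1, NA, 1, 1), 2, 2)), "non-finite")
  # noiseless Gaussian spot at a known sub-pixel centre, via the renderer
  cam <- smallCamera()
  img <- smPET:::.renderSpots(64, 64, 25.3, 40.7, 4000, cam@psfSigmaPx)
  s <- detectSpots(img, thresholdK = 5, psfSigmaPx = cam@psfSigmaPx)
  expect_identical(nrow(s), 1L)
  expect_lt(abs(s$x - 25.3), 0.05)
  expect_lt(abs(s$y - 40.7), 0.05)
  # brute-force moment oracle over the whole image agrees
  xs <- 0:63
  tot <- sum(img)
  expect_lt(abs(s$x - sum(colSums(img) * xs) / tot), 0.05)
  expect_lt(abs(s$y - sum(rowSums(img) * xs) / tot), 0.05)
  # two spots 20 px apart are both found to the same accuracy
  img2 <- smPET:::.renderSpots(64, 64, c(15.2, 35.2), c(20.6, 20.6),
                               c(4000, 4000), cam@psfSigmaPx)
  s2 <- detectSpots(img2, 5, cam@psfSigmaPx)
  s2 <- s2[order(s2$x), ]
  expect_identical(nrow(s2), 2L)
  expect_true(all(abs(s2$x - c(15.2, 35.2)) < 0.05))
  expect_true(all(abs(s2$y - 20.6) < 0.05))
})

test_that("registration recovers identity, shift and rotation transforms", {
  set.seed(8)
  b <- as.data.frame(smPET:::.placeSpots(12, 64, 64, margin = 5,
                                         minSep = 10))
  names(b) <- c("x", "y")
  # identity
  tr0 <- registerChannels(b, b)
  expect_equal(tr0@linear, diag(2), tolerance = 1e-9)
  expect_equal(tr0@offset, c(0, 0), tolerance = 1e-9)
  expect_lt(tr0@residualRms, 1e-9)
  # pure shift: offset recovered within 1e-6 px
  b2 <- data.frame(x = b$x + 3.2, y = b$y - 1.5)
  trS <- registerChannels(b, b2)
  expect_equal(trS@linear, diag(2), tolerance = 1e-7)
  expect_equal(trS@offset, c(-3.2, 1.5), tolerance = 1e-6)
  # rotation about the image centre + shift: mapped beads land on channel 1
  w <- affineMisalignment(shift = c(3.2, -1.5), angleDeg = 0.5,
                          center = c(32, 32))
  b2r <- as.data.frame(smPET:::.warpPoints(as.matrix(b), w))
  names(b2r) <- c("x", "y")
  trR <- registerChannels(b, b2r)
  expect_lt(trR@residualRms, 1e-6)
  mapped <- applyTransform(trR, b2r)
  expect_lt(sqrt(mean((mapped[, 1] - b$x)^2 + (mapped[, 2] - b$y)^2)), 1e-6)
})

test_that("registration rejects degenerate bead geometry", {
  lin <- data.frame(x = c(10, 20, 30), y = c(10, 20, 30))
  expect_error(registerChannels(lin, lin), "collinear")
  two <- data.frame(x = c(10, 30), y = c(10, 20))
  expect_error(registerChannels(two, two), "fewer than 3")
})

test_that("bead frames: identity warp gives identical fields, shift is recovered", {
  cam <- smallCamera()
  bf <- makeBeadFrames(12, cam, misalignment = NULL, seed = 4L, noise = FALSE)
  expect_identical(bf$green, bf$red)
  # 12 beads, shift-only warp: detected centroid displacement equals the
  # shift within 0.1 px even with shot noise
  w <- affineMisalignment(shift = c(3.2, -1.5))
  bf2 <- makeBeadFrames(12, cam, misalignment = w, seed = 4L)
  s1 <- detectSpots(bf2$green, 5, cam@psfSigmaPx)
  s2 <- detectSpots(bf2$red, 5, cam@psfSigmaPx)
  expect_identical(nrow(s1), 12L)
  expect_identical(nrow(s2), 12L)
  tr <- registerChannels(s1, s2)
  expect_lt(max(abs(tr@offset - c(-3.2, 1.5))), 0.1)
  expect_error(makeBeadFrames(2, cam), ">= 3")
  expect_error(makeBeadFrames(3, cam,
                              positions = cbind(c(10, 20, 30), c(10, 20, 30))),
               "collinear")
})

test_that("colocalization matches the brute-force assignment oracle", {
  # identical coordinates: all matched at distance 0
  s <- data.frame(x = c(10, 30, 50), y = c(12, 33, 20))
  pairs <- colocalize(s, s, identityTransform(), tolPx = 2)
  expect_identical(nrow(pairs), 3L)
  expect_true(all(pairs$distance_px == 0))
  # beyond tolerance: unmatched
  one <- data.frame(x = 10, y = 10)
  far <- data.frame(x = 13, y = 10)
  expect_identical(nrow(colocalize(one, far, tolPx = 2)), 0L)
  expect_identical(nrow(colocalize(one, far, tolPx = 4)), 1L)
  # ambiguous near-pairs agree with exhaustive minimum-total-distance
  # assignment
  s1 <- data.frame(x = c(10, 11.5, 40), y = c(10, 10, 40))
  s2 <- data.frame(x = c(10.6, 12.0, 40.2), y = c(10, 10, 40))
  pairs <- colocalize(s1, s2, tolPx = 2)
  oracle <- oracleAssign(s1$x, s2$x, window = 2)
  expect_identical(nrow(pairs), oracle$n)
  # greedy-by-distance equals the optimum on this instance
  expect_equal(sum(pairs$distance_px), oracle$cost, tolerance = 1e-9)
  # conservation: one-to-one
  expect_lte(nrow(pairs), min(nrow(s1), nrow(s2)))
  expect_identical(anyDuplicated(pairs$x1), 0L)
  # empty inputs
  expect_identical(nrow(colocalize(s1[0, ], s2, tolPx = 2)), 0L)
})

test_that("trace extraction: max-pixel read-out, time base and border guard", {
  # uniform stack: constant trace of that value
  stack <- list(green = array(7, dim = c(32, 32, 5)),
                red = array(3, dim = c(32, 32, 5)))
  rois <- data.frame(molecule_id = 1L, x1 = 16, y1 = 16, x2 = 16, y2 = 16)
  ts <- extractTraces(stack, rois, roiHalfWidthPx = 3, frameIntervalS = 0.3)
  expect_equal(as.numeric(traceMatrix(ts, "green")[1, ]), rep(7, 5))
  expect_equal(as.numeric(traceMatrix(ts, "red")[1, ]), rep(3, 5))
  # frame 20 at 0.3 s/frame is 6.0 s
  expect_equal(frameTimes(ts)[1:5], (0:4) * 0.3)
  ts2 <- extractTraces(list(g = array(0, dim = c(8, 8, 25))),
                       data.frame(molecule_id = 1L, x1 = 4, y1 = 4),
                       roiHalfWidthPx = 2, frameIntervalS = 0.3)
  expect_equal(frameTimes(ts2)[21], 6.0)
  # ROI touching the border errors with the molecule named
  bad <- data.frame(molecule_id = 7L, x1 = 1, y1 = 16, x2 = 1, y2 = 16)
  expect_error(extractTraces(stack, bad, 3, 0.3), "7")
  # noiseless rendered always-open spot: constant trace at the peak pixel
  cfg <- SimulationConfig(nMolecules = 1, kClose = 0, kOpen = 0,
                          kBleachGreen = 0, kBleachRed = 0, durationS = 3,
                          seed = 5L)
  traj <- simulateClampTrajectories(cfg)
  cam <- smallCamera()
  ri <- renderImageStack(traj, cam, seed = 2L, noise = FALSE)
  rois1 <- data.frame(molecule_id = 1L,
                      x1 = ri$positions$x1, y1 = ri$positions$y1,
                      x2 = ri$positions$x2, y2 = ri$positions$y2)
  tse <- extractTraces(ri$stacks, rois1, 3, 0.3)
  tr <- as.numeric(traceMatrix(tse, "green")[1, ])
  expect_true(all(tr == tr[1]))          # constant across frames
  frame1 <- ri$stacks$green[, , 1]
  expect_equal(tr[1], max(frame1))       # equals the rendered peak pixel
  # max pixel sits at the rounded true centre
  pk <- which(frame1 == max(frame1), arr.ind = TRUE)
  expect_equal(as.integer(pk[1, "col"] - 1L), as.integer(round(ri$positions$x1)))
  expect_equal(as.integer(pk[1, "row"] - 1L), as.integer(round(ri$positions$y1)))
})

test_that("blank stacks yield no spots at default thresholds", {
  cam <- smallCamera()
  cfg <- SimulationConfig(nMolecules = 0, durationS = 30, seed = 3L)
  traj <- simulateClampTrajectories(cfg)
  ri <- renderImageStack(traj, cam, seed = 9L)
  nFrames <- dim(ri$stacks$green)[3]
  expect_identical(nFrames, 100L)
  nWithSpots <- sum(vapply(seq_len(nFrames), function(f)
    nrow(detectSpots(ri$stacks$green[, , f], 5, cam@psfSigmaPx)) > 0,
    logical(1)))
  expect_lte(nWithSpots / nFrames, 0.01)
})

test_that("placement respects separation and fails gracefully when packed", {
  cam <- smallCamera()
  cfg <- SimulationConfig(nMolecules = 500, durationS = 0.3, seed = 3L)
  traj <- simulateClampTrajectories(cfg)
  expect_error(renderImageStack(traj, cam, seed = 1L), "could not place")
  cfg2 <- SimulationConfig(nMolecules = 15, durationS = 0.3, seed = 3L)
  ri <- renderImageStack(simulateClampTrajectories(cfg2), cam, seed = 1L)
  d <- as.matrix(dist(ri$positions[, c("x1", "y1")]))
  diag(d) <- Inf
  expect_gte(min(d), 4 * cam@psfSigmaPx)
  # injected shift misalignment is exactly the ground-truth offset
  w <- affineMisalignment(shift = c(3.2, -1.5))
  ri2 <- renderImageStack(simulateClampTrajectories(cfg2), cam,
                          misalignment = w, seed = 1L)
  expect_equal(ri2$positions$x2, ri2$positions$x1 + 3.2)
  expect_equal(ri2$positions$y2, ri2$positions$y1 - 1.5)
})

test_that("end-to-end colocalization recovers molecules, robust to misalignment", {
  cam <- smallCamera()
  cfg <- SimulationConfig(nMolecules = 12, durationS = 9, seed = 14L)
  traj <- simulateClampTrajectories(cfg)
  run <- function(w) {
    ri <- renderImageStack(traj, cam, misalignment = w, seed = 5L)
    tr <- if (is.null(w)) identityTransform() else {
      bf <- makeBeadFrames(12, cam, misalignment = w, seed = 6L)
      registerChannels(detectSpots(bf$green, 5, cam@psfSigmaPx),
                       detectSpots(bf$red, 5, cam@psfSigmaPx))
    }
    s1 <- detectSpots(maxProjection(ri$stacks$green), 5, cam@psfSigmaPx)
    s2 <- detectSpots(maxProjection(ri$stacks$red), 5, cam@psfSigmaPx)
    nrow(colocalize(s1, s2, tr, tolPx = 2))
  }
  nAligned <- run(NULL)
  expect_gte(nAligned / 12, 0.95)
  w <- affineMisalignment(shift = c(3.2, -1.5), angleDeg = 0.5,
                          center = c(32, 32))
  nWarped <- run(w)
  expect_lte(abs(nWarped - nAligned) / 12, 0.02)
})
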