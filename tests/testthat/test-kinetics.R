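# Transition pairing, dwell extraction, synchronicity bookkeeping and DSPO
# confirmation logic.

test_that("synchronicity pairing follows the six-frame window", {
  cfg <- AnalysisConfig(syncWindowFrames = 6L)
  # |dframe| = 4 <= 6: one synchronous pair
  ev <- pairSynchronous(data.frame(frame = 100L, direction = "down"),
                        data.frame(frame = 104L, direction = "down"), cfg)
  expect_identical(sum(ev$class == "synchronous"), 2L)
  expect_identical(ev$partner_frame[ev$channel == "green"], 104L)
  # |dframe| = 10 > 6: both non-synchronous (terminal quenches become
  # bleach candidates by the no-later-recovery rule)
  ev2 <- pairSynchronous(data.frame(frame = 100L, direction = "down"),
                         data.frame(frame = 110L, direction = "down"), cfg)
  expect_identical(sum(ev2$class == "synchronous"), 0L)
  # direction mismatch never pairs
  ev3 <- pairSynchronous(data.frame(frame = 100L, direction = "down"),
                         data.frame(frame = 102L, direction = "up"), cfg)
  expect_identical(sum(ev3$class == "synchronous"), 0L)
  expect_identical(nrow(ev3), 2L)
  # empty inputs give an empty classification
  expect_identical(nrow(pairSynchronous(NULL, NULL, cfg)), 0L)
})

test_that("greedy pairing equals the brute-force assignment oracle", {
  set.seed(31)
  cfg <- AnalysisConfig(syncWindowFrames = 6L)
  for (rep in 1:40) {
    n1 <- sample(0:4, 1); n2 <- sample(0:4, 1)
    f1 <- sort(sample(0:120, n1)); f2 <- sort(sample(0:120, n2))
    # same-direction steps only, so the oracle reduces to frame matching;
    # enforce the detector's minimum step separation within a channel
    if (n1 > 1 && any(diff(f1) < 3)) next
    if (n2 > 1 && any(diff(f2) < 3)) next
    ev <- pairSynchronous(
      data.frame(frame = f1, direction = rep("down", n1)),
      data.frame(frame = f2, direction = rep("down", n2)), cfg)
    oracle <- oracleAssign(f1, f2, window = 6)
    expect_identical(sum(ev$class == "synchronous") / 2, as.numeric(oracle$n))
  }
})

test_that("dwell extraction arithmetic, censoring and provenance", {
  cfg <- AnalysisConfig(frameIntervalS = 0.3)
  # quench at 100, recovery at 140: one closed dwell of 12 s, uncensored
  steps <- data.frame(molecule_id = 1L, channel = "green",
                      frame = c(100L, 140L), direction = c("down", "up"))
  d <- extractDwells(steps, nFrames = 1800L, cfg)
  inner <- d[!d$left_censored & !d$right_censored, ]
  expect_identical(nrow(inner), 1L)
  expect_identical(inner$state, "closed")
  expect_equal(inner$duration_s, 12.0)
  # a single step yields no uncensored dwell (both flanks censored)
  d1 <- extractDwells(steps[1, ], nFrames = 1800L, cfg)
  expect_identical(sum(!d1$left_censored & !d1$right_censored), 0L)
  # overlapping steps indicate an upstream bug
  bad <- data.frame(molecule_id = 1L, channel = "green",
                    frame = c(100L, 100L), direction = c("down", "up"))
  expect_error(extractDwells(bad, 1800L, cfg), "overlapping")
})

test_that("simulated closed dwells recover the 12-s mean (seed 13)", {
  cfg <- SimulationConfig(nMolecules = 120, kClose = 1, kOpen = 5,
                          pUncoupled = 0, kBleachGreen = 0, kBleachRed = 0,
                          seed = 13L)
  traj <- simulateClampTrajectories(cfg)
  ts <- renderTraces(traj, seed = 13L, shotNoise = FALSE, signalLevel = 100,
                     backgroundLevel = 0, readNoiseSd = 10)
  id <- idealizeTraces(ts)
  dw <- extractDwells(id$steps, id$nFrames,
                      AnalysisConfig(frameIntervalS = 0.3))
  closed <- dw$duration_s[dw$state == "closed" & !dw$left_censored &
                          !dw$right_censored]
  expect_gt(length(closed), 800)
  expect_lt(abs(mean(closed) - 12) / 12, 0.10)
})

test_that("cumulative sum curves are correct and converge to the CDF", {
  expect_equal(dwellCumSum(c(3, 1, 2)),
               data.frame(duration = c(1, 2, 3), count = 1:3))
  same <- dwellCumSum(rep(4, 7))
  expect_true(all(same$duration == 4))
  expect_identical(same$count[7], 7L)
  expect_error(dwellCumSum(numeric(0)), "no dwell")
  # DKW bound at alpha = 0.01, n = 2000: sup|F_n - F| <= sqrt(log(2/a)/(2n))
  set.seed(5)
  tau <- 10
  x <- rexp(2000, 1 / tau)
  curve <- dwellCumSum(x)
  fn <- curve$count / 2000
  f <- pexp(curve$duration, 1 / tau)
  expect_lte(max(abs(fn - f)), sqrt(log(2 / 0.01) / (2 * 2000)))
})

test_that("synchronicity percentages reproduce the published count arithmetic", {
  # per-construct counts: (422, 62), (516, 55), (322, 57)
  p1 <- synchronicityPercent(422, 62)
  p2 <- synchronicityPercent(516, 55)
  p3 <- synchronicityPercent(322, 57)
  expect_equal(p1$percentNonSyncRatio, 14.7, tolerance = 0.01)
  expect_equal(p1$percentNonSyncTotal, 12.8, tolerance = 0.01)
  expect_equal(p3$percentNonSyncRatio, 17.7, tolerance = 0.01)
  expect_equal(p3$percentNonSyncTotal, 15.0, tolerance = 0.01)
  # all constructs fall in the reported 10-18% band (ratio convention)
  for (p in list(p1, p2, p3)) {
    expect_gte(p$percentNonSyncRatio, 10)
    expect_lte(p$percentNonSyncRatio, 18)
  }
  p0 <- synchronicityPercent(100, 0)
  expect_identical(p0$percentNonSyncRatio, 0)
  expect_identical(p0$percentNonSyncTotal, 0)
})

test_that("DSPO logic confirms PET events and flags anomalies", {
  dt <- 1; dur <- 900
  # quench at 300 s + recovery at 650 s (O2 at 600): confirmed
  # quench at 300 s, no recovery: unconfirmed
  # recovery at 500 s < O2: anomalous
  steps <- rbind(
    data.frame(molecule_id = 1L, frame = c(300L, 650L),
               direction = c("down", "up")),
    data.frame(molecule_id = 2L, frame = 300L, direction = "down"),
    data.frame(molecule_id = 3L, frame = c(100L, 500L),
               direction = c("down", "up")))
  pet <- identifyPetEvents(steps, 600, dt, dur)
  expect_true(pet$pet_confirmed[pet$molecule_id == 1L])
  expect_false(pet$pet_confirmed[pet$molecule_id == 2L])
  expect_false(pet$pet_confirmed[pet$molecule_id == 3L])
  anom <- attr(pet, "anomalous_recovery")
  expect_identical(anom$molecule_id, 3L)
  expect_error(identifyPetEvents(steps, 1200, dt, dur), "outside")
})

test_that("pipeline reports near-total synchrony when coupling is perfect", {
  cfg <- SimulationConfig(nMolecules = 60, pUncoupled = 0,
                          syncJitterFrames = 0L, kBleachGreen = 0,
                          kBleachRed = 0, seed = 19L)
  traj <- simulateClampTrajectories(cfg)
  ts <- renderTraces(traj, seed = 19L)
  id <- idealizeTraces(ts)
  kin <- analyzeKinetics(id$steps, id$nFrames, AnalysisConfig())
  pctSync <- 100 * kin@nSynchronous /
    (kin@nSynchronous + kin@nNonSynchronous)
  expect_gte(pctSync, 98)
})

test_that("non-synchronous closed dwells carry opening-like kinetics", {
  cfg <- SimulationConfig(nMolecules = 150, kClose = 1, kOpen = 5,
                          pUncoupled = 0.3, kBleachGreen = 0, kBleachRed = 0,
                          seed = 23L)
  traj <- simulateClampTrajectories(cfg)
  ts <- renderTraces(traj, seed = 23L)
  id <- idealizeTraces(ts)
  acfg <- AnalysisConfig()
  events <- classifyTransitions(id$steps, acfg)
  dw <- extractDwells(id$steps, id$nFrames, acfg, events)
  nsClosed <- dw$duration_s[dw$state == "closed" & !dw$left_censored &
                            !dw$right_censored &
                            dw$provenance == "non_synchronous" &
                            !is.na(dw$provenance)]
  expect_gt(length(nsClosed), 25)
  fit <- fitExponentialCdf(dwellCumSum(nsClosed), "fixed_mono")
  kOpenHat <- meanRate(fit)
  expect_lt(abs(kOpenHat - 5) / 5, 0.25)
})

test_that("green and red channels give consistent rate constants", {
  cfg <- SimulationConfig(nMolecules = 100, kClose = 1, kOpen = 5,
                          pUncoupled = 0.12, seed = 29L)
  traj <- simulateClampTrajectories(cfg)
  ts <- renderTraces(traj, seed = 29L)
  id <- idealizeTraces(ts)
  kin <- analyzeKinetics(id$steps, id$nFrames, AnalysisConfig())
  g <- kin@perChannel$green; r <- kin@perChannel$red
  # bootstrap s.e. over molecules via the mean-dwell approximation
  bootSe <- function(ch, state) {
    events <- classifyTransitions(id$steps, AnalysisConfig())
    dw <- extractDwells(id$steps, id$nFrames, AnalysisConfig(), events)
    d <- dw[dw$channel == ch & dw$state == state & !dw$left_censored &
            !dw$right_censored, ]
    mols <- unique(d$molecule_id)
    set.seed(1)
    reps <- replicate(100, {
      pick <- sample(mols, length(mols), replace = TRUE)
      60 / mean(unlist(lapply(pick, function(m)
        d$duration_s[d$molecule_id == m])))
    })
    sd(reps)
  }
  seC <- sqrt(bootSe("green", "open")^2 + bootSe("red", "open")^2)
  seO <- sqrt(bootSe("green", "closed")^2 + bootSe("red", "closed")^2)
  expect_lt(abs(g$kC - r$kC), 2 * seC)
  expect_lt(abs(g$kO - r$kO), 2 * seO)
})
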