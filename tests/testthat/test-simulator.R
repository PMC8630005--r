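# Generative model of the coupled clamp: exponential dwell statistics,
# concertedness, uncoupled-event bookkeeping, bleaching, determinism.

test_that("config validation rejects unphysical parameters", {
  expect_error(SimulationConfig(kClose = -1), "rates")
  expect_error(SimulationConfig(pUncoupled = 1.5), "pUncoupled")
  expect_error(SimulationConfig(frameIntervalS = 0), "frameIntervalS")
  expect_error(SimulationConfig(durationS = 0.1, frameIntervalS = 0.3),
               "durationS")
  expect_error(SimulationConfig(mode = "banana"), "mode")
})

test_that("zero rates give constant open trajectories and an empty event log", {
  for (mode in c("atp_cycling", "apo")) {
    traj <- simulateClampTrajectories(SimulationConfig(
      nMolecules = 5, kClose = 0, kOpen = 0, kBleachGreen = 0,
      kBleachRed = 0, mode = mode, seed = 3L))
    expect_true(all(traj@states == 1L))
    expect_identical(nrow(eventLog(traj)), 0L)
  }
})

test_that("dwell times are exponential with the configured means", {
  # k_close = 1/min, k_open = 5/min: mean open dwell 60 s, closed 12 s
  cfg <- SimulationConfig(nMolecules = 200, kClose = 1, kOpen = 5,
                          pUncoupled = 0, kBleachGreen = 0, kBleachRed = 0,
                          seed = 42L)
  traj <- simulateClampTrajectories(cfg)
  s <- stateMatrix(traj, "green")
  dt <- frameInterval(traj)
  openD <- c(); closedD <- c()
  nClosures <- 0L; totalOpenS <- 0
  for (m in seq_len(nrow(s))) {
    r <- rle(s[m, ])
    totalOpenS <- totalOpenS + sum(r$lengths[r$values == 1L]) * dt
    nClosures <- nClosures + sum(r$values == 2L)
    if (length(r$lengths) < 3L) next
    inner <- 2:(length(r$lengths) - 1L)            # censored flanks dropped
    openD <- c(openD, r$lengths[inner][r$values[inner] == 1L] * dt)
    closedD <- c(closedD, r$lengths[inner][r$values[inner] == 2L] * dt)
  }
  expect_gt(length(openD) + length(closedD), 1500)
  # open dwells (mean 60 s) are visibly window-censored in a 540-s trace, so
  # use the censoring-consistent exponential MLE: total open time / closures
  expect_lt(abs(totalOpenS / nClosures - 60) / 60, 0.10)
  # closed dwells (mean 12 s) are essentially unaffected by the window
  expect_lt(abs(mean(closedD) - 12) / 12, 0.10)
  # distribution shape: KS against the exponential with the sample mean.
  # Closed dwells are ~40 frames long, so discretization is mild; jitter
  # the frame quantization uniformly to avoid spurious KS rejection.
  set.seed(1)
  jit <- closedD + runif(length(closedD), -dt / 2, dt / 2)
  expect_gt(ks.test(jit, "pexp", 1 / mean(jit))$p.value, 0.01)
})

test_that("with no uncoupled events both channels step at the same frame", {
  cfg <- SimulationConfig(nMolecules = 50, pUncoupled = 0,
                          syncJitterFrames = 0L, kBleachGreen = 0,
                          kBleachRed = 0, seed = 11L)
  traj <- simulateClampTrajectories(cfg)
  ev <- eventLog(traj)
  g <- ev[ev$channel == "green", ]
  r <- ev[ev$channel == "red", ]
  expect_identical(g$frame, r$frame)
  expect_identical(g$kind, r$kind)
  expect_true(all(grepl("^coupled", ev$kind)))
})

test_that("the uncoupled fraction of closures converges to p_uncoupled", {
  p <- 0.25
  cfg <- SimulationConfig(nMolecules = 300, pUncoupled = p,
                          kBleachGreen = 0, kBleachRed = 0, seed = 7L)
  ev <- eventLog(simulateClampTrajectories(cfg))
  nUnc <- sum(ev$kind == "uncoupled_close")
  nCoup <- sum(ev$kind == "coupled_close" & ev$channel == "green")
  n <- nUnc + nCoup
  phat <- nUnc / n
  ci <- 3 * sqrt(p * (1 - p) / n)
  expect_lt(abs(phat - p), ci)
})

test_that("uncoupled excursions are initiated only as closures", {
  cfg <- SimulationConfig(nMolecules = 100, pUncoupled = 0.3, seed = 5L)
  ev <- eventLog(simulateClampTrajectories(cfg))
  unc <- ev[grepl("^uncoupled", ev$kind), ]
  # every uncoupled_open is preceded in its channel by an uncoupled_close
  for (m in unique(unc$molecule_id)) {
    for (ch in unique(unc$channel[unc$molecule_id == m])) {
      k <- unc[unc$molecule_id == m & unc$channel == ch, ]
      k <- k[order(k$frame), ]
      expect_identical(k$kind[1L], "uncoupled_close")
    }
  }
})

test_that("bleached is absorbing and logged", {
  cfg <- SimulationConfig(nMolecules = 60, kBleachGreen = 2, kBleachRed = 2,
                          seed = 9L)
  traj <- simulateClampTrajectories(cfg)
  s <- stateMatrix(traj, "green")
  for (m in seq_len(nrow(s))) {
    b <- which(s[m, ] == 3L)
    if (length(b)) expect_true(all(s[m, b[1L]:ncol(s)] == 3L))
  }
  expect_gt(sum(eventLog(traj)$kind == "bleach"), 0)
})

test_that("the simulator is a pure function of (config, seed)", {
  cfg <- SimulationConfig(nMolecules = 10, seed = 123L)
  t1 <- simulateClampTrajectories(cfg)
  t2 <- simulateClampTrajectories(cfg)
  expect_identical(t1@states, t2@states)
  expect_identical(eventLog(t1), eventLog(t2))
  t3 <- simulateClampTrajectories(SimulationConfig(nMolecules = 10,
                                                   seed = 124L))
  expect_false(identical(t1@states, t3@states))
})

test_that("AMP-PNP mode: closure before O2 recovers by DSPO after O2", {
  cfg <- SimulationConfig(nMolecules = 150, mode = "ampnp_onecolour",
                          durationS = 900, frameIntervalS = 1,
                          kClose = 0.3, o2ApplicationS = 600,
                          dspoMeanDelayS = 30, kBleachGreen = 0, seed = 21L)
  traj <- simulateClampTrajectories(cfg)
  ev <- eventLog(traj)
  closes <- ev[ev$kind == "coupled_close", ]
  recs <- ev[ev$kind == "dspo_recovery", ]
  o2Frame <- 600 / 1
  for (i in seq_len(nrow(closes))) {
    if (closes$frame[i] < o2Frame) {
      # quenched at O2 application, recovered at 600 s + Exp(delay)
      m <- closes$molecule_id[i]
      s <- stateMatrix(traj, "green")[m, ]
      expect_identical(s[o2Frame + 1L], 2L)
      r <- recs$frame[recs$molecule_id == m]
      expect_length(r, 1L)
      expect_gte(r, o2Frame)
    }
  }
  # recovery delays after O2 have roughly the configured mean
  d <- (recs$frame - o2Frame) * 1
  expect_gt(length(d), 50)
  expect_lt(abs(mean(d) - 30) / 30, 0.25)
})

test_that("renderTraces noiseless limit is piecewise constant at event frames", {
  cfg <- SimulationConfig(nMolecules = 8, seed = 31L)
  traj <- simulateClampTrajectories(cfg)
  ts <- renderTraces(traj, shotNoise = FALSE, readNoiseSd = 0, seed = 1L)
  ev <- eventLog(traj)
  for (ch in c("green", "red")) {
    tr <- traceMatrix(ts, ch)
    st <- stateMatrix(traj, ch)
    for (m in seq_len(nrow(tr))) {
      breaks <- which(diff(tr[m, ]) != 0)        # 0-based frame = index
      expected <- sort(ev$frame[ev$molecule_id == m & ev$channel == ch])
      expect_identical(as.integer(breaks), as.integer(expected))
      # two-level mapping: open high, closed/bleached at background
      expect_identical(length(unique(tr[m, st[m, ] != 1L])) <= 1L, TRUE)
    }
  }
})

test_that("shot-noise variance matches the Poisson model", {
  cfg <- SimulationConfig(nMolecules = 1, kClose = 0, kOpen = 0,
                          kBleachGreen = 0, kBleachRed = 0, seed = 2L)
  traj <- simulateClampTrajectories(cfg)
  lev <- 500
  ts <- renderTraces(traj, seed = 8L, shotNoise = TRUE, signalLevel = lev,
                     backgroundLevel = 0, readNoiseSd = 0)
  x <- as.numeric(traceMatrix(ts, "green")[1L, ])
  n <- length(x)
  # chi-square test of the variance/mean (Fano) ratio at alpha = 0.01
  stat <- (n - 1) * var(x) / mean(x)
  expect_gt(stat, qchisq(0.005, n - 1))
  expect_lt(stat, qchisq(0.995, n - 1))
})

test_that("rendered traces are deterministic given the seed", {
  cfg <- SimulationConfig(nMolecules = 4, seed = 6L)
  traj <- simulateClampTrajectories(cfg)
  a <- renderTraces(traj, seed = 99L)
  b <- renderTraces(traj, seed = 99L)
  expect_identical(traceMatrix(a, "green"), traceMatrix(b, "green"))
  expect_identical(traceMatrix(a, "red"), traceMatrix(b, "red"))
})
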