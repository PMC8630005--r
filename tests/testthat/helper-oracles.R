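# Independent oracles used to freeze expected values: naive direct-summation
# convolution, exhaustive least-squares change-point fits, and brute-force
# assignment. Deliberately simple and separate from the package internals.

# reflective padding + naive O(n k) convolution: y[t] = sum_j k[j] x[t+j]
oracleConv <- function(x, kernel) {
  n <- length(x)
  R <- (length(kernel) - 1L) %/% 2L
  xp <- c(x[min(R, n):1], x, x[n:(n - min(R, n) + 1L)])
  y <- numeric(n)
  for (t in seq_len(n)) {
    acc <- 0
    for (j in -R:R) acc <- acc + kernel[j + R + 1L] * xp[t + R + j]
    y[t] <- acc
  }
  y
}

oracleDogKernel <- function(scale) {
  R <- ceiling(4 * scale)
  j <- -R:R
  w <- j * exp(-j^2 / (2 * scale^2))
  w / sum(w[j > 0])
}

oracleMultiscale <- function(x, scales = c(1, 2, 4)) {
  p <- rep(1, length(x))
  for (s in scales) p <- p * oracleConv(x, oracleDogKernel(s))
  p
}

# exhaustive least-squares single change point; returns 0-based frame of the
# first sample of the new level
oracleChangePoint1 <- function(x) {
  n <- length(x)
  best <- NULL
  for (k in 2:(n - 1)) {
    rss <- sum((x[1:(k - 1)] - mean(x[1:(k - 1)]))^2) +
      sum((x[k:n] - mean(x[k:n]))^2)
    if (is.null(best) || rss < best$rss) best <- list(k = k, rss = rss)
  }
  best$k - 1L
}

# exhaustive least-squares two change points (0-based frames)
oracleChangePoint2 <- function(x) {
  n <- length(x)
  css <- function(seg) sum((seg - mean(seg))^2)
  best <- NULL
  for (k1 in 2:(n - 2)) {
    r1 <- css(x[1:(k1 - 1)])
    for (k2 in (k1 + 1):(n - 1)) {
      rss <- r1 + css(x[k1:(k2 - 1)]) + css(x[k2:n])
      if (is.null(best) || rss < best$rss) best <- list(k = c(k1, k2), rss = rss)
    }
  }
  best$k - 1L
}

# brute-force one-to-one assignment between two small frame vectors:
# maximize the number of pairs within the window, then minimize total |d|
oracleAssign <- function(f1, f2, window) {
  best <- list(n = -1L, cost = Inf, pairs = NULL)
  n1 <- length(f1)
  recurse <- function(i, used2, pairs, cost) {
    if (i > n1) {
      n <- nrow(pairs)
      if (n > best$n || (n == best$n && cost < best$cost))
        best <<- list(n = n, cost = cost, pairs = pairs)
      return(invisible())
    }
    recurse(i + 1L, used2, pairs, cost)          # leave f1[i] unmatched
    for (j in seq_along(f2)) {
      if (used2[j]) next
      d <- abs(f1[i] - f2[j])
      if (d <= window) {
        used2[j] <- TRUE
        recurse(i + 1L, used2, rbind(pairs, c(i, j)), cost + d)
        used2[j] <- FALSE
      }
    }
  }
  recurse(1L, logical(length(f2)),
          matrix(integer(0), 0L, 2L), 0)
  best
}

# two-level trace builder; stepFrames are 0-based frames of the first sample
# at the new level
makeStepTrace <- function(n, stepFrames, directions, high = 100, low = 10,
                          noiseSd = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  lev <- numeric(n)
  cur <- if (length(directions) && directions[1] == "down") high else low
  prev <- 1L
  for (k in seq_along(stepFrames)) {
    b <- stepFrames[k] + 1L               # 1-based first sample of new level
    lev[prev:(b - 1L)] <- cur
    cur <- if (directions[k] == "down") low else high
    prev <- b
  }
  lev[prev:n] <- cur
  lev + if (noiseSd > 0) rnorm(n, 0, noiseSd) else 0
}
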