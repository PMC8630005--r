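# Dwell-time and bulk-decay exponential fitting. Cumulative sum plots are
# the bin-free representation of dwell-time distributions: the fitted model
# is N(t) = N_tot * sum_i a_i * (1 - exp(-t / tau_i)) with sum(a_i) = 1.

#' Cumulative sum curve of dwell times
#'
#' @param durations numeric vector of dwell durations (>= 1 value).
#' @return data.frame with \code{duration} (sorted ascending) and
#'   \code{count} (number of dwells <= duration); monotone non-decreasing,
#'   final count = n.
#' @examples
#' dwellCumSum(c(3, 1, 2))
#' @export
dwellCumSum <- function(durations) {
  if (!length(durations)) stop("no dwell durations supplied")
  if (any(!is.finite(durations) | durations <= 0))
    stop("durations must be finite and > 0")
  data.frame(duration = sort(durations), count = seq_along(durations))
}

.fitMono <- function(t, y, n, mstart) {
  best <- NULL
  for (tau0 in mstart) {
    fit <- tryCatch(
      minpack.lm::nlsLM(y ~ n * (1 - exp(-t / tau)),
                        start = list(tau = tau0),
                        lower = 1e-12, upper = Inf,
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (!is.null(fit)) {
      rss <- sum(resid(fit)^2)
      if (is.null(best) || rss < best$rss)
        best <- list(a = 1, tau = coef(fit)[["tau"]], rss = rss)
    }
  }
  best
}

.fitBi <- function(t, y, n, mstart) {
  best <- NULL
  grid <- expand.grid(t1 = mstart, t2 = mstart)
  grid <- grid[grid$t1 < grid$t2, , drop = FALSE]
  for (g in seq_len(nrow(grid))) {
    fit <- tryCatch(
      minpack.lm::nlsLM(
        y ~ n * (a * (1 - exp(-t / tau1)) + (1 - a) * (1 - exp(-t / tau2))),
        start = list(a = 0.5, tau1 = grid$t1[g], tau2 = grid$t2[g]),
        lower = c(0, 1e-12, 1e-12), upper = c(1, Inf, Inf),
        control = minpack.lm::nls.lm.control(maxiter = 400)),
      error = function(e) NULL)
    if (!is.null(fit)) {
      rss <- sum(resid(fit)^2)
      if (is.null(best) || rss < best$rss) {
        cf <- coef(fit)
        best <- list(a = c(cf[["a"]], 1 - cf[["a"]]),
                     tau = c(cf[["tau1"]], cf[["tau2"]]), rss = rss)
      }
    }
  }
  best
}

.bic <- function(rss, n, k) n * log(max(rss, 1e-300) / n) + k * log(n)

#' Fit mono-/bi-exponential models to a cumulative dwell-time curve
#'
#' Least-squares fit of \code{N(t) = N_tot * sum_i a_i (1 - exp(-t/tau_i))}
#' with amplitudes constrained to sum to 1 and multi-start initialization
#' (time constants at 0.5x, 1x and 2x the sample mean). With
#' \code{modelSelection = "bic"} both models are fitted (sample size
#' permitting) and the lower Bayesian information criterion wins.
#'
#' @param curve data.frame from \code{\link{dwellCumSum}}, or a numeric
#'   vector of durations.
#' @param modelSelection "bic", "fixed_mono" or "fixed_bi".
#' @param timeUnit unit of the durations, "s" (default) or "min".
#' @return an \linkS4class{ExponentialFit}.
#' @examples
#' d <- dwellCumSum(rexp(200, 1 / 10))
#' fitExponentialCdf(d, "fixed_mono")
#' @export
fitExponentialCdf <- function(curve, modelSelection = c("bic", "fixed_mono",
                                                        "fixed_bi"),
                              timeUnit = "s") {
  modelSelection <- match.arg(modelSelection)
  if (is.numeric(curve)) curve <- dwellCumSum(curve)
  t <- curve$duration; y <- curve$count
  n <- length(t)
  minN <- if (modelSelection == "fixed_bi") 25L else 10L
  if (n < minN)
    stop(sprintf("too few dwells: %d supplied, minimum %d for this model",
                 n, minN))
  if (length(unique(t)) == 1L)
    stop("all dwell durations are equal; exponential fit is degenerate")
  mstart <- mean(t) * c(0.5, 1, 2)
  mono <- if (modelSelection != "fixed_bi") .fitMono(t, y, n, mstart) else NULL
  bi <- if (modelSelection != "fixed_mono" && n >= 25L)
          .fitBi(t, y, n, mstart) else NULL
  if (modelSelection == "fixed_bi" && is.null(bi))
    stop("bi-exponential fit did not converge")
  pick <- NULL; k <- NA_integer_
  if (modelSelection == "bic") {
    bicMono <- if (!is.null(mono)) .bic(mono$rss, n, 1L) else Inf
    bicBi <- if (!is.null(bi)) .bic(bi$rss, n, 3L) else Inf
    if (!is.finite(bicMono) && !is.finite(bicBi))
      stop("neither exponential model converged")
    if (bicBi < bicMono) { pick <- bi; k <- 2L; bicSel <- bicBi }
    else { pick <- mono; k <- 1L; bicSel <- bicMono }
  } else if (modelSelection == "fixed_mono") {
    if (is.null(mono)) stop("mono-exponential fit did not converge")
    pick <- mono; k <- 1L; bicSel <- .bic(mono$rss, n, 1L)
  } else {
    pick <- bi; k <- 2L; bicSel <- .bic(bi$rss, n, 3L)
  }
  ord <- order(pick$tau)
  a <- pick$a[ord]; tau <- pick$tau[ord]
  # collapse numerically-degenerate second components
  a <- a / sum(a)
  new("ExponentialFit", amplitudes = a, taus = tau, nComponents = k,
      rss = pick$rss, bic = bicSel, nDwells = as.integer(n),
      timeUnit = timeUnit, converged = TRUE)
}

#' @rdname meanRate
#' @export
setMethod("meanRate", "ExponentialFit", function(fit) {
  if (abs(sum(fit@amplitudes) - 1) > 1e-6)
    stop("amplitudes are not normalized to sum to 1")
  wtau <- sum(fit@amplitudes * fit@taus)       # amplitude-weighted mean time
  if (fit@timeUnit == "s") 60 / wtau else 1 / wtau
})

#' Fit a bi-exponential bulk fluorescence decay
#'
#' Fits \code{I(t) = I_inf + A1 exp(-t/tau1) + A2 exp(-t/tau2)} to a bulk
#' PET quenching time course (e.g. clamp closure triggered at t = 0) and
#' reports the amplitude-weighted mean rate constant.
#'
#' @param time numeric vector of times (only t >= 0 is fitted).
#' @param intensity bulk fluorescence intensities.
#' @param timeUnit unit of \code{time}, "min" (default) or "s".
#' @return list with \code{fit} (an \linkS4class{ExponentialFit} holding the
#'   normalized decay amplitudes), \code{meanRatePerMin}, \code{iInf} and
#'   \code{amplitudesRaw}.
#' @export
fitBulkDecay <- function(time, intensity, timeUnit = "min") {
  keep <- time >= 0 & is.finite(time) & is.finite(intensity)
  t <- time[keep]; I <- intensity[keep]
  if (length(t) < 30L)
    stop("need at least 30 points after t = 0 to fit a bulk decay")
  headI <- mean(I[seq_len(max(3L, length(I) %/% 10L))])
  tailI <- mean(I[seq.int(length(I) - max(3L, length(I) %/% 10L) + 1L,
                          length(I))])
  spread <- stats::sd(I)
  if (!(headI > tailI + 0.1 * spread) || spread == 0)
    stop("series is not decaying; cannot fit a decay model")
  span <- max(t) - min(t)
  best <- NULL
  for (s in list(c(0.05, 0.5), c(0.1, 1), c(0.02, 0.2))) {
    fit <- tryCatch(
      minpack.lm::nlsLM(
        I ~ iInf + A1 * exp(-t / tau1) + A2 * exp(-t / tau2),
        start = list(iInf = min(I), A1 = (headI - tailI) / 2,
                     A2 = (headI - tailI) / 2, tau1 = s[1] * span,
                     tau2 = s[2] * span),
        lower = c(-Inf, 0, 0, 1e-12, 1e-12),
        control = minpack.lm::nls.lm.control(maxiter = 400)),
      error = function(e) NULL)
    if (!is.null(fit)) {
      rss <- sum(resid(fit)^2)
      if (is.null(best) || rss < best$rss) best <- list(fit = fit, rss = rss)
    }
  }
  if (is.null(best)) stop("bulk decay fit did not converge")
  cf <- coef(best$fit)
  A <- c(cf[["A1"]], cf[["A2"]]); tau <- c(cf[["tau1"]], cf[["tau2"]])
  ord <- order(tau)
  A <- A[ord]; tau <- tau[ord]
  a <- A / sum(A)
  ef <- new("ExponentialFit", amplitudes = a, taus = tau, nComponents = 2L,
            rss = best$rss, bic = .bic(best$rss, length(t), 5L),
            nDwells = as.integer(length(t)), timeUnit = timeUnit,
            converged = TRUE)
  list(fit = ef, meanRatePerMin = meanRate(ef), iInf = cf[["iInf"]],
       amplitudesRaw = A)
}

#' Free-energy change for a rate-constant ratio
#'
#' Converts a fold-change of a rate constant into the corresponding change
#' of activation free energy, |-R T ln(k/k')| in kcal/mol, with
#' R = 1.987e-3 kcal mol^-1 K^-1.
#'
#' @param rateRatio dimensionless rate ratio k/k' (> 0).
#' @param temperatureK absolute temperature in kelvin (default 298.15, i.e.
#'   25 degrees C).
#' @return free-energy change in kcal/mol.
#' @examples
#' deltaDeltaG(2)        # ~0.41 kcal/mol for a two-fold change at 25 C
#' @export
deltaDeltaG <- function(rateRatio, temperatureK = 298.15) {
  if (!is.finite(rateRatio) || rateRatio <= 0)
    stop("rateRatio must be a positive number")
  if (!is.finite(temperatureK) || temperatureK <= 0)
    stop("temperatureK must be > 0")
  R <- 1.987e-3
  abs(-R * temperatureK * log(rateRatio))
}
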