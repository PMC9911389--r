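## Closed-form expected-metric oracle for clean synthetic cohorts.
##
## The statistic averages each trial's potential over a fixed window and
## runs a two-sample t-test per channel on resampled trial sets. On clean
## synthetic data its expectation is computable: the window-mean noise
## variance follows exactly from the generator's circulant spectral model,
## weak inter-trial correlation of window means (long-memory 1/f noise)
## enters as the mean pairwise covariance between trials, resampling with
## replacement from a finite trial pool inflates the numerator variance by
## (1/n + (n-1)/(n m)) per group relative to the within-resample variance
## estimate, and the per-trial amplitude jitter adds variance to the
## effect-bearing condition. Combining these gives a scaled noncentral-t
## tail probability per channel.

# Integer sample grid of a half-open window [w1, w2) at the given rate
# (matches the epoch-time selection used by the metric).
.gridWindow <- function(window, srate) {
  kmin <- ceiling(window[1] * srate - 1e-6)
  kmax <- ceiling(window[2] * srate - 1e-6) - 1
  if (kmax < kmin) stop("window contains no samples at this rate")
  kmin:kmax
}

# Circulant autocovariance (lags 0..n-1) of the generator's stationary
# background (1/f plus drift) at recording length n.
.noiseAutocov <- function(cfg, n) {
  f <- .foldedFreq(n, cfg@srate)
  S <- numeric(n)
  aP <- .pinkAmp(f, cfg@noise$exponent)
  S <- S + aP^2 * cfg@noise$rms^2 / mean(aP^2)
  if (cfg@drift$rms > 0) {
    aD <- .driftAmp(f, cfg@drift$cornerHz)
    S <- S + aD^2 * cfg@drift$rms^2 / mean(aD^2)
  }
  Re(stats::fft(S, inverse = TRUE)) / n
}

# Covariance of two m-sample window means whose starts are L samples apart
# (L = 0 gives the window-mean variance), under autocovariance r (circular).
.windowMeanCov <- function(r, m, L, n) {
  k <- -(m - 1):(m - 1)
  w <- m - abs(k)
  lag <- abs(L + k) %% n
  lag <- pmin(lag, n - lag)
  sum(w * r[lag + 1]) / m^2
}

# Two-sided two-sample t-test power under the two-stage resampling scheme.
# delta: true mean difference; varA/varB: per-trial variances; m: draw per
# group; pool: trials available per group (Inf -> classic iid power).
.resampledPower <- function(delta, varA, varB, m, pool, alpha) {
  if (is.finite(pool)) {
    inflate <- 1 / pool + (pool - 1) / (pool * m)
    vnum <- (varA + varB) * inflate
    se2exp <- (varA + varB) * (pool - 1) / (pool * m)
  } else {
    vnum <- (varA + varB) / m
    se2exp <- vnum
  }
  kap <- sqrt(se2exp / vnum)
  df <- 2 * (m - 1)
  tc <- stats::qt(1 - alpha / 2, df)
  ncp <- delta / sqrt(vnum)
  1 - stats::pt(tc * kap, df, ncp) + stats::pt(-tc * kap, df, ncp)
}

#' Expected metric on clean synthetic data
#'
#' Analytic oracle for \code{\link{resampledMetric}} in the clean regime
#' (no artifact transients): returns the expected percentage of significant
#' channels as the mean over channels of the two-sample t-test power at
#' each channel's effect size. The per-channel effect is the window-mean
#' amplitude of the condition-difference bump times the realized topography
#' weight; the per-trial noise variance of the window mean follows exactly
#' from the generator's spectral model (1/f background plus drift),
#' corrected for the mean inter-trial covariance induced by long-memory
#' noise. With \code{poolSize} set, the two-stage correction for resampling
#' with replacement from a finite trial pool is applied (without it the
#' classic iid power is returned, whose value at zero effect is exactly
#' \code{100 * alpha}).
#'
#' @param cfg a \linkS4class{SyntheticConfig} (ignored when \code{d} is
#'   given).
#' @param nResample trials drawn per condition per repetition.
#' @param alpha per-channel test level.
#' @param window averaging window (start, end) s; default: effect latency
#'   +/- 50 ms.
#' @param topography realized per-channel effect weights (ground truth from
#'   \code{\link{generateSubject}}); default: all 1.
#' @param subjectAmp realized subject effect amplitude; default
#'   \code{cfg@effect$amplitude}.
#' @param nSamplesRec recording length in samples (ground truth); default:
#'   estimated from the event design.
#' @param poolSize trials available per condition (finite-pool correction);
#'   NULL/Inf for the classic iid power.
#' @param d optional vector of standardized effect sizes; bypasses the
#'   generative model and returns mean power at those d (useful as a plain
#'   noncentral-t power calculator).
#' @return expected percentage of significant channels in [0, 100].
#' @examples
#' expectedMetric(d = 0)              # 5 (level)
#' expectedMetric(d = 1)              # power at d = 1, n = 50/group
#' @export
expectedMetric <- function(cfg = NULL, nResample = 50, alpha = 0.05,
                           window = NULL, topography = NULL,
                           subjectAmp = NULL, nSamplesRec = NULL,
                           poolSize = NULL, d = NULL) {
  m <- as.integer(nResample)
  if (m < 2L) stop("nResample must be >= 2")
  pool <- if (is.null(poolSize)) Inf else poolSize
  if (!is.null(d)) {
    # d is standardized by the per-group SD, so unit variances per group
    pw <- .resampledPower(abs(d), 1, 1, m, pool, alpha)
    return(100 * mean(pw))
  }
  stopifnot(is(cfg, "SyntheticConfig"))
  if (cfg@noise$rms <= 0) stop("noise rms must be positive")
  if (cfg@artifacts$rate > 0 && cfg@artifacts$amplitude > 0)
    stop("the oracle covers the clean regime only (artifacts present)")
  eff <- cfg@effect
  if (is.null(window)) window <- c(eff$latency - 0.05, eff$latency + 0.05)
  if (is.null(topography)) topography <- rep(1, cfg@nChannels)
  if (is.null(subjectAmp)) subjectAmp <- eff$amplitude
  if (is.null(nSamplesRec))
    nSamplesRec <- stats::nextn(
      as.integer(ceiling((2 * cfg@nTrials * 2.0 + 6) * cfg@srate)), c(2, 3, 5))

  k <- .gridWindow(window, cfg@srate)
  mWin <- length(k)
  bumpMean <- mean(exp(-(k / cfg@srate - eff$latency)^2 / (2 * eff$width^2)))

  r <- .noiseAutocov(cfg, nSamplesRec)
  s2w <- .windowMeanCov(r, mWin, 0L, nSamplesRec)
  # mean pairwise covariance between trials (events ~2 s apart)
  N <- 2L * cfg@nTrials
  lagStep <- round(mean(.isiRange) * cfg@srate)
  dSep <- seq_len(N - 1L)
  covs <- vapply(dSep, function(dd)
    .windowMeanCov(r, mWin, dd * lagStep, nSamplesRec), numeric(1))
  cbar <- 2 * sum((N - dSep) * covs) / (N * (N - 1))
  s2eff <- max(s2w - cbar, 1e-12)

  delta <- abs(subjectAmp * topography * bumpMean)
  jitterVar <- diff(.jitterRange)^2 / 12
  varA <- rep(s2eff, length(delta))
  varB <- s2eff + delta^2 * jitterVar
  pw <- .resampledPower(delta, varA, varB, m, pool, alpha)
  100 * mean(pw)
}
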