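## Core statistic: percentage of channels with a significant between-condition
## difference of window-averaged potentials, averaged over trial resamples.

# Half-open window selection on the epoch time axis: [start, end).
.windowIndex <- function(times, window) {
  if (length(window) != 2L || window[1] >= window[2])
    stop("window must be (start, end) with start < end")
  sel <- which(times >= window[1] - 1e-9 & times < window[2] - 1e-9)
  if (!length(sel))
    stop(sprintf("window [%g, %g) contains no epoch samples", window[1], window[2]))
  sel
}

# channels x trials matrix of per-trial mean potential over the window
.windowMeans <- function(ep, window) {
  sel <- .windowIndex(ep@times, window)
  d <- ep@data[, sel, , drop = FALSE]
  colMeans(aperm(d, c(2, 1, 3)))  # average over time -> channels x trials
}

.checkCompatible <- function(a, b) {
  if (!identical(a@channelLabels, b@channelLabels))
    stop("mismatched channels between the two conditions")
  if (length(a@times) != length(b@times) ||
      max(abs(a@times - b@times)) > 1e-9)
    stop("mismatched epoch time axes between the two conditions")
  if (a@srate != b@srate)
    stop("mismatched sampling rates between the two conditions")
  invisible(TRUE)
}

# Elementwise two-sample t-test significance on summary matrices.
# Degenerate cells (zero variance in both groups): equal means -> t = 0,
# non-significant; unequal means -> significant (limiting behaviour).
.tTestSig <- function(meanA, varA, mA, meanB, varB, mB, alpha,
                      varEqual = TRUE) {
  num <- meanA - meanB
  if (varEqual) {
    sp2 <- ((mA - 1) * varA + (mB - 1) * varB) / (mA + mB - 2)
    se2 <- sp2 * (1 / mA + 1 / mB)
    df <- mA + mB - 2
  } else {
    va <- varA / mA
    vb <- varB / mB
    se2 <- va + vb
    df <- se2^2 / (va^2 / (mA - 1) + vb^2 / (mB - 1))
  }
  sig <- array(FALSE, dim = if (is.null(dim(num))) length(num) else dim(num))
  pos <- se2 > 0
  if (any(pos)) {
    dfp <- if (length(df) == 1L) df else df[pos]
    p <- 2 * stats::pt(-abs(num[pos] / sqrt(se2[pos])), dfp)
    sig[pos] <- p < alpha
  }
  deg <- !pos
  if (any(deg)) sig[deg] <- abs(num[deg]) > 0
  sig
}

#' Percentage of significant channels between two conditions
#'
#' For each channel, each trial's potential is averaged over the analysis
#' window; the two sets of per-trial means are compared with a two-sided
#' unpaired t-test (pooled variance by default) and the channel is counted
#' significant when p < alpha. Returns 100 x (significant channels) /
#' (channels). A channel with zero variance in both groups is significant
#' only if the group means differ (t = 0 convention otherwise).
#'
#' @param a,b \linkS4class{EpochSet}s sharing channels, time axis and
#'   sampling rate; each with at least 2 trials.
#' @param window (start, end) in seconds; samples in the half-open interval
#'   are averaged.
#' @param alpha two-sided test level (default 0.05).
#' @param varEqual TRUE for the pooled-variance Student test (default),
#'   FALSE for Welch.
#' @return percentage in [0, 100].
#' @examples
#' ep <- EpochSet(array(rnorm(4 * 10 * 20), c(4, 10, 20)),
#'                times = (0:9) / 100, srate = 100, condition = "A")
#' channelSignificance(ep, ep, window = c(0, 0.1))  # identical data: 0
#' @export
channelSignificance <- function(a, b, window, alpha = 0.05, varEqual = TRUE) {
  .checkCompatible(a, b)
  if (dim(a@data)[3] < 2L || dim(b@data)[3] < 2L)
    stop("each condition needs at least 2 trials")
  Wa <- .windowMeans(a, window)
  Wb <- .windowMeans(b, window)
  mA <- ncol(Wa)
  mB <- ncol(Wb)
  ma <- rowMeans(Wa)
  mb <- rowMeans(Wb)
  va <- rowSums((Wa - ma)^2) / (mA - 1)
  vb <- rowSums((Wb - mb)^2) / (mB - 1)
  sig <- .tTestSig(ma, va, mA, mb, vb, mB, alpha, varEqual)
  100 * mean(sig)
}

# Draw index matrix (m x nBoot). With replacement: one sample.int call whose
# draw order defines the reproducibility contract (condition A's indices are
# drawn before condition B's within each call sequence). Without replacement:
# one subsample per repetition.
.drawIndices <- function(n, m, nBoot, replace) {
  if (replace) {
    matrix(sample.int(n, m * nBoot, replace = TRUE), m, nBoot)
  } else {
    if (m > n) stop("cannot subsample more trials than available without replacement")
    vapply(seq_len(nBoot), function(i) sample.int(n, m), integer(m))
  }
}

# Multiplicity counts (n x nBoot) of an index matrix.
.indexCounts <- function(idx, n) {
  nBoot <- ncol(idx)
  off <- rep.int(0:(nBoot - 1L), rep.int(nrow(idx), nBoot)) * n
  matrix(tabulate(as.vector(idx) + off, nbins = n * nBoot), n, nBoot)
}

# Bootstrap engine: per repetition draw mA/mB trials per condition, run the
# per-channel t-test on window means, average the percentage of significant
# channels over repetitions. Uses weighted sums (W %*% counts), so cost is
# one matrix product per chunk rather than nBoot subset operations.
.bootstrapMetric <- function(Wa, Wb, mA, mB, cfg) {
  nA <- ncol(Wa)
  nB <- ncol(Wb)
  ctr <- rowMeans(cbind(Wa, Wb))  # center for numerical stability
  Wa <- Wa - ctr
  Wb <- Wb - ctr
  Wa2 <- Wa^2
  Wb2 <- Wb^2
  nBoot <- cfg@nBoot
  chunk <- max(64L, min(nBoot, as.integer(4e6 %/% max(nA + nB, 1L))))
  pct <- numeric(nBoot)
  done <- 0L
  while (done < nBoot) {
    b <- min(chunk, nBoot - done)
    ia <- .drawIndices(nA, mA, b, cfg@replace)
    ib <- .drawIndices(nB, mB, b, cfg@replace)
    Ca <- .indexCounts(ia, nA)
    Cb <- .indexCounts(ib, nB)
    Sa <- Wa %*% Ca
    Sb <- Wb %*% Cb
    meanA <- Sa / mA
    meanB <- Sb / mB
    varA <- pmax((Wa2 %*% Ca) - Sa^2 / mA, 0) / (mA - 1)
    varB <- pmax((Wb2 %*% Cb) - Sb^2 / mB, 0) / (mB - 1)
    sig <- .tTestSig(meanA, varA, mA, meanB, varB, mB, cfg@alpha,
                     cfg@varEqual)
    pct[done + seq_len(b)] <- 100 * colMeans(sig)
    done <- done + b
  }
  list(mean = mean(pct),
       mcse = stats::sd(pct) / sqrt(nBoot))
}

.metricImpl <- function(a, b, cfg, mode, seed) {
  .checkCompatible(a, b)
  if (length(cfg@window) != 2L)
    stop("cfg must carry an analysis window (start, end)")
  nA <- dim(a@data)[3]
  nB <- dim(b@data)[3]
  if (mode == "resample_50") {
    mA <- mB <- cfg@nResample
  } else {
    mA <- nA
    mB <- nB
  }
  if (mA < 2L || mB < 2L)
    stop("resample size must be >= 2 (t-test undefined)")
  Wa <- .windowMeans(a, cfg@window)
  Wb <- .windowMeans(b, cfg@window)
  set.seed(seed)
  res <- .bootstrapMetric(Wa, Wb, mA, mB, cfg)
  out <- new("MetricResult", subjectId = a@subjectId,
             meanPctSignificant = res$mean,
             nChannels = nrow(Wa), nTrialsUsed = c(nA, nB),
             mode = mode, config = cfg)
  attr(out, "mcse") <- res$mcse
  out
}

#' Resampled data-quality metric for one subject
#'
#' The core statistic: in each of \code{nBoot} repetitions, draw
#' \code{nResample} trials (with replacement by default) independently from
#' each condition, compute the percentage of channels with a significant
#' between-condition difference of window-averaged potentials
#' (\code{\link{channelSignificance}}), and average over repetitions. The
#' result is deterministic given \code{cfg@seed}; the returned object
#' carries the Monte-Carlo standard error as attribute \code{mcse}.
#'
#' @param a,b \linkS4class{EpochSet}s of the two conditions for one subject.
#' @param cfg a \linkS4class{MetricConfig} with the analysis window set.
#' @return a \linkS4class{MetricResult} with mode \code{"resample_50"}.
#' @examples
#' set.seed(1)
#' mk <- function(shift) EpochSet(
#'   array(rnorm(8 * 25 * 60) + shift, c(8, 25, 60)),
#'   times = (0:24) / 250, srate = 250, condition = if (shift > 0) "B" else "A")
#' r <- resampledMetric(mk(0), mk(0.8), metricConfig(window = c(0, 0.1),
#'                                                   nBoot = 200, seed = 2))
#' metricValue(r)
#' @export
resampledMetric <- function(a, b, cfg = metricConfig()) {
  .metricImpl(a, b, cfg, "resample_50", cfg@seed)
}

#' All-remaining-trials variant of the metric
#'
#' Identical to \code{\link{resampledMetric}} except each repetition draws
#' as many trials as each condition still has (nA from a, nB from b, with
#' replacement). Used to judge trial-rejection methods, where the surviving
#' trial count itself carries the cost of rejection.
#'
#' @inheritParams resampledMetric
#' @return a \linkS4class{MetricResult} with mode \code{"all_trials"}.
#' @export
allTrialsMetric <- function(a, b, cfg = metricConfig()) {
  .metricImpl(a, b, cfg, "all_trials", cfg@seed)
}

#' Per-subject metrics over a cohort
#'
#' Applies \code{\link{resampledMetric}} (or \code{\link{allTrialsMetric}})
#' to each subject's condition pair. Subject i uses its own RNG stream
#' seeded as \code{cfg@seed + i}, so per-subject results do not depend on
#' cohort order.
#'
#' @param pairs list of per-subject lists with elements \code{a} and
#'   \code{b} (\linkS4class{EpochSet}s).
#' @param cfg a \linkS4class{MetricConfig} with the analysis window set.
#' @param mode "resample" (default) or "all_trials".
#' @return list of \linkS4class{MetricResult}, one per subject; extract the
#'   values with \code{\link{metricValues}}.
#' @export
cohortMetric <- function(pairs, cfg = metricConfig(),
                         mode = c("resample", "all_trials")) {
  mode <- match.arg(mode)
  mode <- if (mode == "resample") "resample_50" else "all_trials"
  lapply(seq_along(pairs), function(i)
    .metricImpl(pairs[[i]]$a, pairs[[i]]$b, cfg, mode, cfg@seed + i))
}
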