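## Latency scan and maximum-effect window selection.

# Unscaled median absolute deviation (descriptive spread of the curves).
.unscaledMad <- function(v) stats::median(abs(v - stats::median(v)))

.scanBins <- function(times, srate, step, width) {
  t0 <- times[1]
  tEnd <- times[length(times)] + 1 / srate
  starts <- c()
  s <- t0
  while (s + width <= tEnd + 1e-9) {
    starts <- c(starts, s)
    s <- s + step
  }
  if (!length(starts)) stop("epoch too short for a single scan bin")
  starts
}

#' Significance curve across latencies for a cohort
#'
#' For every latency bin (width \code{cfg@scanWindow}, stepped by
#' \code{cfg@scanStep} across the epoch, half-open), computes each subject's
#' resampled metric using the bin as the averaging window, then summarises
#' across subjects with the median and the unscaled median absolute
#' deviation. Intended for long epochs (e.g. -1 to 2 s) so the scan covers
#' pre- and post-stimulus latencies; with the 50-ms defaults a (-1, 2) s
#' epoch yields 60 bins. Subject i uses RNG stream \code{cfg@seed + i}.
#'
#' @param pairs list of per-subject lists with elements \code{a}, \code{b}
#'   (\linkS4class{EpochSet}s sharing srate and epoch window across
#'   subjects).
#' @param cfg a \linkS4class{MetricConfig}; its \code{window} slot is
#'   ignored (each bin is the window).
#' @return a \linkS4class{SignificanceCurve}; latencies are bin centers.
#' @seealso \code{\link{findEffectWindow}}
#' @export
latencyScan <- function(pairs, cfg = metricConfig()) {
  stopifnot(length(pairs) >= 1L)
  ref <- pairs[[1]]$a
  for (p in pairs) {
    .checkCompatible(p$a, p$b)
    if (p$a@srate != ref@srate ||
        length(p$a@times) != length(ref@times) ||
        max(abs(p$a@times - ref@times)) > 1e-9)
      stop("all subjects must share the sampling rate and epoch window")
  }
  starts <- .scanBins(ref@times, ref@srate, cfg@scanStep, cfg@scanWindow)
  nBins <- length(starts)
  perSubject <- matrix(0, length(pairs), nBins)
  ids <- character(length(pairs))
  for (i in seq_along(pairs)) {
    a <- pairs[[i]]$a
    b <- pairs[[i]]$b
    ids[i] <- a@subjectId
    m <- cfg@nResample
    set.seed(cfg@seed + i)
    for (k in seq_len(nBins)) {
      win <- c(starts[k], starts[k] + cfg@scanWindow)
      Wa <- .windowMeans(a, win)
      Wb <- .windowMeans(b, win)
      perSubject[i, k] <- .bootstrapMetric(Wa, Wb, m, m, cfg)$mean
    }
  }
  med <- apply(perSubject, 2, stats::median)
  madU <- apply(perSubject, 2, .unscaledMad)
  rownames(perSubject) <- ids
  new("SignificanceCurve", latencies = starts + cfg@scanWindow / 2,
      perSubject = perSubject, median = med, mad = madU, subjectIds = ids)
}

#' Select the 100-ms window of maximum effect
#'
#' Smooths the median significance curve with a centered moving average
#' (length \code{smoothLen}; truncated at the edges) and takes the latency
#' of the maximum (earliest on ties) as the window center; the window is
#' that latency plus and minus 50 ms, clipped to the epoch range with a
#' warning if necessary.
#'
#' @param curve a \linkS4class{SignificanceCurve}, or a numeric median curve
#'   (in which case \code{latencies} must be given).
#' @param smoothLen odd moving-average length (default 3).
#' @param latencies latencies in seconds when \code{curve} is numeric.
#' @param epochRange optional (min, max) seconds used for clipping; defaults
#'   to the latency range.
#' @return an \linkS4class{EffectWindow}.
#' @examples
#' w <- findEffectWindow(c(0, 10, 50, 10, 0), latencies = seq(0, 0.2, 0.05))
#' windowCenter(w)  # 0.1
#' @export
findEffectWindow <- function(curve, smoothLen = 3, latencies = NULL,
                             epochRange = NULL) {
  if (is(curve, "SignificanceCurve")) {
    x <- curve@median
    latencies <- curve@latencies
  } else {
    x <- as.numeric(curve)
    if (is.null(latencies) || length(latencies) != length(x))
      stop("latencies must accompany a numeric curve")
  }
  if (!length(x)) stop("empty significance curve")
  smoothLen <- as.integer(smoothLen)
  if (smoothLen < 1L || smoothLen %% 2L == 0L)
    stop("smoothLen must be odd and >= 1")
  h <- (smoothLen - 1L) %/% 2L
  n <- length(x)
  sm <- vapply(seq_len(n), function(i)
    mean(x[max(1L, i - h):min(n, i + h)]), numeric(1))
  center <- latencies[which.max(sm)]  # which.max: earliest on ties
  if (is.null(epochRange)) epochRange <- range(latencies)
  start <- center - 0.050
  end <- center + 0.050
  if (start < epochRange[1] - 1e-9 || end > epochRange[2] + 1e-9) {
    warning("effect window clipped at the epoch edge")
    start <- max(start, epochRange[1])
    end <- min(end, epochRange[2])
  }
  new("EffectWindow", center = center, start = start, end = end)
}
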