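## Minimal preprocessing operators evaluated against the quality metric.

#' High-pass filter specification
#'
#' @slot kind "butterworth" (default, order 4 per pass) or "fir_sinc"
#'   (Hamming-windowed sinc).
#' @slot cutoffHz high-pass edge in Hz.
#' @slot order per-pass IIR order (Butterworth default 4).
#' @slot twoPass TRUE (default) applies the filter forward and backward
#'   (zero phase); FALSE applies a single causal pass (FIR filters are
#'   delay-compensated).
#' @slot firTransitionHz transition bandwidth of the windowed-sinc design;
#'   NA chooses max(cutoff, 1) Hz.
#' @exportClass FilterSpec
setClass("FilterSpec",
  representation(kind = "character", cutoffHz = "numeric", order = "integer",
                 twoPass = "logical", firTransitionHz = "numeric"),
  prototype(kind = "butterworth", cutoffHz = 0.5, order = 4L, twoPass = TRUE,
            firTransitionHz = NA_real_)
)

setValidity("FilterSpec", function(object) {
  msg <- NULL
  if (!object@kind %in% c("butterworth", "fir_sinc"))
    msg <- c(msg, "kind must be 'butterworth' or 'fir_sinc'")
  if (object@cutoffHz <= 0)
    msg <- c(msg, "cutoffHz must be positive")
  if (object@order < 1L)
    msg <- c(msg, "order must be >= 1")
  if (is.null(msg)) TRUE else msg
})

#' Construct a FilterSpec
#'
#' @param kind,cutoffHz,order,twoPass,firTransitionHz see
#'   \linkS4class{FilterSpec}.
#' @return a \linkS4class{FilterSpec}.
#' @examples
#' filterSpec("butterworth", cutoffHz = 0.5)
#' @export
filterSpec <- function(kind = c("butterworth", "fir_sinc"), cutoffHz = 0.5,
                       order = 4, twoPass = TRUE, firTransitionHz = NA) {
  new("FilterSpec", kind = match.arg(kind), cutoffHz = cutoffHz,
      order = as.integer(order), twoPass = twoPass,
      firTransitionHz = as.numeric(firTransitionHz))
}

# Hamming-window FIR length for a given transition bandwidth (normalized).
.firOrder <- function(transitionHz, srate) {
  ord <- ceiling(3.3 * srate / transitionHz)
  ord + ord %% 2L  # even order -> odd length, type-I linear phase
}

# Single-pass zero-phase FIR: filter then remove the (order/2) group delay.
.firCompensated <- function(b, x) {
  gd <- (length(b) - 1L) %/% 2L
  y <- signal::filter(b, 1, c(x, numeric(gd)))
  as.numeric(y)[(gd + 1L):(gd + length(x))]
}

.applyRows <- function(data, f) {
  out <- data
  for (i in seq_len(nrow(data))) out[i, ] <- f(data[i, ])
  out
}

#' High-pass filter a continuous recording
#'
#' Removes slow drifts below the cutoff. Filtering is applied to continuous
#' data (before epoching) and is zero-phase by default: the Butterworth
#' design is run forward and backward (so the stated order is per pass and
#' the -3 dB attenuation at the cutoff doubles), the windowed-sinc FIR is
#' either run twice or applied once with its linear-phase delay compensated.
#'
#' @param rec a \linkS4class{ContinuousRecording}.
#' @param spec a \linkS4class{FilterSpec}; numeric input is interpreted as a
#'   Butterworth cutoff in Hz.
#' @return the filtered \linkS4class{ContinuousRecording}.
#' @examples
#' rec <- ContinuousRecording(matrix(100, 2, 5000), srate = 250)
#' hp <- highpassFilter(rec, 0.5)   # DC is removed
#' @export
highpassFilter <- function(rec, spec = filterSpec()) {
  stopifnot(is(rec, "ContinuousRecording"))
  if (is.numeric(spec)) spec <- filterSpec("butterworth", cutoffHz = spec)
  ny <- rec@srate / 2
  if (spec@cutoffHz >= ny)
    stop("cutoff must be below the Nyquist frequency")
  if (spec@kind == "butterworth") {
    flt <- signal::butter(spec@order, spec@cutoffHz / ny, type = "high")
    f <- if (spec@twoPass) {
      function(x) as.numeric(signal::filtfilt(flt, x))
    } else {
      function(x) as.numeric(signal::filter(flt, x))
    }
  } else {
    trans <- spec@firTransitionHz
    # default transition min(cutoff, 1 Hz): keeps DC strictly inside the
    # stopband (a wider band centered on a low cutoff would leave DC at the
    # transition edge with only ~25 dB attenuation)
    if (!is.finite(trans)) trans <- min(spec@cutoffHz, 1)
    ord <- .firOrder(trans, rec@srate)
    # plain numeric coefficients (the classed return would mis-dispatch in
    # the three-argument filtfilt call)
    b <- as.numeric(signal::fir1(ord, spec@cutoffHz / ny, type = "high",
                                 window = signal::hamming(ord + 1)))
    f <- if (spec@twoPass) {
      function(x) as.numeric(signal::filtfilt(b, 1, x))
    } else {
      function(x) .firCompensated(b, x)
    }
  }
  initialize(rec, data = .applyRows(rec@data, f))
}

#' Notch (band-stop) filter for line noise
#'
#' Suppresses the mains frequency with a band-stop filter, by default an
#' FIR design with passband edges 48 and 52 Hz (2-Hz transition), applied
#' zero-phase. A 50-Hz component is attenuated by well over 20 dB while a
#' 10-Hz component passes within 5\%.
#'
#' @param rec a \linkS4class{ContinuousRecording}.
#' @param band (low, high) passband edges in Hz (default c(48, 52)).
#' @param kind "fir" (Hamming-window band-stop, default) or "iir"
#'   (Butterworth band-stop, order 2 per pass).
#' @return the filtered \linkS4class{ContinuousRecording}.
#' @export
notchFilter <- function(rec, band = c(48, 52), kind = c("fir", "iir")) {
  stopifnot(is(rec, "ContinuousRecording"))
  kind <- match.arg(kind)
  ny <- rec@srate / 2
  if (length(band) != 2L || band[1] <= 0 || band[2] >= ny || band[1] >= band[2])
    stop("band must be inside (0, Nyquist) with low < high")
  if (kind == "fir") {
    ord <- .firOrder(2, rec@srate)
    b <- as.numeric(signal::fir1(ord, band / ny, type = "stop",
                                 window = signal::hamming(ord + 1)))
    f <- function(x) as.numeric(signal::filtfilt(b, 1, x))
  } else {
    flt <- signal::butter(2, band / ny, type = "stop")
    f <- function(x) as.numeric(signal::filtfilt(flt, x))
  }
  initialize(rec, data = .applyRows(rec@data, f))
}

.rereferenceMatrix <- function(data, scheme, labels) {
  if (identical(scheme, "none")) return(data)
  if (identical(scheme, "average")) {
    ref <- colMeans(data)
  } else if (identical(scheme, "median")) {
    ref <- apply(data, 2, stats::median)
  } else {
    idx <- match(scheme, labels)
    if (anyNA(idx))
      stop(sprintf("unknown channel label(s): %s",
                   paste(scheme[is.na(idx)], collapse = ", ")))
    ref <- colMeans(data[idx, , drop = FALSE])
  }
  sweep(data, 2, ref)
}

#' @describeIn rereference continuous recording
#' @export
setMethod("rereference", "ContinuousRecording", function(x, scheme = "average") {
  initialize(x, data = .rereferenceMatrix(x@data, scheme, x@channelLabels))
})

#' @describeIn rereference epoch set (per sample, per trial)
#' @export
setMethod("rereference", "EpochSet", function(x, scheme = "average") {
  d <- dim(x@data)
  flat <- matrix(x@data, d[1], d[2] * d[3])
  out <- .rereferenceMatrix(flat, scheme, x@channelLabels)
  initialize(x, data = array(out, d))
})

#' Subtract a pre-stimulus baseline from each epoch
#'
#' Per channel and trial, the mean over the baseline interval (half-open
#' [start, end), end at or before stimulus onset) is subtracted from the
#' whole epoch.
#'
#' @param ep an \linkS4class{EpochSet}.
#' @param interval (start, end) seconds, pre-stimulus (end <= 0), inside the
#'   epoch.
#' @return the baseline-corrected \linkS4class{EpochSet}.
#' @examples
#' ep <- EpochSet(array(c(2, 2, 4, 6), c(1, 4, 1)), times = (-2:1) / 100,
#'                srate = 100)
#' recordingData(baselineSubtract(ep, c(-0.02, 0)))[1, , 1]  # 0 0 2 4
#' @export
baselineSubtract <- function(ep, interval = c(-0.2, 0)) {
  stopifnot(is(ep, "EpochSet"))
  if (interval[2] > 1e-9)
    stop("baseline interval must be pre-stimulus (end <= 0)")
  if (interval[1] < ep@times[1] - 1e-9)
    stop("baseline interval lies outside the epoch")
  base <- .windowMeans(ep, interval)  # channels x trials
  d <- dim(ep@data)
  # subtract each channel x trial baseline mean from every timepoint
  out <- ep@data - aperm(array(base, c(d[1], d[3], d[2])), c(1, 3, 2))
  initialize(ep, data = out)
}

# Welch-style averaged periodogram: 1-s Hann segments, 50% overlap.
.welchPsd <- function(x, srate) {
  L <- max(8L, round(srate))
  if (length(x) < L) L <- length(x)
  step <- max(1L, L %/% 2L)
  starts <- seq(1L, length(x) - L + 1L, by = step)
  w <- 0.5 - 0.5 * cos(2 * pi * seq_len(L) / (L + 1))  # Hann taper
  acc <- numeric(L %/% 2L + 1L)
  for (s in starts) {
    seg <- x[s:(s + L - 1L)] * w
    P <- abs(stats::fft(seg))^2 / (sum(w^2) * srate)
    acc <- acc + P[seq_len(L %/% 2L + 1L)]
  }
  list(freq = (0:(L %/% 2L)) * srate / L, psd = acc / length(starts))
}

#' Detect channels with excessive line noise
#'
#' Estimates each channel's narrowband power at the mains frequency
#' (+/- 1 Hz, Welch-style averaged periodogram: 1-s Hann segments, 50\%
#' overlap), converts log-power to a robust z-score against the other
#' channels (median and 1.4826 x MAD), and flags channels whose z exceeds
#' the threshold (default 4 standard deviations).
#'
#' @param rec a \linkS4class{ContinuousRecording} with at least 4 channels.
#' @param lineHz mains frequency (default 50).
#' @param sdThreshold robust z-score threshold (default 4).
#' @return integer indices of the flagged channels (possibly empty), with
#'   the z-scores as attribute \code{z}.
#' @export
detectLineNoiseChannels <- function(rec, lineHz = 50, sdThreshold = 4) {
  stopifnot(is(rec, "ContinuousRecording"))
  if (nrow(rec@data) < 4L)
    stop("at least 4 channels are required")
  if (lineHz >= rec@srate / 2)
    stop("line frequency must be below Nyquist")
  p <- vapply(seq_len(nrow(rec@data)), function(i) {
    w <- .welchPsd(rec@data[i, ], rec@srate)
    sel <- w$freq >= lineHz - 1 & w$freq <= lineHz + 1
    mean(w$psd[sel])
  }, numeric(1))
  lp <- log10(p + .Machine$double.xmin)
  med <- stats::median(lp)
  madv <- 1.4826 * stats::median(abs(lp - med))
  z <- if (madv > 0) (lp - med) / madv else ifelse(lp > med, Inf, 0)
  out <- which(z > sdThreshold)
  attr(out, "z") <- z
  out
}

#' Reject trials by amplitude threshold
#'
#' Drops trials whose amplitude exceeds a microvolt threshold on any
#' channel. Mode "abs" (default) rejects when any sample magnitude exceeds
#' the threshold (a -T..+T range criterion); mode "ptp" rejects when any
#' channel's peak-to-peak range (max - min within the epoch) exceeds it.
#'
#' @param ep an \linkS4class{EpochSet}.
#' @param thresholdUv positive threshold in microvolts (default 200).
#' @param mode "abs" or "ptp".
#' @return list with \code{epochs} (surviving \linkS4class{EpochSet}, NULL
#'   when every trial is rejected), \code{rejectedFraction}, and
#'   \code{rejected} (trial indices).
#' @examples
#' dat <- array(rnorm(2 * 10 * 5), c(2, 10, 5)); dat[1, 4, 3] <- 300
#' rejectTrialsPeakToPeak(EpochSet(dat, times = (0:9) / 100, srate = 100)
#'   )$rejectedFraction  # 0.2
#' @export
rejectTrialsPeakToPeak <- function(ep, thresholdUv = 200,
                                   mode = c("abs", "ptp")) {
  stopifnot(is(ep, "EpochSet"))
  mode <- match.arg(mode)
  if (thresholdUv <= 0) stop("threshold must be positive")
  nt <- dim(ep@data)[3]
  bad <- vapply(seq_len(nt), function(t) {
    tr <- ep@data[, , t, drop = FALSE]
    if (mode == "abs") {
      max(abs(tr)) > thresholdUv
    } else {
      dim(tr) <- dim(tr)[1:2]
      any(apply(tr, 1, function(ch) max(ch) - min(ch)) > thresholdUv)
    }
  }, logical(1))
  keep <- which(!bad)
  epochs <- if (length(keep))
    initialize(ep, data = ep@data[, , keep, drop = FALSE]) else NULL
  list(epochs = epochs, rejectedFraction = mean(bad), rejected = which(bad))
}
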