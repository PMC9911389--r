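#' @import methods
NULL

.checkFinite <- function(x, what) {
  if (anyNA(x) || any(is.infinite(x)))
    return(sprintf("%s contains NA/NaN/Inf values", what))
  NULL
}

.checkPositions <- function(pos, nChannels) {
  msg <- NULL
  if (nrow(pos) == 0L) return(msg)
  if (nrow(pos) != nChannels)
    msg <- c(msg, "channelPositions must have one row per channel")
  if (ncol(pos) != 3L)
    msg <- c(msg, "channelPositions must have 3 columns (x, y, z)")
  if (nrow(pos) == nChannels && ncol(pos) == 3L) {
    norms <- sqrt(rowSums(pos^2))
    if (any(abs(norms - 1) > 1e-6))
      msg <- c(msg, "channelPositions must lie on the unit sphere (|norm - 1| <= 1e-6)")
  }
  msg
}

#' Continuous multichannel EEG recording
#'
#' Holds one subject's continuous EEG as a channels x samples matrix in
#' microvolts, together with the sampling rate, channel labels, optional
#' unit-sphere electrode positions (required for spherical-spline
#' interpolation) and a subject identifier.
#'
#' @slot data numeric matrix, channels x samples, in microvolts.
#' @slot srate sampling rate in Hz.
#' @slot channelLabels character vector, one label per row of \code{data}.
#' @slot channelPositions numeric matrix, channels x 3, unit-norm electrode
#'   coordinates; a 0-row matrix means positions are unavailable.
#' @slot subjectId subject identifier.
#' @exportClass ContinuousRecording
setClass("ContinuousRecording",
  representation(
    data = "matrix",
    srate = "numeric",
    channelLabels = "character",
    channelPositions = "matrix",
    subjectId = "character"
  ),
  prototype(
    data = matrix(numeric(0), 0, 0),
    srate = 250,
    channelLabels = character(0),
    channelPositions = matrix(numeric(0), 0, 3),
    subjectId = "subject"
  )
)

setValidity("ContinuousRecording", function(object) {
  msg <- NULL
  if (length(object@srate) != 1L || !is.finite(object@srate) || object@srate <= 0)
    msg <- c(msg, "srate must be a single positive number")
  if (nrow(object@data) != length(object@channelLabels))
    msg <- c(msg, "data must have one row per channel label")
  msg <- c(msg, .checkFinite(object@data, "data"))
  msg <- c(msg, .checkPositions(object@channelPositions, nrow(object@data)))
  if (length(object@subjectId) != 1L)
    msg <- c(msg, "subjectId must be a single string")
  if (is.null(msg)) TRUE else msg
})

#' Event marker table
#'
#' Stimulus/event markers for a continuous recording: 0-based sample indices
#' and a condition label per event. Onsets must be strictly increasing;
#' whether each onset fits inside a recording is checked at epoch-extraction
#' time.
#'
#' @slot onsets integer vector of 0-based sample indices, strictly increasing.
#' @slot labels character vector of condition labels, one per event.
#' @exportClass EventTable
setClass("EventTable",
  representation(onsets = "integer", labels = "character"),
  prototype(onsets = integer(0), labels = character(0))
)

setValidity("EventTable", function(object) {
  msg <- NULL
  if (length(object@onsets) != length(object@labels))
    msg <- c(msg, "onsets and labels must have the same length")
  if (anyNA(object@onsets) || any(object@onsets < 0L))
    msg <- c(msg, "onsets must be non-negative sample indices")
  if (length(object@onsets) > 1L && any(diff(object@onsets) <= 0L))
    msg <- c(msg, "onsets must be strictly increasing")
  if (is.null(msg)) TRUE else msg
})

#' Epoched EEG for one subject and condition
#'
#' A channels x timepoints x trials array of event-locked EEG segments
#' (microvolts) with a time axis in seconds relative to event onset.
#'
#' @slot data numeric array, channels x timepoints x trials.
#' @slot times numeric vector of seconds relative to the event, uniformly
#'   spaced at 1/srate.
#' @slot srate sampling rate in Hz.
#' @slot condition condition label (non-empty).
#' @slot subjectId subject identifier.
#' @slot channelLabels,channelPositions as in
#'   \linkS4class{ContinuousRecording}.
#' @exportClass EpochSet
setClass("EpochSet",
  representation(
    data = "array",
    times = "numeric",
    srate = "numeric",
    condition = "character",
    subjectId = "character",
    channelLabels = "character",
    channelPositions = "matrix"
  ),
  prototype(
    data = array(numeric(0), c(0, 0, 0)),
    times = numeric(0),
    srate = 250,
    condition = "condition",
    subjectId = "subject",
    channelLabels = character(0),
    channelPositions = matrix(numeric(0), 0, 3)
  )
)

setValidity("EpochSet", function(object) {
  msg <- NULL
  d <- dim(object@data)
  if (length(d) != 3L)
    msg <- c(msg, "data must be a 3-d array (channels x timepoints x trials)")
  else {
    if (d[2] != length(object@times))
      msg <- c(msg, "length(times) must equal the number of timepoints")
    if (d[1] != length(object@channelLabels))
      msg <- c(msg, "data must have one channel per channel label")
    if (d[3] < 1L)
      msg <- c(msg, "at least one trial is required")
    msg <- c(msg, .checkPositions(object@channelPositions, d[1]))
  }
  if (length(object@srate) != 1L || !is.finite(object@srate) || object@srate <= 0)
    msg <- c(msg, "srate must be a single positive number")
  if (length(object@times) > 1L) {
    dt <- diff(object@times)
    if (any(abs(dt - 1 / object@srate) > 1e-9))
      msg <- c(msg, "times must be uniformly spaced at 1/srate (tolerance 1e-9)")
  }
  if (length(object@condition) != 1L || !nzchar(object@condition))
    msg <- c(msg, "condition must be a single non-empty string")
  msg <- c(msg, .checkFinite(object@data, "data"))
  if (is.null(msg)) TRUE else msg
})

#' Configuration of the resampled significance metric
#'
#' All constants of the data-quality statistic: the per-channel test level,
#' the number of trials drawn per condition in each resample, the number of
#' bootstrap repetitions, the averaging window, the latency-scan geometry and
#' the median-curve smoother length.
#'
#' @slot alpha per-channel two-sided test level (default 0.05).
#' @slot nResample trials drawn with replacement per condition per repetition
#'   (default 50).
#' @slot nBoot number of bootstrap repetitions (default 20000).
#' @slot window numeric length-2 (start, end) averaging window in seconds, or
#'   \code{numeric(0)} when unset (the latency scan sets its own bins).
#' @slot scanStep latency-scan step in seconds (default 0.050).
#' @slot scanWindow latency-scan bin width in seconds (default 0.050).
#' @slot smoothLen moving-average length for the median curve (odd, default 3).
#' @slot varEqual logical; TRUE (default) uses the pooled-variance Student
#'   t-test, FALSE the Welch variant.
#' @slot replace logical; TRUE (default) draws trials with replacement (the
#'   reference procedure). FALSE subsamples without replacement, a variant
#'   whose null expectation is exactly 100*alpha (see the vignette on
#'   calibration).
#' @slot seed RNG seed for the resampling draws.
#' @exportClass MetricConfig
setClass("MetricConfig",
  representation(
    alpha = "numeric", nResample = "integer", nBoot = "integer",
    window = "numeric", scanStep = "numeric", scanWindow = "numeric",
    smoothLen = "integer", varEqual = "logical", replace = "logical",
    seed = "integer"
  ),
  prototype(
    alpha = 0.05, nResample = 50L, nBoot = 20000L, window = numeric(0),
    scanStep = 0.050, scanWindow = 0.050, smoothLen = 3L, varEqual = TRUE,
    replace = TRUE, seed = 1L
  )
)

setValidity("MetricConfig", function(object) {
  msg <- NULL
  if (object@alpha <= 0 || object@alpha >= 1)
    msg <- c(msg, "alpha must be in (0, 1)")
  if (object@nResample < 2L)
    msg <- c(msg, "nResample must be >= 2 (t-test undefined otherwise)")
  if (object@nBoot < 1L)
    msg <- c(msg, "nBoot must be >= 1")
  if (object@smoothLen < 1L || object@smoothLen %% 2L == 0L)
    msg <- c(msg, "smoothLen must be odd and >= 1")
  if (!length(object@window) %in% c(0L, 2L))
    msg <- c(msg, "window must be numeric(0) or (start, end)")
  if (length(object@window) == 2L && object@window[1] >= object@window[2])
    msg <- c(msg, "window start must be before window end")
  if (object@scanStep <= 0 || object@scanWindow <= 0)
    msg <- c(msg, "scanStep and scanWindow must be positive")
  if (is.null(msg)) TRUE else msg
})

#' Per-subject metric value
#'
#' The average percentage of channels with a significant between-condition
#' difference over all bootstrap repetitions, for one subject.
#'
#' @slot subjectId subject identifier.
#' @slot meanPctSignificant percentage in [0, 100].
#' @slot nChannels number of channels tested.
#' @slot nTrialsUsed integer length-2: surviving trial counts per condition.
#' @slot mode "resample_50" (fixed draw size) or "all_trials".
#' @slot config the \linkS4class{MetricConfig} snapshot used.
#' @exportClass MetricResult
setClass("MetricResult",
  representation(
    subjectId = "character", meanPctSignificant = "numeric",
    nChannels = "integer", nTrialsUsed = "integer", mode = "character",
    config = "MetricConfig"
  )
)

setValidity("MetricResult", function(object) {
  msg <- NULL
  if (object@meanPctSignificant < 0 || object@meanPctSignificant > 100)
    msg <- c(msg, "meanPctSignificant must be within [0, 100]")
  if (!object@mode %in% c("resample_50", "all_trials"))
    msg <- c(msg, "mode must be 'resample_50' or 'all_trials'")
  if (length(object@nTrialsUsed) != 2L)
    msg <- c(msg, "nTrialsUsed must have length 2 (one count per condition)")
  if (is.null(msg)) TRUE else msg
})

#' Percentage-significant curve across latencies
#'
#' Per-subject percentages of significant channels at each scanned latency,
#' with the across-subject median and (unscaled) median absolute deviation.
#'
#' @slot latencies bin-center latencies in seconds.
#' @slot perSubject matrix subjects x latencies of percentages.
#' @slot median per-latency median across subjects.
#' @slot mad per-latency median absolute deviation (median |x - median|,
#'   no consistency factor).
#' @slot subjectIds subject identifiers (rownames of \code{perSubject}).
#' @exportClass SignificanceCurve
setClass("SignificanceCurve",
  representation(
    latencies = "numeric", perSubject = "matrix", median = "numeric",
    mad = "numeric", subjectIds = "character"
  )
)

setValidity("SignificanceCurve", function(object) {
  msg <- NULL
  nl <- length(object@latencies)
  if (length(object@median) != nl || length(object@mad) != nl)
    msg <- c(msg, "median and mad must have one value per latency")
  if (ncol(object@perSubject) != nl)
    msg <- c(msg, "perSubject must have one column per latency")
  if (nrow(object@perSubject) != length(object@subjectIds))
    msg <- c(msg, "perSubject must have one row per subject")
  vals <- c(object@perSubject, object@median)
  if (length(vals) && (min(vals) < 0 || max(vals) > 100))
    msg <- c(msg, "percentages must be within [0, 100]")
  if (is.null(msg)) TRUE else msg
})

#' Selected 100-ms window of maximum effect
#'
#' The latency of maximum (smoothed) median significance, plus/minus 50 ms.
#' The window may be narrower than 100 ms when clipped at the epoch edges.
#'
#' @slot center latency of the smoothed maximum, seconds.
#' @slot start,end window bounds in seconds (nominally center -/+ 0.050).
#' @exportClass EffectWindow
setClass("EffectWindow",
  representation(center = "numeric", start = "numeric", end = "numeric")
)

setValidity("EffectWindow", function(object) {
  msg <- NULL
  if (object@end <= object@start)
    msg <- c(msg, "end must be after start")
  if (object@end - object@start > 0.100 + 1e-9)
    msg <- c(msg, "window must not exceed 100 ms")
  if (object@start < object@center - 0.050 - 1e-9 ||
      object@end > object@center + 0.050 + 1e-9)
    msg <- c(msg, "window must lie within center +/- 50 ms")
  if (is.null(msg)) TRUE else msg
})

#' Configuration of the subject-paired method comparison
#'
#' @slot nBoot bootstrap repetitions over subjects (default 20000).
#' @slot ciLevel confidence level of the percentile interval (default 0.95).
#' @slot trialRejectionExclusionFrac subjects with strictly more than this
#'   fraction of trials rejected in any condition are excluded (default 0.75).
#' @slot minSubjects minimum retained subjects for significance (default 4).
#' @slot trendBand p-values in (low, high] are reported as trends
#'   (default (0.01, 0.05)).
#' @slot seed RNG seed for the subject resampling.
#' @exportClass ComparisonConfig
setClass("ComparisonConfig",
  representation(
    nBoot = "integer", ciLevel = "numeric",
    trialRejectionExclusionFrac = "numeric", minSubjects = "integer",
    trendBand = "numeric", seed = "integer"
  ),
  prototype(
    nBoot = 20000L, ciLevel = 0.95, trialRejectionExclusionFrac = 0.75,
    minSubjects = 4L, trendBand = c(0.01, 0.05), seed = 1L
  )
)

setValidity("ComparisonConfig", function(object) {
  msg <- NULL
  if (object@ciLevel <= 0 || object@ciLevel >= 1)
    msg <- c(msg, "ciLevel must be in (0, 1)")
  if (object@minSubjects < 2L)
    msg <- c(msg, "minSubjects must be >= 2")
  if (length(object@trendBand) != 2L || object@trendBand[1] >= object@trendBand[2])
    msg <- c(msg, "trendBand must be an increasing pair")
  if (is.null(msg)) TRUE else msg
})

#' Result of a subject-paired bootstrap comparison
#'
#' @slot perSubjectDiff named numeric: metric difference (method A - method B)
#'   in percentage points per retained subject.
#' @slot meanDiff mean difference across retained subjects (NA when not
#'   computed).
#' @slot ci95 percentile bootstrap interval (low, high).
#' @slot pValue two-sided bootstrap p-value (tie-inclusive, floored at
#'   2/nBoot); NA when not computed.
#' @slot label "significant", "trend", "ns" or "not_computed".
#' @slot excludedSubjects data.frame with columns subject_id, reason.
#' @exportClass ComparisonResult
setClass("ComparisonResult",
  representation(
    perSubjectDiff = "numeric", meanDiff = "numeric", ci95 = "numeric",
    pValue = "numeric", label = "character", excludedSubjects = "data.frame"
  )
)

setValidity("ComparisonResult", function(object) {
  msg <- NULL
  if (!object@label %in% c("significant", "trend", "ns", "not_computed"))
    msg <- c(msg, "label must be significant/trend/ns/not_computed")
  if (object@label != "not_computed") {
    if (length(object@ci95) != 2L)
      msg <- c(msg, "ci95 must be (low, high)")
    else if (!(object@ci95[1] <= object@meanDiff + 1e-12 &&
               object@meanDiff <= object@ci95[2] + 1e-12))
      msg <- c(msg, "ci95 must bracket meanDiff")
  }
  if (is.null(msg)) TRUE else msg
})

#' Generative specification of a synthetic ERP cohort
#'
#' Full description of a simulated multi-subject, two-condition EEG study:
#' electrode count and sampling rate, trial counts, the condition-difference
#' evoked response (amplitude, latency, width, spatial smoothness), 1/f
#' background noise, slow drift, mains-line contamination, sparse
#' high-amplitude artifact transients, between-subject amplitude variability
#' and the master seed.
#'
#' @slot nSubjects number of subjects in the cohort.
#' @slot nChannels number of EEG channels (electrodes on a deterministic
#'   spherical spiral).
#' @slot srate sampling rate in Hz (default 250).
#' @slot nTrials trials per condition.
#' @slot effect list(amplitude, latency, width, smoothness): Gaussian-bump
#'   condition difference in microvolts at \code{latency} seconds with SD
#'   \code{width} seconds, spatial correlation length \code{smoothness} on
#'   the unit sphere.
#' @slot noise list(exponent, rms): 1/f^exponent background, total RMS in
#'   microvolts.
#' @slot drift list(rms, cornerHz): slow drift RMS and corner frequency.
#' @slot line list(freq, amplitude, badChannelCount): mains frequency,
#'   per-channel sinusoid amplitude, and number of channels with 10x
#'   elevated line amplitude.
#' @slot artifacts list(rate, amplitude, duration): transients per minute,
#'   peak microvolts, duration in seconds.
#' @slot interSubjectAmplitudeSd SD of the per-subject effect amplitude
#'   (microvolts).
#' @slot seed master RNG seed; subject i uses stream seed + i.
#' @exportClass SyntheticConfig
setClass("SyntheticConfig",
  representation(
    nSubjects = "integer", nChannels = "integer", srate = "numeric",
    nTrials = "integer", effect = "list", noise = "list", drift = "list",
    line = "list", artifacts = "list", interSubjectAmplitudeSd = "numeric",
    seed = "integer"
  )
)

setValidity("SyntheticConfig", function(object) {
  msg <- NULL
  need <- function(lst, fields, what) {
    miss <- setdiff(fields, names(lst))
    if (length(miss))
      sprintf("%s is missing fields: %s", what, paste(miss, collapse = ", "))
    else NULL
  }
  msg <- c(msg,
    need(object@effect, c("amplitude", "latency", "width", "smoothness"), "effect"),
    need(object@noise, c("exponent", "rms"), "noise"),
    need(object@drift, c("rms", "cornerHz"), "drift"),
    need(object@line, c("freq", "amplitude", "badChannelCount"), "line"),
    need(object@artifacts, c("rate", "amplitude", "duration"), "artifacts"))
  if (is.null(msg)) {
    amps <- c(object@effect$amplitude, object@noise$rms, object@drift$rms,
              object@line$amplitude, object@artifacts$amplitude,
              object@interSubjectAmplitudeSd)
    if (any(amps < 0)) msg <- c(msg, "all amplitudes must be >= 0")
    if (object@nTrials < 2L) msg <- c(msg, "nTrials must be >= 2")
    if (object@nSubjects < 1L) msg <- c(msg, "nSubjects must be >= 1")
    if (object@nChannels < 1L) msg <- c(msg, "nChannels must be >= 1")
    if (object@srate <= 0) msg <- c(msg, "srate must be positive")
  }
  if (is.null(msg)) TRUE else msg
})
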