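#' Construct a ContinuousRecording
#'
#' @param data channels x samples numeric matrix (microvolts).
#' @param srate sampling rate in Hz.
#' @param channelLabels character vector of channel names; defaults to
#'   "Ch1", "Ch2", ...
#' @param channelPositions channels x 3 unit-norm electrode coordinates, or
#'   NULL when unavailable.
#' @param subjectId subject identifier.
#' @return a \linkS4class{ContinuousRecording}.
#' @examples
#' rec <- ContinuousRecording(matrix(rnorm(200), 2, 100), srate = 100)
#' nChannels(rec)
#' @export
ContinuousRecording <- function(data, srate, channelLabels = NULL,
                                channelPositions = NULL,
                                subjectId = "subject") {
  data <- as.matrix(data)
  storage.mode(data) <- "double"
  if (is.null(channelLabels))
    channelLabels <- paste0("Ch", seq_len(nrow(data)))
  if (is.null(channelPositions))
    channelPositions <- matrix(numeric(0), 0, 3)
  new("ContinuousRecording", data = data, srate = srate,
      channelLabels = as.character(channelLabels),
      channelPositions = channelPositions,
      subjectId = subjectId)
}

#' Construct an EventTable
#'
#' @param onsets 0-based sample indices, strictly increasing.
#' @param labels condition label per event.
#' @return an \linkS4class{EventTable}.
#' @export
EventTable <- function(onsets = integer(0), labels = character(0)) {
  new("EventTable", onsets = as.integer(onsets), labels = as.character(labels))
}

#' Construct an EpochSet
#'
#' @param data channels x timepoints x trials numeric array (microvolts).
#' @param times seconds relative to event onset, uniformly spaced at 1/srate.
#' @param srate sampling rate in Hz.
#' @param condition condition label.
#' @param subjectId subject identifier.
#' @param channelLabels,channelPositions see
#'   \code{\link{ContinuousRecording}}.
#' @return an \linkS4class{EpochSet}.
#' @export
EpochSet <- function(data, times, srate, condition = "condition",
                     subjectId = "subject", channelLabels = NULL,
                     channelPositions = NULL) {
  storage.mode(data) <- "double"
  if (is.null(channelLabels))
    channelLabels <- paste0("Ch", seq_len(dim(data)[1]))
  if (is.null(channelPositions))
    channelPositions <- matrix(numeric(0), 0, 3)
  new("EpochSet", data = data, times = as.numeric(times), srate = srate,
      condition = condition, subjectId = subjectId,
      channelLabels = as.character(channelLabels),
      channelPositions = channelPositions)
}

#' Construct a MetricConfig
#'
#' Defaults follow the reference protocol: alpha 0.05, 50 trials drawn with
#' replacement per condition, 20000 bootstrap repetitions, 50-ms latency
#' scan step and bin width, size-3 moving-average smoother.
#'
#' @param alpha,nResample,nBoot,window,scanStep,scanWindow,smoothLen,varEqual,replace,seed
#'   see \linkS4class{MetricConfig}. \code{window} may also be an
#'   \linkS4class{EffectWindow} (its bounds are used).
#' @return a \linkS4class{MetricConfig}.
#' @examples
#' cfg <- metricConfig(window = c(0.30, 0.40), nBoot = 1000, seed = 7)
#' @export
metricConfig <- function(alpha = 0.05, nResample = 50, nBoot = 20000,
                         window = numeric(0), scanStep = 0.050,
                         scanWindow = 0.050, smoothLen = 3, varEqual = TRUE,
                         replace = TRUE, seed = 1) {
  if (is(window, "EffectWindow")) window <- c(window@start, window@end)
  new("MetricConfig", alpha = alpha, nResample = as.integer(nResample),
      nBoot = as.integer(nBoot), window = as.numeric(window),
      scanStep = scanStep, scanWindow = scanWindow,
      smoothLen = as.integer(smoothLen), varEqual = varEqual,
      replace = replace, seed = as.integer(seed))
}

#' Construct a ComparisonConfig
#'
#' @param nBoot,ciLevel,trialRejectionExclusionFrac,minSubjects,trendBand,seed
#'   see \linkS4class{ComparisonConfig}.
#' @return a \linkS4class{ComparisonConfig}.
#' @export
comparisonConfig <- function(nBoot = 20000, ciLevel = 0.95,
                             trialRejectionExclusionFrac = 0.75,
                             minSubjects = 4, trendBand = c(0.01, 0.05),
                             seed = 1) {
  new("ComparisonConfig", nBoot = as.integer(nBoot), ciLevel = ciLevel,
      trialRejectionExclusionFrac = trialRejectionExclusionFrac,
      minSubjects = as.integer(minSubjects), trendBand = trendBand,
      seed = as.integer(seed))
}

#' Construct a SyntheticConfig
#'
#' Defaults describe a realistic mid-density ERP study: 64 channels at
#' 250 Hz, 100 trials per condition, a 6-microvolt Gaussian-bump condition
#' difference at 350 ms (SD 50 ms) on a smooth random topography, pink
#' (1/f) background of 10 microvolts RMS, 5-microvolt slow drift below
#' 0.05 Hz, 2-microvolt 50-Hz line noise, and 2 high-amplitude artifact
#' transients per minute.
#'
#' @param nSubjects,nChannels,srate,nTrials cohort geometry.
#' @param effect list(amplitude, latency, width, smoothness) of the
#'   condition-difference bump; see \linkS4class{SyntheticConfig}.
#' @param noise list(exponent, rms) of the 1/f background.
#' @param drift list(rms, cornerHz) of the slow drift.
#' @param line list(freq, amplitude, badChannelCount) of mains contamination.
#' @param artifacts list(rate, amplitude, duration) of sparse transients.
#' @param interSubjectAmplitudeSd SD of per-subject effect amplitude.
#' @param seed master seed; subject i is generated from stream seed + i.
#' @return a \linkS4class{SyntheticConfig}.
#' @examples
#' cfg <- syntheticConfig(nSubjects = 2, nChannels = 16, nTrials = 30)
#' @export
syntheticConfig <- function(nSubjects = 8, nChannels = 64, srate = 250,
                            nTrials = 100,
                            effect = list(amplitude = 6, latency = 0.35,
                                          width = 0.05, smoothness = 1),
                            noise = list(exponent = 1, rms = 10),
                            drift = list(rms = 5, cornerHz = 0.05),
                            line = list(freq = 50, amplitude = 2,
                                        badChannelCount = 0),
                            artifacts = list(rate = 2, amplitude = 100,
                                             duration = 0.3),
                            interSubjectAmplitudeSd = 1,
                            seed = 1) {
  defaults <- formals(syntheticConfig)
  fill <- function(given, def) {
    def <- eval(def)
    for (nm in setdiff(names(def), names(given))) given[[nm]] <- def[[nm]]
    given
  }
  new("SyntheticConfig", nSubjects = as.integer(nSubjects),
      nChannels = as.integer(nChannels), srate = srate,
      nTrials = as.integer(nTrials),
      effect = fill(effect, defaults$effect),
      noise = fill(noise, defaults$noise),
      drift = fill(drift, defaults$drift),
      line = fill(line, defaults$line),
      artifacts = fill(artifacts, defaults$artifacts),
      interSubjectAmplitudeSd = interSubjectAmplitudeSd,
      seed = as.integer(seed))
}

#' Accessors for the core containers
#'
#' @param x a \linkS4class{ContinuousRecording}, \linkS4class{EventTable} or
#'   \linkS4class{EpochSet}.
#' @return the corresponding component: channel/trial/sample counts, sampling
#'   rate, labels, positions, data, times or condition.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setMethod("nChannels", "ContinuousRecording", function(x) nrow(x@data))
#' @rdname accessors
#' @export
setMethod("nChannels", "EpochSet", function(x) dim(x@data)[1])
#' @rdname accessors
#' @export
setMethod("nSamples", "ContinuousRecording", function(x) ncol(x@data))
#' @rdname accessors
#' @export
setMethod("nTrials", "EpochSet", function(x) dim(x@data)[3])
#' @rdname accessors
#' @export
setMethod("samplingRate", "ContinuousRecording", function(x) x@srate)
#' @rdname accessors
#' @export
setMethod("samplingRate", "EpochSet", function(x) x@srate)
#' @rdname accessors
#' @export
setMethod("channelLabels", "ContinuousRecording", function(x) x@channelLabels)
#' @rdname accessors
#' @export
setMethod("channelLabels", "EpochSet", function(x) x@channelLabels)
#' @rdname accessors
#' @export
setMethod("channelPositions", "ContinuousRecording", function(x) x@channelPositions)
#' @rdname accessors
#' @export
setMethod("channelPositions", "EpochSet", function(x) x@channelPositions)
#' @rdname accessors
#' @export
setMethod("subjectId", "ContinuousRecording", function(x) x@subjectId)
#' @rdname accessors
#' @export
setMethod("subjectId", "EpochSet", function(x) x@subjectId)
#' @rdname accessors
#' @export
setMethod("epochTimes", "EpochSet", function(x) x@times)
#' @rdname accessors
#' @export
setMethod("condition", "EpochSet", function(x) x@condition)
#' @rdname accessors
#' @export
setMethod("recordingData", "ContinuousRecording", function(x) x@data)
#' @rdname accessors
#' @export
setMethod("recordingData", "EpochSet", function(x) x@data)

#' Event-table accessors
#'
#' @param x an \linkS4class{EventTable}.
#' @return \code{eventOnsets}: 0-based sample indices;
#'   \code{eventLabels}: condition labels.
#' @export
eventOnsets <- function(x) x@onsets

#' @rdname eventOnsets
#' @export
eventLabels <- function(x) x@labels

setMethod("show", "ContinuousRecording", function(object) {
  cat(sprintf("ContinuousRecording '%s': %d channels x %d samples @ %g Hz (%.1f s)%s\n",
              object@subjectId, nrow(object@data), ncol(object@data),
              object@srate, ncol(object@data) / object@srate,
              if (nrow(object@channelPositions)) ", with positions" else ""))
})

setMethod("show", "EventTable", function(object) {
  cat(sprintf("EventTable: %d events", length(object@onsets)))
  if (length(object@onsets)) {
    tab <- table(object@labels)
    cat(" (", paste(sprintf("%s: %d", names(tab), tab), collapse = ", "), ")",
        sep = "")
  }
  cat("\n")
})

setMethod("show", "EpochSet", function(object) {
  d <- dim(object@data)
  cat(sprintf("EpochSet '%s' condition '%s': %d channels x %d timepoints x %d trials @ %g Hz, t in [%.3f, %.3f] s\n",
              object@subjectId, object@condition, d[1], d[2], d[3],
              object@srate, min(object@times), max(object@times)))
})

setMethod("show", "MetricResult", function(object) {
  cat(sprintf("MetricResult '%s' [%s]: %.2f%% significant channels (%d channels; %d/%d trials; alpha=%g, nResample=%d, nBoot=%d)\n",
              object@subjectId, object@mode, object@meanPctSignificant,
              object@nChannels, object@nTrialsUsed[1], object@nTrialsUsed[2],
              object@config@alpha, object@config@nResample,
              object@config@nBoot))
})

setMethod("show", "SignificanceCurve", function(object) {
  cat(sprintf("SignificanceCurve: %d subjects x %d latencies in [%.3f, %.3f] s; peak median %.1f%%\n",
              nrow(object@perSubject), length(object@latencies),
              min(object@latencies), max(object@latencies),
              max(object@median)))
})

setMethod("show", "EffectWindow", function(object) {
  cat(sprintf("EffectWindow: center %.3f s, window [%.3f, %.3f] s\n",
              object@center, object@start, object@end))
})

setMethod("show", "ComparisonResult", function(object) {
  if (object@label == "not_computed") {
    cat("ComparisonResult: not computed (too few retained subjects)\n")
  } else {
    cat(sprintf("ComparisonResult: mean diff %.2f pp, 95%% CI [%.2f, %.2f], p = %.4g (%s), %d subjects\n",
                object@meanDiff, object@ci95[1], object@ci95[2],
                object@pValue, object@label, length(object@perSubjectDiff)))
  }
  if (nrow(object@excludedSubjects))
    cat(sprintf("  excluded: %s\n",
                paste(object@excludedSubjects$subject_id, collapse = ", ")))
})

#' Effect-window accessors
#'
#' @param x an \linkS4class{EffectWindow}.
#' @return numeric scalar (seconds).
#' @export
windowCenter <- function(x) x@center

#' @rdname windowCenter
#' @export
windowBounds <- function(x) c(x@start, x@end)

#' Metric-result accessors
#'
#' @param x a \linkS4class{MetricResult} (or a list of them for
#'   \code{metricValues}).
#' @return \code{metricValue}: the subject's mean percentage of significant
#'   channels; \code{metricValues}: named vector over a cohort.
#' @export
metricValue <- function(x) x@meanPctSignificant

#' @rdname metricValue
#' @export
metricValues <- function(x) {
  vapply(x, function(r) r@meanPctSignificant, numeric(1),
         USE.NAMES = FALSE) |>
    stats::setNames(vapply(x, function(r) r@subjectId, character(1)))
}

#' Significance-curve accessors
#'
#' @param x a \linkS4class{SignificanceCurve}.
#' @return \code{curveLatencies}: bin centers (s); \code{curveMedian},
#'   \code{curveMad}: across-subject summaries; \code{curvePerSubject}:
#'   subjects x latencies matrix.
#' @export
curveLatencies <- function(x) x@latencies

#' @rdname curveLatencies
#' @export
curveMedian <- function(x) x@median

#' @rdname curveLatencies
#' @export
curveMad <- function(x) x@mad

#' @rdname curveLatencies
#' @export
curvePerSubject <- function(x) x@perSubject

#' Comparison-result accessors
#'
#' @param x a \linkS4class{ComparisonResult}.
#' @return components of the comparison: the mean paired difference, the
#'   percentile CI, the bootstrap p-value, the label, per-subject
#'   differences, or the exclusion table.
#' @export
comparisonMeanDiff <- function(x) x@meanDiff

#' @rdname comparisonMeanDiff
#' @export
comparisonCI <- function(x) x@ci95

#' @rdname comparisonMeanDiff
#' @export
comparisonPValue <- function(x) x@pValue

#' @rdname comparisonMeanDiff
#' @export
comparisonLabel <- function(x) x@label

#' @rdname comparisonMeanDiff
#' @export
comparisonDiffs <- function(x) x@perSubjectDiff

#' @rdname comparisonMeanDiff
#' @export
comparisonExcluded <- function(x) x@excludedSubjects
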