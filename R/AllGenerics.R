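#' @rdname accessors
#' @export
setGeneric("nChannels", function(x) standardGeneric("nChannels"))

#' @rdname accessors
#' @export
setGeneric("nTrials", function(x) standardGeneric("nTrials"))

#' @rdname accessors
#' @export
setGeneric("nSamples", function(x) standardGeneric("nSamples"))

#' @rdname accessors
#' @export
setGeneric("samplingRate", function(x) standardGeneric("samplingRate"))

#' @rdname accessors
#' @export
setGeneric("channelLabels", function(x) standardGeneric("channelLabels"))

#' @rdname accessors
#' @export
setGeneric("channelPositions", function(x) standardGeneric("channelPositions"))

#' @rdname accessors
#' @export
setGeneric("subjectId", function(x) standardGeneric("subjectId"))

#' @rdname accessors
#' @export
setGeneric("epochTimes", function(x) standardGeneric("epochTimes"))

#' @rdname accessors
#' @export
setGeneric("condition", function(x) standardGeneric("condition"))

#' @rdname accessors
#' @export
setGeneric("recordingData", function(x) standardGeneric("recordingData"))

#' Re-reference EEG data
#'
#' Express all channels relative to a derived reference: the per-sample mean
#' across channels ("average"), the per-sample median ("median"), the mean of
#' a named subset of channels, or no change ("none"). Works on continuous
#' recordings and on epoch sets (trial by trial).
#'
#' @param x a \linkS4class{ContinuousRecording} or \linkS4class{EpochSet}.
#' @param scheme "none", "average", "median", or a character vector of
#'   channel labels whose mean becomes the reference.
#' @return an object of the same class as \code{x}.
#' @examples
#' rec <- ContinuousRecording(matrix(c(1, 2, 6), 3, 4), srate = 100,
#'                            channelLabels = c("C1", "C2", "C3"))
#' recordingData(rereference(rec, "median"))[, 1]  # -1 0 4
#' @export
setGeneric("rereference", function(x, scheme = "average") standardGeneric("rereference"))

#' Write a data container to disk
#'
#' @param obj a \linkS4class{ContinuousRecording} or \linkS4class{EpochSet}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @seealso \code{\link{readContainer}}
#' @export
setGeneric("writeContainer", function(obj, path) standardGeneric("writeContainer"))

#' Spherical-spline interpolation of bad channels
#'
#' Replaces the listed channels by spherical-spline estimates (Perrin-style,
#' order-4 splines, Legendre expansion to degree 7, regularization 1e-5)
#' computed from the remaining channels. Requires unit-sphere electrode
#' positions and at least 3 good channels. Channel count and order are
#' preserved.
#'
#' @param x a \linkS4class{ContinuousRecording} or \linkS4class{EpochSet}.
#' @param bad integer indices or channel labels of the channels to replace.
#' @return an object of the same class as \code{x}.
#' @export
setGeneric("interpolateChannels", function(x, bad) standardGeneric("interpolateChannels"))
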