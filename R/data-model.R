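#' Extract condition epochs from a continuous recording
#'
#' Cuts one trial per event carrying the requested condition label. Sample
#' indexing is 0-based and epoch windows are half-open: trial t covers
#' samples \code{onset + round(tmin*srate) .. onset + round(tmax*srate) - 1},
#' so the default (-0.3, 0.7) s window at 250 Hz yields 250 samples and time
#' 0 is the event sample itself. Events whose window would exceed the
#' recording bounds are dropped and counted (attribute \code{nDropped} and a
#' message).
#'
#' @param rec a \linkS4class{ContinuousRecording}.
#' @param events an \linkS4class{EventTable} for that recording.
#' @param condition the event label to extract.
#' @param tmin,tmax epoch window in seconds relative to the event (default
#'   -0.3 to 0.7, the standard 1-s analysis epoch).
#' @return an \linkS4class{EpochSet} with attribute \code{nDropped}.
#' @examples
#' rec <- ContinuousRecording(matrix(rnorm(2000), 2, 1000), srate = 100)
#' ev <- EventTable(onsets = seq(100, 800, by = 100),
#'                  labels = rep("std", 8))
#' ep <- extractEpochs(rec, ev, "std")
#' nTrials(ep)  # 8
#' @export
extractEpochs <- function(rec, events, condition, tmin = -0.3, tmax = 0.7) {
  stopifnot(is(rec, "ContinuousRecording"), is(events, "EventTable"))
  if (tmin >= tmax)
    stop("invalid window: tmin must be smaller than tmax")
  sel <- which(events@labels == condition)
  if (!length(sel))
    stop(sprintf("empty condition: no events labelled '%s'", condition))
  o0 <- round(tmin * rec@srate)
  o1 <- round(tmax * rec@srate)
  onsets <- events@onsets[sel]
  ns <- ncol(rec@data)
  keep <- (onsets + o0 >= 0L) & (onsets + o1 <= ns)
  nDropped <- sum(!keep)
  if (!any(keep))
    stop("empty condition: no event window fits inside the recording")
  if (nDropped)
    message(sprintf("extractEpochs: dropped %d event(s) whose window exceeds the recording", nDropped))
  onsets <- onsets[keep]
  nt <- o1 - o0
  dat <- array(0, c(nrow(rec@data), nt, length(onsets)))
  for (i in seq_along(onsets)) {
    # 0-based sample s maps to column s + 1
    dat[, , i] <- rec@data[, (onsets[i] + o0 + 1L):(onsets[i] + o1), drop = FALSE]
  }
  ep <- EpochSet(dat, times = (o0:(o1 - 1L)) / rec@srate, srate = rec@srate,
                 condition = condition, subjectId = rec@subjectId,
                 channelLabels = rec@channelLabels,
                 channelPositions = rec@channelPositions)
  attr(ep, "nDropped") <- nDropped
  ep
}

.containerFields <- list(
  ContinuousRecording = c("type", "data", "srate", "labels", "positions",
                          "subject_id"),
  EpochSet = c("type", "data", "times", "srate", "labels", "positions",
               "condition", "subject_id")
)

#' @describeIn writeContainer continuous recording
#' @export
setMethod("writeContainer", "ContinuousRecording", function(obj, path) {
  saveRDS(list(type = "ContinuousRecording", data = obj@data,
               srate = obj@srate, labels = obj@channelLabels,
               positions = obj@channelPositions, subject_id = obj@subjectId),
          path)
  invisible(path)
})

#' @describeIn writeContainer epoch set
#' @export
setMethod("writeContainer", "EpochSet", function(obj, path) {
  saveRDS(list(type = "EpochSet", data = obj@data, times = obj@times,
               srate = obj@srate, labels = obj@channelLabels,
               positions = obj@channelPositions, condition = obj@condition,
               subject_id = obj@subjectId),
          path)
  invisible(path)
})

#' Read a data container from disk
#'
#' Restores a \linkS4class{ContinuousRecording} or \linkS4class{EpochSet}
#' written by \code{\link{writeContainer}}. The container is a single-file
#' store with fixed field names (data/times/srate/labels/positions/
#' condition/subject_id); the round trip is bit-exact. An optional channel
#' selection excludes non-EEG auxiliary channels at read time.
#'
#' @param path file written by \code{\link{writeContainer}}.
#' @param channels optional character vector: keep only these channel labels
#'   (in the stored order).
#' @return the stored object.
#' @export
readContainer <- function(path, channels = NULL) {
  if (!file.exists(path)) stop(sprintf("no such container: %s", path))
  lst <- readRDS(path)
  if (!is.list(lst) || is.null(lst$type) ||
      !lst$type %in% names(.containerFields))
    stop("malformed container: missing field: type")
  for (f in .containerFields[[lst$type]])
    if (is.null(lst[[f]])) stop(sprintf("malformed container: missing field: %s", f))
  keep <- seq_along(lst$labels)
  if (!is.null(channels)) {
    keep <- which(lst$labels %in% channels)
    if (!length(keep)) stop("channel selection removed every channel")
  }
  pos <- lst$positions
  if (nrow(pos)) pos <- pos[keep, , drop = FALSE]
  if (lst$type == "ContinuousRecording") {
    ContinuousRecording(lst$data[keep, , drop = FALSE], srate = lst$srate,
                        channelLabels = lst$labels[keep],
                        channelPositions = pos, subjectId = lst$subject_id)
  } else {
    EpochSet(lst$data[keep, , , drop = FALSE], times = lst$times,
             srate = lst$srate, condition = lst$condition,
             subjectId = lst$subject_id, channelLabels = lst$labels[keep],
             channelPositions = pos)
  }
}

#' Read a BIDS-style events table
#'
#' Parses a tab-separated events file with columns \code{onset} (seconds)
#' and \code{trial_type}; onsets are converted to 0-based sample indices by
#' rounding \code{onset * srate} to the nearest sample (recordings resampled
#' offline frequently carry event latencies that do not fall on data
#' samples).
#'
#' @param path path to the \code{*_events.tsv} file.
#' @param srate sampling rate of the recording the onsets refer to (Hz).
#' @return an \linkS4class{EventTable}.
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' writeLines(c("onset\ttrial_type", "0.5\ttarget", "1.0\tstandard"), tf)
#' eventOnsets(readEventsTsv(tf, srate = 250))  # 125 250
#' @export
readEventsTsv <- function(path, srate) {
  if (missing(srate) || !is.numeric(srate) || length(srate) != 1L || srate <= 0)
    stop("unknown srate: a positive sampling rate is required to convert onsets")
  if (file.exists(path) && file.size(path) == 0L) return(EventTable())
  tab <- utils::read.delim(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE, check.names = FALSE)
  if (nrow(tab) == 0L) return(EventTable())
  for (col in c("onset", "trial_type"))
    if (!col %in% names(tab)) stop(sprintf("missing column: %s", col))
  if (is.unsorted(tab$onset, strictly = TRUE))
    stop("event onsets must be strictly increasing")
  onsets <- as.integer(round(tab$onset * srate))
  if (any(diff(onsets) <= 0L))
    stop("event onsets collide after rounding to the sample grid")
  EventTable(onsets = onsets, labels = as.character(tab$trial_type))
}

#' Write a BIDS-style events table
#'
#' Inverse convenience of \code{\link{readEventsTsv}}: onsets are written in
#' seconds (\code{onset = sample / srate}).
#'
#' @param events an \linkS4class{EventTable}.
#' @param path output path.
#' @param srate sampling rate used to convert sample indices to seconds.
#' @return \code{path}, invisibly.
#' @export
writeEventsTsv <- function(events, path, srate) {
  df <- data.frame(onset = events@onsets / srate,
                   trial_type = events@labels)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
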