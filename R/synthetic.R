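## Synthetic two-condition ERP cohorts with known ground truth.
##
## Generative model per subject: continuous data = 1/f background + slow
## drift + mains sinusoid + sparse high-amplitude transients + a common
## evoked response at every event; condition "B" events additionally carry
## the condition-difference bump (Gaussian in time, smooth random topography
## across the scalp, emulating volume conduction). Events alternate
## pseudo-randomly with inter-stimulus intervals uniform in [1.8, 2.2] s.

# Deterministic spherical-spiral electrode layout (golden-angle spiral over
# the upper ~2/3 of the unit sphere, cap-like).
.spiralPositions <- function(n) {
  i <- seq_len(n)
  z <- 1 - (4 / 3) * (i - 0.5) / n
  phi <- i * pi * (3 - sqrt(5))
  r <- sqrt(pmax(1 - z^2, 0))
  cbind(r * cos(phi), r * sin(phi), z)
}

# Zero-mean unit-variance Gaussian random field on the electrode positions
# with squared-exponential covariance (chordal distance, length ell).
.gaussianField <- function(pos, ell) {
  n <- nrow(pos)
  D2 <- outer(rowSums(pos^2), rowSums(pos^2), "+") - 2 * pos %*% t(pos)
  K <- exp(-pmax(D2, 0) / (2 * ell^2)) + diag(1e-8, n)
  as.vector(t(chol(K)) %*% stats::rnorm(n))
}

# Two-sided spectral amplitude shapes on the length-n DFT grid.
.foldedFreq <- function(n, srate) {
  f <- (0:(n - 1)) * srate / n
  pmin(f, srate - f)
}

.pinkAmp <- function(f, exponent) {
  a <- numeric(length(f))
  pos <- f > 0
  a[pos] <- f[pos]^(-exponent / 2)
  a
}

.driftAmp <- function(f, cornerHz) {
  a <- 1 / (1 + (f / cornerHz)^2)
  a[1] <- 0
  a
}

# Gaussian stationary noise with the given spectral amplitude shape, scaled
# to the target RMS; the implied circulant autocovariance is known in
# closed form (used by the expected-metric oracle).
.spectralNoise <- function(n, amp, rms) {
  if (rms <= 0) return(numeric(n))
  w <- stats::rnorm(n)
  x <- Re(stats::fft(stats::fft(w) * amp, inverse = TRUE)) / n
  x * rms / sqrt(mean(amp^2))
}

# Common evoked response shape (arbitrary but fixed): an early negative and
# a later positive deflection, unit peak scale.
.commonErpShape <- function(t) {
  -0.6 * exp(-(t - 0.10)^2 / (2 * 0.03^2)) +
    exp(-(t - 0.25)^2 / (2 * 0.06^2))
}

.isiRange <- c(1.8, 2.2)
.jitterRange <- c(0.8, 1.2)  # trial-to-trial effect amplitude jitter

#' Generate one synthetic subject
#'
#' Simulates a continuous two-condition recording plus its event table,
#' deterministic given \code{(cfg@seed, subjectIndex)} (the subject's RNG
#' stream is seeded with their sum). Condition "B" events add the
#' condition-difference bump scaled by a smooth random topography shared
#' within the subject and by a per-trial amplitude jitter uniform in
#' [0.8, 1.2]; condition "A" events add none. Both conditions carry the
#' same common evoked response. The returned ground truth records the
#' realized effect topography and subject amplitude for the oracle.
#'
#' @param cfg a \linkS4class{SyntheticConfig}.
#' @param subjectIndex 1-based subject index within the cohort.
#' @return list with \code{recording} (\linkS4class{ContinuousRecording}),
#'   \code{events} (\linkS4class{EventTable}) and \code{groundTruth} (list:
#'   topoEffect, topoErp, ampSubject, nSamples, positions).
#' @examples
#' s <- generateSubject(syntheticConfig(nChannels = 8, nTrials = 5), 1)
#' s$recording
#' @export
generateSubject <- function(cfg, subjectIndex = 1) {
  stopifnot(is(cfg, "SyntheticConfig"))
  eff <- cfg@effect
  if (eff$latency + 3 * eff$width > .isiRange[1])
    stop("evoked-effect window exceeds the minimum inter-stimulus interval")
  if (eff$latency - 3 * eff$width < -1)
    stop("effect latency must lie within the epoch")
  set.seed(cfg@seed + subjectIndex)
  nCh <- cfg@nChannels
  srate <- cfg@srate
  pos <- .spiralPositions(nCh)

  topoEffect <- 1 + 0.3 * .gaussianField(pos, eff$smoothness)
  topoErp <- 1 + 0.5 * .gaussianField(pos, 1)
  ampS <- eff$amplitude +
    if (cfg@interSubjectAmplitudeSd > 0)
      cfg@interSubjectAmplitudeSd * stats::rnorm(1) else 0

  nEv <- 2L * cfg@nTrials
  labels <- sample(rep(c("A", "B"), cfg@nTrials))
  isi <- stats::runif(nEv - 1L, .isiRange[1], .isiRange[2])
  pad <- 3
  onsetSec <- pad + c(0, cumsum(isi))
  total <- onsetSec[nEv] + pad
  # FFT-friendly length (5-smooth) so spectral synthesis stays O(n log n)
  n <- stats::nextn(as.integer(ceiling(total * srate)), c(2, 3, 5))
  total <- n / srate
  onsets <- as.integer(round(onsetSec * srate))

  data <- matrix(0, nCh, n)
  ampPink <- .pinkAmp(.foldedFreq(n, srate), cfg@noise$exponent)
  for (i in seq_len(nCh))
    data[i, ] <- .spectralNoise(n, ampPink, cfg@noise$rms)
  if (cfg@drift$rms > 0) {
    ampDrift <- .driftAmp(.foldedFreq(n, srate), cfg@drift$cornerHz)
    for (i in seq_len(nCh))
      data[i, ] <- data[i, ] + .spectralNoise(n, ampDrift, cfg@drift$rms)
  }

  if (cfg@line$amplitude > 0) {
    lineAmp <- rep(cfg@line$amplitude, nCh)
    if (cfg@line$badChannelCount > 0) {
      badLine <- sample.int(nCh, cfg@line$badChannelCount)
      lineAmp[badLine] <- lineAmp[badLine] * 10
    }
    tSec <- (seq_len(n) - 1) / srate
    phase <- stats::runif(nCh, 0, 2 * pi)
    for (i in seq_len(nCh))
      data[i, ] <- data[i, ] + lineAmp[i] * sin(2 * pi * cfg@line$freq * tSec + phase[i])
  }

  nArt <- 0L
  if (cfg@artifacts$rate > 0 && cfg@artifacts$amplitude > 0) {
    nArt <- stats::rpois(1, cfg@artifacts$rate * total / 60)
    for (k in seq_len(nArt)) {
      tc <- stats::runif(1, 0, total)
      peak <- cfg@artifacts$amplitude * stats::runif(1, 0.5, 1.5) *
        sample(c(-1, 1), 1)
      profile <- .gaussianField(pos, 0.5)
      sd <- cfg@artifacts$duration / 4
      kGrid <- seq(round((tc - 3 * sd) * srate), round((tc + 3 * sd) * srate))
      kGrid <- kGrid[kGrid >= 0 & kGrid < n]
      if (!length(kGrid)) next
      env <- exp(-(kGrid / srate - tc)^2 / (2 * sd^2))
      data[, kGrid + 1L] <- data[, kGrid + 1L] + outer(peak * profile, env)
    }
  }

  # evoked responses
  erpGrid <- 0:round(0.6 * srate)
  erpWave <- 4 * .commonErpShape(erpGrid / srate)  # 4 uV common response
  bumpGrid <- seq(round((eff$latency - 4 * eff$width) * srate),
                  round((eff$latency + 4 * eff$width) * srate))
  bumpWave <- exp(-(bumpGrid / srate - eff$latency)^2 / (2 * eff$width^2))
  for (e in seq_len(nEv)) {
    i0 <- onsets[e]
    cols <- i0 + erpGrid + 1L
    data[, cols] <- data[, cols] + outer(topoErp, erpWave)
    if (labels[e] == "B") {
      jit <- stats::runif(1, .jitterRange[1], .jitterRange[2])
      cols <- i0 + bumpGrid + 1L
      data[, cols] <- data[, cols] + outer(ampS * jit * topoEffect, bumpWave)
    }
  }

  list(
    recording = ContinuousRecording(data, srate = srate,
                                    channelLabels = paste0("Ch", seq_len(nCh)),
                                    channelPositions = pos,
                                    subjectId = sprintf("S%02d", subjectIndex)),
    events = EventTable(onsets = onsets, labels = labels),
    groundTruth = list(topoEffect = topoEffect, topoErp = topoErp,
                       ampSubject = ampS, nSamples = n, positions = pos,
                       nArtifacts = nArt, durationSec = total)
  )
}

#' Generate a synthetic cohort
#'
#' Runs \code{\link{generateSubject}} for each of \code{cfg@nSubjects}
#' subjects (subject i on RNG stream \code{cfg@seed + i}, so subjects are
#' statistically independent and individually reproducible). Per-subject
#' effect amplitudes vary with \code{cfg@interSubjectAmplitudeSd}.
#' Optionally writes per-subject containers, events files, a manifest TSV
#' and a ground-truth JSON to \code{outDir}.
#'
#' @param cfg a \linkS4class{SyntheticConfig}.
#' @param outDir optional output directory.
#' @return (invisibly when writing) list of subject lists as returned by
#'   \code{\link{generateSubject}}.
#' @export
generateCohort <- function(cfg, outDir = NULL) {
  subjects <- lapply(seq_len(cfg@nSubjects), function(i)
    generateSubject(cfg, i))
  if (!is.null(outDir)) {
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    manifest <- do.call(rbind, lapply(subjects, function(s) {
      id <- s$recording@subjectId
      recName <- paste0(id, "_recording.ers")
      evName <- paste0(id, "_events.tsv")
      writeContainer(s$recording, file.path(outDir, recName))
      writeEventsTsv(s$events, file.path(outDir, evName), s$recording@srate)
      # manifest paths are relative to the manifest itself, so a cohort
      # directory is relocatable and runs reproduce byte-identically
      data.frame(subject_id = id, recording = recName, events = evName)
    }))
    utils::write.table(manifest, file.path(outDir, "manifest.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    gt <- lapply(subjects, function(s)
      c(list(subject_id = s$recording@subjectId),
        s$groundTruth[c("topoEffect", "ampSubject", "nSamples")]))
    jsonlite::write_json(gt, file.path(outDir, "ground_truth.json"),
                         auto_unbox = TRUE, digits = NA)
    return(invisible(subjects))
  }
  subjects
}

#' Epoch a generated cohort into condition pairs
#'
#' Convenience wrapper: extracts condition "A" and "B" epochs for every
#' generated subject, yielding the pair list consumed by
#' \code{\link{cohortMetric}} and \code{\link{latencyScan}}.
#'
#' @param subjects list returned by \code{\link{generateCohort}} (each
#'   element may also be a list(recording, events)).
#' @param tmin,tmax epoch window in seconds (default -0.3 to 0.7).
#' @return list of per-subject lists with elements \code{a}, \code{b}.
#' @export
epochPairs <- function(subjects, tmin = -0.3, tmax = 0.7) {
  lapply(subjects, function(s) list(
    a = extractEpochs(s$recording, s$events, "A", tmin, tmax),
    b = extractEpochs(s$recording, s$events, "B", tmin, tmax)))
}
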