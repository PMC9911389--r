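# Fixture builders shared across the suite. Everything is generated in code
# at test time; seeds are fixed so expected values are stable.

# Epoch set of iid Gaussian noise (optionally with a mean shift on selected
# channels), times starting at t0.
makeEpochSet <- function(nCh = 4, nTime = 10, nTrials = 20, srate = 250,
                         shift = 0, shiftChannels = integer(0), t0 = 0,
                         condition = "A", subjectId = "S01", sd = 1,
                         positions = FALSE) {
  dat <- array(rnorm(nCh * nTime * nTrials, sd = sd), c(nCh, nTime, nTrials))
  if (length(shiftChannels))
    dat[shiftChannels, , ] <- dat[shiftChannels, , ] + shift
  pos <- if (positions) erpsig:::.spiralPositions(nCh) else NULL
  EpochSet(dat, times = t0 + (0:(nTime - 1)) / srate, srate = srate,
           condition = condition, subjectId = subjectId,
           channelPositions = pos)
}

# A null condition pair (same generative law, no effect).
makeNullPair <- function(nCh = 8, nTime = 10, nTrials = 30, srate = 250,
                         subjectId = "S01") {
  list(a = makeEpochSet(nCh, nTime, nTrials, srate, condition = "A",
                        subjectId = subjectId),
       b = makeEpochSet(nCh, nTime, nTrials, srate, condition = "B",
                        subjectId = subjectId))
}

fullWindow <- function(ep) {
  tt <- epochTimes(ep)
  c(tt[1], tt[length(tt)] + 1 / samplingRate(ep))
}

# Direction-test cohort (drifty, 12 subjects) shared between acceptance
# blocks; generated once per test run.
.cohortCache <- new.env(parent = emptyenv())

directionCohort <- function() {
  if (is.null(.cohortCache$drift)) {
    cfg <- syntheticConfig(nSubjects = 12, nChannels = 32, nTrials = 60,
                           drift = list(rms = 20), seed = 20260919)
    .cohortCache$drift <- list(cfg = cfg, subjects = generateCohort(cfg))
  }
  .cohortCache$drift
}
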