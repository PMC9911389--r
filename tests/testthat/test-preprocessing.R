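# amplitude of a sinusoid at freq f in the middle third of a signal
.midAmplitude <- function(x, f, srate) {
  n <- length(x)
  sel <- floor(n / 3):floor(2 * n / 3)
  tt <- (sel - 1) / srate
  fit <- stats::lm(x[sel] ~ sin(2 * pi * f * tt) + cos(2 * pi * f * tt))
  sqrt(sum(stats::coef(fit)[2:3]^2))
}

test_that("high-pass filtering removes DC and leaves zero input at zero", {
  rec <- ContinuousRecording(matrix(100, 2, 250 * 60), srate = 250)
  for (spec in list(filterSpec("butterworth", 0.5),
                    filterSpec("fir_sinc", 0.5))) {
    out <- recordingData(highpassFilter(rec, spec))
    mid <- out[, 2000:13000]
    expect_lt(max(abs(mid)), 0.1)
  }
  z <- ContinuousRecording(matrix(0, 1, 1000), srate = 250)
  expect_equal(recordingData(highpassFilter(z, 1)), matrix(0, 1, 1000))
})

test_that("a sinusoid at the Butterworth cutoff is attenuated to 0.5 by the two passes", {
  srate <- 250; f <- 2
  tt <- (0:(srate * 40 - 1)) / srate
  rec <- ContinuousRecording(matrix(sin(2 * pi * f * tt), 1), srate = srate)
  out <- highpassFilter(rec, filterSpec("butterworth", cutoffHz = f))
  ratio <- .midAmplitude(recordingData(out)[1, ], f, srate)
  expect_lt(abs(ratio - 0.5), 0.01)  # -3 dB per pass, two passes
})

test_that("filters are linear and two-pass filtering has zero phase", {
  set.seed(40)
  srate <- 250
  x <- rnorm(5000); y <- rnorm(5000)
  mk <- function(v) ContinuousRecording(matrix(v, 1), srate = srate)
  f <- function(v, spec) recordingData(highpassFilter(mk(v), spec))[1, ]
  for (spec in list(filterSpec("butterworth", 1),
                    filterSpec("fir_sinc", 1))) {
    lhs <- f(2 * x - 3 * y, spec)
    rhs <- 2 * f(x, spec) - 3 * f(y, spec)
    expect_lt(max(abs(lhs - rhs)) / max(abs(lhs)), 1e-8)
  }
  # phase: an 8-Hz sinusoid keeps its phase within one sample
  f0 <- 8
  tt <- (0:(srate * 20 - 1)) / srate
  s <- sin(2 * pi * f0 * tt)
  out <- f(s, filterSpec("butterworth", 0.5))
  sel <- 1500:3500
  fit <- stats::lm(out[sel] ~ sin(2 * pi * f0 * tt[sel]) + cos(2 * pi * f0 * tt[sel]))
  phase <- atan2(stats::coef(fit)[3], stats::coef(fit)[2])
  expect_lt(abs(phase) / (2 * pi * f0), 1 / srate)
})

test_that("the notch suppresses 50 Hz by over 20 dB and spares 10 Hz within 5%", {
  srate <- 250
  tt <- (0:(srate * 10 - 1)) / srate
  for (kind in c("fir", "iir")) {
    r50 <- ContinuousRecording(matrix(sin(2 * pi * 50 * tt), 1), srate = srate)
    out50 <- .midAmplitude(recordingData(notchFilter(r50, kind = kind))[1, ],
                           50, srate)
    expect_lte(out50, 0.1)
    r10 <- ContinuousRecording(matrix(sin(2 * pi * 10 * tt), 1), srate = srate)
    out10 <- .midAmplitude(recordingData(notchFilter(r10, kind = kind))[1, ],
                           10, srate)
    expect_true(out10 >= 0.95 && out10 <= 1.05)
  }
  expect_error(notchFilter(ContinuousRecording(matrix(0, 1, 100), srate = 100),
                           band = c(48, 52)), "Nyquist|band")
})

test_that("re-referencing schemes behave as projections and hand examples", {
  rec <- ContinuousRecording(matrix(c(1, 2, 6), 3, 5), srate = 100,
                             channelLabels = c("C1", "C2", "C3"))
  med <- rereference(rec, "median")
  expect_equal(recordingData(med)[, 1], c(-1, 0, 4))

  set.seed(41)
  rnd <- ContinuousRecording(matrix(rnorm(40), 4, 10), srate = 100)
  avg1 <- rereference(rnd, "average")
  expect_lt(max(abs(colMeans(recordingData(avg1)))), 1e-9)
  avg2 <- rereference(avg1, "average")
  expect_equal(recordingData(avg2), recordingData(avg1), tolerance = 1e-12)

  expect_identical(recordingData(rereference(rnd, "none")), recordingData(rnd))
  sub <- rereference(rnd, c("Ch1", "Ch3"))
  expect_equal(recordingData(sub),
               sweep(recordingData(rnd), 2,
                     colMeans(recordingData(rnd)[c(1, 3), ])))
  expect_error(rereference(rnd, "Oz"), "unknown channel")

  # epoch sets are re-referenced trial by trial
  ep <- makeEpochSet(4, 6, 3)
  epAvg <- rereference(ep, "average")
  expect_lt(max(abs(apply(recordingData(epAvg), c(2, 3), mean))), 1e-9)
})

test_that("baseline subtraction removes the pre-stimulus mean", {
  ep <- EpochSet(array(c(2, 2, 4, 6), c(1, 4, 1)), times = (-2:1) / 100,
                 srate = 100)
  out <- baselineSubtract(ep, c(-0.02, 0))
  expect_equal(recordingData(out)[1, , 1], c(0, 0, 2, 4))

  const <- EpochSet(array(7, c(2, 5, 3)), times = (-4:0) / 100, srate = 100)
  expect_equal(max(abs(recordingData(baselineSubtract(const, c(-0.04, 0))))), 0)

  set.seed(42)
  zm <- makeEpochSet(2, 6, 4, t0 = -6 / 250)
  dat <- recordingData(zm)
  for (ch in 1:2) for (tr in 1:4)  # make the baseline-interval mean exactly 0
    dat[ch, , tr] <- dat[ch, , tr] - mean(dat[ch, 1:3, tr])
  zm <- initialize(zm, data = dat)
  out2 <- baselineSubtract(zm, c(epochTimes(zm)[1], epochTimes(zm)[4]))
  expect_equal(recordingData(out2), recordingData(zm), tolerance = 1e-12)

  expect_error(baselineSubtract(ep, c(-0.5, 0)), "outside")
  expect_error(baselineSubtract(ep, c(-0.01, 0.01)), "pre-stimulus")
})

test_that("line-noise channel detection flags exactly the contaminated channel", {
  srate <- 250
  tt <- (0:(srate * 20 - 1)) / srate
  set.seed(43)
  base <- matrix(rnorm(8 * length(tt)), 8)
  same <- ContinuousRecording(matrix(rep(sin(2 * pi * 7 * tt), each = 8) +
                                       1, 8, length(tt), byrow = FALSE),
                              srate = srate)
  expect_length(detectLineNoiseChannels(same), 0)

  noisy <- base
  rms <- sqrt(mean(base[3, ]^2))
  noisy[3, ] <- noisy[3, ] + 10 * rms * sqrt(2) * sin(2 * pi * 50 * tt)
  rec <- ContinuousRecording(noisy, srate = srate)
  flagged <- detectLineNoiseChannels(rec)  # default threshold of 4 SD
  expect_identical(as.integer(flagged), 3L)

  expect_error(detectLineNoiseChannels(
    ContinuousRecording(matrix(rnorm(300), 3), srate = 100)), "4 channels")
  expect_error(detectLineNoiseChannels(rec, lineHz = 200), "Nyquist")
})

test_that("spherical-spline interpolation reproduces smooth fields", {
  set.seed(44)
  pos <- erpsig:::.spiralPositions(32)
  # constant field: interpolating any channel reproduces it near-exactly
  const <- ContinuousRecording(matrix(5, 32, 10), srate = 100,
                               channelPositions = pos)
  out <- interpolateChannels(const, 7)
  expect_lt(max(abs(recordingData(out)[7, ] - 5)) / 5, 1e-6)

  # smooth dipolar topography vs an inverse-distance-weighted oracle
  dipole <- function(p) p %*% c(0.4, -0.2, 0.9)
  field <- as.vector(dipole(pos))
  tc <- seq(0, 1, length.out = 20)
  dat <- outer(field, tc)  # topography scaled over time
  rec <- ContinuousRecording(dat, srate = 100, channelPositions = pos)
  bad <- c(5, 18)
  interp <- recordingData(interpolateChannels(rec, bad))
  idw <- function(b) {
    good <- setdiff(1:32, bad)
    w <- 1 / (colSums((t(pos[good, ]) - pos[b, ])^2) + 1e-9)
    colSums(dat[good, ] * w) / sum(w)
  }
  for (b in bad) {
    expect_gt(stats::cor(interp[b, -1], idw(b)[-1]), 0.95)
    expect_lt(max(abs(interp[b, ] - dat[b, ])), 0.25 * max(abs(dat)))
  }
  # untouched channels, count and order preserved
  expect_identical(interp[-bad, ], dat[-bad, ])
  expect_identical(dim(interp), dim(dat))

  expect_identical(recordingData(interpolateChannels(rec, integer(0))), dat)
  expect_error(interpolateChannels(rec, 1:32), "all channels")
})

test_that("amplitude-threshold trial rejection counts and drops the right trials", {
  set.seed(45)
  dat <- array(rnorm(2 * 10 * 10), c(2, 10, 10))
  dat[1, , 4] <- seq(0, 300, length.out = 10)  # one 300-uV swing
  ep <- EpochSet(dat, times = (0:9) / 100, srate = 100)

  none <- rejectTrialsPeakToPeak(ep, thresholdUv = 1e9)
  expect_equal(none$rejectedFraction, 0)
  expect_equal(nTrials(none$epochs), 10)

  for (mode in c("abs", "ptp")) {
    r <- rejectTrialsPeakToPeak(ep, thresholdUv = 200, mode = mode)
    expect_identical(r$rejected, 4L)
    expect_equal(r$rejectedFraction, 0.1)
    expect_equal(nTrials(r$epochs), 9)
  }
  expect_error(rejectTrialsPeakToPeak(ep, thresholdUv = -5), "positive")
})
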