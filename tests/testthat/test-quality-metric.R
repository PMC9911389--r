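test_that("identical trial arrays give 0% significant channels", {
  set.seed(10)
  ep <- makeEpochSet(6, 12, 25)
  expect_equal(channelSignificance(ep, ep, fullWindow(ep)), 0)
})

test_that("channel significance matches an independent t-test oracle on fixed arrays", {
  set.seed(11)
  a <- makeEpochSet(4, 10, 50)
  b <- makeEpochSet(4, 10, 50, shift = 5, shiftChannels = 1:2)
  win <- fullWindow(a)
  pct <- channelSignificance(a, b, win)
  expect_equal(pct, 50)

  # brute-force oracle: stats::t.test per channel on the window means
  Wa <- apply(recordingData(a), c(1, 3), mean)
  Wb <- apply(recordingData(b), c(1, 3), mean)
  oracle <- mean(vapply(1:4, function(ch)
    stats::t.test(Wa[ch, ], Wb[ch, ], var.equal = TRUE)$p.value < 0.05,
    logical(1))) * 100
  expect_equal(pct, oracle)

  # Welch variant agrees with its own oracle
  pctW <- channelSignificance(a, b, win, varEqual = FALSE)
  oracleW <- mean(vapply(1:4, function(ch)
    stats::t.test(Wa[ch, ], Wb[ch, ])$p.value < 0.05, logical(1))) * 100
  expect_equal(pctW, oracleW)
})

test_that("channel significance is invariant to rescaling, channel permutation and trial order", {
  set.seed(12)
  a <- makeEpochSet(5, 8, 30)
  b <- makeEpochSet(5, 8, 30, shift = 0.6, shiftChannels = c(2, 4))
  win <- fullWindow(a)
  base <- channelSignificance(a, b, win)

  scale10 <- function(ep) initialize(ep, data = recordingData(ep) * 10)
  expect_identical(channelSignificance(scale10(a), scale10(b), win), base)

  perm <- c(3, 1, 5, 2, 4)
  permute <- function(ep) initialize(ep, data = recordingData(ep)[perm, , ],
                                     channelLabels = channelLabels(ep)[perm])
  expect_identical(channelSignificance(permute(a), permute(b), win), base)

  shuffle <- function(ep, ord) initialize(ep, data = recordingData(ep)[, , ord])
  expect_equal(channelSignificance(shuffle(a, sample(30)), b, win), base)
})

test_that("degenerate zero-variance channels follow the t = 0 convention", {
  flat <- function(v) EpochSet(array(v, c(1, 4, 3)), times = (0:3) / 100,
                               srate = 100)
  win <- c(0, 0.04)
  expect_equal(channelSignificance(flat(2), flat(2), win), 0)    # equal means
  expect_equal(channelSignificance(flat(2), flat(5), win), 100)  # shifted
})

test_that("mismatched channels or too few trials are errors", {
  set.seed(13)
  a <- makeEpochSet(3, 6, 10)
  b <- makeEpochSet(4, 6, 10)
  expect_error(channelSignificance(a, b, fullWindow(a)), "mismatched channels")
  one <- makeEpochSet(3, 6, 1)
  expect_error(channelSignificance(a, one, fullWindow(a)), "at least 2 trials")
  expect_error(metricConfig(nResample = 1), "nResample")
})

test_that("a single bootstrap repetition reproduces one explicit resample", {
  set.seed(14)
  a <- makeEpochSet(6, 10, 18)
  b <- makeEpochSet(6, 10, 15, shift = 0.5, shiftChannels = 1:3)
  cfg <- metricConfig(window = fullWindow(a), nResample = 8, nBoot = 1,
                      seed = 77)
  r <- resampledMetric(a, b, cfg)
  # the documented draw order: condition A indices, then condition B
  set.seed(77)
  ia <- sample.int(18, 8, replace = TRUE)
  ib <- sample.int(15, 8, replace = TRUE)
  sub <- function(ep, idx) initialize(ep, data = recordingData(ep)[, , idx])
  expect_equal(metricValue(r),
               channelSignificance(sub(a, ia), sub(b, ib), fullWindow(a)))
})

test_that("the metric is deterministic given config and seed", {
  set.seed(15)
  a <- makeEpochSet(5, 10, 20)
  b <- makeEpochSet(5, 10, 20, shift = 0.4, shiftChannels = 1:2)
  cfg <- metricConfig(window = fullWindow(a), nBoot = 300, nResample = 10,
                      seed = 5)
  r1 <- resampledMetric(a, b, cfg)
  r2 <- resampledMetric(a, b, cfg)
  expect_identical(metricValue(r1), metricValue(r2))
  expect_identical(r1@nTrialsUsed, c(20L, 20L))
})

test_that("all-trials mode coincides with the fixed draw when pool sizes equal nResample", {
  set.seed(16)
  a <- makeEpochSet(4, 8, 50)
  b <- makeEpochSet(4, 8, 50, shift = 0.3, shiftChannels = 1)
  cfg <- metricConfig(window = fullWindow(a), nResample = 50, nBoot = 150,
                      seed = 9)
  expect_identical(metricValue(resampledMetric(a, b, cfg)),
                   metricValue(allTrialsMetric(a, b, cfg)))
  expect_identical(allTrialsMetric(a, b, cfg)@mode, "all_trials")
})

test_that("bootstrap mean matches the exhaustive 81-outcome enumeration", {
  set.seed(17)
  a <- makeEpochSet(3, 6, 3)
  b <- makeEpochSet(3, 6, 3, shift = 1.5, shiftChannels = 1)
  win <- fullWindow(a)
  sub <- function(ep, idx) initialize(ep, data = recordingData(ep)[, , idx])
  draws <- expand.grid(a1 = 1:3, a2 = 1:3, b1 = 1:3, b2 = 1:3)
  exact <- mean(apply(draws, 1, function(d)
    channelSignificance(sub(a, d[1:2]), sub(b, d[3:4]), win)))
  cfg <- metricConfig(window = win, nResample = 2, nBoot = 4000, seed = 3)
  r <- resampledMetric(a, b, cfg)
  expect_lt(abs(metricValue(r) - exact), 3 * attr(r, "mcse"))
})

test_that("subsampling without replacement calibrates to the test level under the null", {
  # drawing m of n trials without replacement makes each repetition an exact
  # level-alpha t-test, so the metric's expectation is 100 * alpha
  set.seed(18)
  cfg <- metricConfig(window = c(0, 0.04), nResample = 20, nBoot = 1200,
                      replace = FALSE, seed = 41)
  vals <- vapply(1:12, function(i) {
    p <- makeNullPair(nCh = 24, nTime = 10, nTrials = 60)
    metricValue(resampledMetric(p$a, p$b, initialize(cfg, window = fullWindow(p$a))))
  }, numeric(1))
  expect_lt(abs(mean(vals) - 5), 1)
})

test_that("with-replacement resampling from a finite pool matches the two-stage oracle, not the nominal level", {
  set.seed(19)
  cfg <- metricConfig(nResample = 20, nBoot = 1200, seed = 42,
                      window = c(0, 1))
  vals <- vapply(1:12, function(i) {
    p <- makeNullPair(nCh = 24, nTime = 10, nTrials = 60)
    metricValue(resampledMetric(p$a, p$b, initialize(cfg, window = fullWindow(p$a))))
  }, numeric(1))
  predicted <- expectedMetric(d = 0, nResample = 20, poolSize = 60)
  expect_gt(mean(vals), 7)  # visibly above the nominal 5%
  expect_lt(abs(mean(vals) - predicted), 1.5)
})

test_that("the metric never decreases along an effect-amplitude ladder", {
  set.seed(20)
  nCh <- 8; nTime <- 10; nTr <- 40
  noiseA <- array(rnorm(nCh * nTime * nTr), c(nCh, nTime, nTr))
  noiseB <- array(rnorm(nCh * nTime * nTr), c(nCh, nTime, nTr))
  tt <- (0:(nTime - 1)) / 250
  mk <- function(noise, amp) EpochSet(noise + amp, times = tt, srate = 250)
  cfg <- metricConfig(window = c(tt[1], tt[nTime] + 1 / 250), nResample = 20,
                      nBoot = 400, seed = 8)
  ladder <- vapply(c(0, 0.2, 0.45, 0.8), function(amp)
    metricValue(resampledMetric(mk(noiseA, 0), mk(noiseB, amp), cfg)),
    numeric(1))
  expect_true(all(diff(ladder) >= -1))  # 1 percentage-point slack
  expect_gt(ladder[4], ladder[1])
})
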