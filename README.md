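# erpsig

**erpsig** quantifies the quality of event-related potential (ERP) data
with a single task-relevant statistic: the bootstrap-resampled percentage
of EEG channels that show a significant evoked-potential difference between
two experimental conditions inside an automatically selected 100-ms
post-stimulus window. Because volume conduction spreads a genuine cortical
effect across the whole scalp, a clean recording should express a strong
condition difference on most electrodes; noise and harmful preprocessing
both erode that percentage. The package is aimed at EEG methodologists and
pipeline builders who want a reference-free, threshold-free way to compare
preprocessing choices (filtering, re-referencing, baseline correction,
artifact rejection) on their own data or on simulated cohorts.

## The statistic

For one subject with two condition epoch sets, each trial's potential is
averaged over the analysis window `[t₁, t₂)` per channel. In each of
`B = 20000` repetitions, `m = 50` trials are drawn with replacement from
each condition and each channel is tested with a two-sided unpaired
Student t-test (pooled variance, df = nₐ + n_b − 2) on the per-trial
window means:

    metric = (1/B) Σ_b 100 · #{channels with p < 0.05 in draw b} / #channels

one value per subject. The analysis window is selected by scanning 50-ms
bins across long (−1 to 2 s) epochs, computing the same statistic per bin,
taking the across-subject median curve, smoothing it with a length-3
moving average, and centering a 100-ms window on the maximum. Methods are
compared subject-paired: per-subject metric differences are bootstrapped
over subjects (20000 draws) to give a percentile CI and a two-sided
p-value (p ≤ 0.01 significant, 0.01 < p ≤ 0.05 a trend). Subjects losing
more than 75% of trials in any condition are excluded, and comparisons
with fewer than 4 retained subjects are not computed.

Everything needed to exercise the statistic without real recordings is
included: minimal preprocessing operators (zero-phase Butterworth and
windowed-sinc high-pass, FIR/IIR notch, average/median/channel-list
re-referencing, baseline subtraction, line-noise channel detection,
spherical-spline interpolation, amplitude-threshold trial rejection) and a
synthetic cohort generator (1/f background, drift, 50-Hz line, sparse
artifacts, Gaussian-bump condition effect on a smooth random topography)
with a closed-form expected-metric oracle.

## Worked example

```r
library(erpsig)
cfg <- syntheticConfig(nSubjects = 4, nChannels = 32, nTrials = 80, seed = 1)
cohort <- generateCohort(cfg)

# 1. scan long epochs for the latency of maximum effect
pairs3s <- epochPairs(cohort, tmin = -1, tmax = 2)
curve <- latencyScan(pairs3s, metricConfig(nResample = 50, nBoot = 300, seed = 2))
win <- findEffectWindow(curve)
win
#> EffectWindow: center 0.325 s, window [0.275, 0.375] s

# 2. per-subject quality metric in that window (1-s epochs)
mcfg <- metricConfig(window = win, nResample = 50, nBoot = 2000, seed = 3)
res <- cohortMetric(epochPairs(cohort), mcfg)
res[[1]]
#> MetricResult 'S01' [resample_50]: 63.70% significant channels
#>   (32 channels; 80/80 trials; alpha=0.05, nResample=50, nBoot=2000)
round(metricValues(res), 1)
#>  S01  S02  S03  S04
#> 63.7 49.9 79.0 30.2

# 3. does a 0.5-Hz high-pass help? (subject-paired bootstrap)
hp <- lapply(cohort, function(s)
  list(recording = highpassFilter(s$recording, 0.5), events = s$events))
hpRes <- cohortMetric(epochPairs(hp), mcfg)
cmp <- pairedBootstrapCompare(hpRes, res, comparisonConfig(seed = 4))
cmp
#> ComparisonResult: mean diff 18.14 pp, 95% CI [15.91, 20.69],
#>   p = 0.0001 (significant), 4 subjects
formatReport(cmp, names = "HP 0.5 Hz vs raw")$text
#> [1] "18% (p = 0.0001)"
```

The scan centered the effect window near the injected 0.35-s effect; the
per-subject metrics show how strongly each simulated subject expresses the
condition difference across the scalp; and high-pass filtering the drifting
raw data raises the metric by 18 percentage points — a significant gain
under the paired bootstrap.

A command-line interface wraps the same functions
(`exec/erpsig <convert|simulate|metric|scan|compare|preprocess>`), with
`--seed` governing all randomness; fixed seeds replay every output
byte-for-byte.

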