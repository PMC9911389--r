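---
title: "Counting significant channels: the erpsig data-quality metric"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Counting significant channels: the erpsig data-quality metric}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(erpsig)
```

## The statistic and its assumptions

EEG effects driven by cortical sources spread to essentially every scalp
electrode through volume conduction, so on clean data a genuine
condition difference should be detectable on most channels. `erpsig`
turns this into a quality metric: the percentage of channels whose
window-averaged potentials differ significantly between two conditions,
averaged over trial resamples.

For a subject with epoch arrays $X^{(a)}, X^{(b)}$ (channels × time ×
trials, µV), each trial is reduced to its mean potential over an analysis
window $[t_1, t_2)$. In each of $B$ repetitions, $m$ trials are drawn
with replacement from each condition's pool and every channel is tested
with a two-sided unpaired Student $t$-test (pooled variance,
$\mathrm{df} = n_a + n_b - 2$) at level $\alpha$; the repetition's score
is $100 \cdot \#\{\text{significant channels}\}/C$, and the metric is the
mean score over repetitions. Defaults are the reference protocol:
$\alpha = 0.05$, $m = 50$, $B = 20000$.

The assumptions are deliberately weak — within-condition exchangeability
of trials and enough trials for a $t$-test — which is what makes the
metric usable as a benchmark across preprocessing variants: it needs no
electrode montage, no reference choice, and no prior ERP template. Two
properties are exact by construction and tested as such: invariance to
global positive rescaling (t statistics are scale-free), to channel
permutation, and to trial order; and a zero-variance convention (a
degenerate channel with equal means counts non-significant, with unequal
means significant — the limit of the t-test as variance vanishes).

### Window selection

The analysis window is chosen from the data: long epochs (−1 to 2 s) are
scanned in 50-ms half-open bins stepped by 50 ms (60 bins), each
subject's metric is computed per bin, and the across-subject median curve
is smoothed with a centered length-3 moving average (truncated at the
edges, so the ends average the two available values). The bin with the
maximum smoothed median — earliest on ties — becomes the window center,
extended ±50 ms and clipped to the epoch with a warning if necessary. The
per-bin statistic is the mean over the bin (not a single sample): bin
means are noise-robust and consistent with how the final 100-ms window is
used. The across-subject spread is summarised by the unscaled median
absolute deviation, a purely descriptive quantity (no 1.4826 consistency
factor).

### Comparing preprocessing variants

Two variants are compared subject-paired: $d_i = a_i - b_i$ per retained
subject, the mean of $d$ bootstrapped by resampling subjects with
replacement ($B = 20000$), a percentile CI, and the two-sided p-value
$p = \max\!\big(2\min(P(\bar d^* \le 0), P(\bar d^* \ge 0)),\, 2/B\big)$
with ties counted in both tails. Effects with $p \le 0.01$ are reported
as significant, $0.01 < p \le 0.05$ as trends (an informal stand-in for a
Bonferroni-type correction when a figure carries fewer than five
comparisons), and effects are rounded to whole percents in the
human-readable report; raw p-values stay in the machine-readable output.
Subjects losing strictly more than 75% of trials in any condition under
either variant are excluded (exactly 75% is retained), and with fewer
than 4 retained subjects no significance is computed.

When a preprocessing variant removes trials, the fair question changes:
`allTrialsMetric()` draws as many trials as each condition still has, so
the cost of losing trials is part of the answer. With equal pool sizes of
50 it coincides with the default draw, which the tests assert.

## Calibration: what the resampled statistic does and does not promise

Drawing $m$ trials *with replacement* from a finite pool of $n$ is not a
calibrated level-$\alpha$ procedure, even under the null. Two effects
inflate the rejection rate: the resampled group means fluctuate around
the *pool* means (which differ by an $O(\sigma\sqrt{2/n})$ amount), and
duplicate trials make the within-resample variance estimate too small for
the actual dispersion of the resampled mean. To first order the
$t$-statistic is inflated by $\sqrt{1 + m/n}$, so the null expectation of
the metric sits well above $100\alpha$ for $m$ comparable to $n$ and
approaches $100\alpha$ only as the pool grows:

```{r null-inflation}
# first-order null rejection rate of the with-replacement scheme
inflate <- function(n, m, alpha = 0.05) {
  df <- 2 * (m - 1)
  kap <- sqrt(((n - 1) / n / m * 2) / (2 * (1 / n + (n - 1) / (n * m))))
  2 * pt(-qt(1 - alpha / 2, df) * kap, df)
}
sapply(c(50, 100, 500, 5000), inflate, m = 50)
```

This is inherent to the procedure, not an implementation artifact; it
cancels in paired comparisons, which is what the metric is for. The
package therefore (a) keeps the reference with-replacement draw as the
default, (b) exposes `replace = FALSE`, a subsampling variant for which
each repetition is an exact level-$\alpha$ test on iid trials (its null
calibration at $100\alpha$ is asserted in the test suite on iid-noise
cohorts), and (c) reports both calibrations in the acceptance script. On
realistic synthetic nulls even the subsampling variant drifts above
$100\alpha$, because long-memory 1/f noise correlates neighbouring
trials and artifact transients fatten the tails — a caveat that applies
equally to real EEG.

The subject-level bootstrap comparison has its own small-sample caveat:
the percentile p-value behaves like a $z$-test where a $t$-test is
needed, rejecting a true null at roughly
$2\,P\!\left(T_{s-1} > z_{\alpha/2}\sqrt{(s-1)/s}\right)$ for $s$
subjects:

```{r bootstrap-smalln}
typeI <- function(s, alpha = 0.05)
  2 * pt(-qnorm(1 - alpha / 2) * sqrt((s - 1) / s), s - 1)
sapply(c(8, 12, 16, 32, 64, 128), typeI)
```

Around cohort sizes typical of single-site EEG studies (8–18 subjects)
the realized type-I rate is 8–11% rather than 5%. The acceptance check of
the protocol's type-I control therefore runs in the large-cohort regime
(96-subject null cohorts), where the bootstrap is approximately
calibrated; the small-cohort behaviour above is a property users should
keep in mind when reading "significant" labels from small studies.

## The synthetic cohort generator

`generateSubject()` builds a continuous recording as a sum of independent
parts, each with a documented default chosen to mimic a mid-density
laboratory ERP study at 250 Hz:

* **1/f background** — spectral synthesis with amplitude
  $\propto f^{-\text{exponent}/2}$ (exponent 1), scaled to 10 µV RMS. The
  construction is circulant-stationary, so its autocovariance is known in
  closed form — the expected-metric oracle depends on this.
* **Slow drift** — noise shaped by $1/(1 + (f/f_c)^2)$ with corner
  0.05 Hz, 5 µV RMS by default (direction tests raise it to 20 µV, "drift
  comparable to the signal").
* **Line noise** — a 50-Hz sinusoid, 2 µV, random phase per channel; an
  optional set of "bad" channels carries 10× the amplitude for the
  detection operator to find.
* **Artifacts** — Poisson transients (2/min), Gaussian envelope of 0.3 s,
  ~100 µV, random smooth spatial profile; stand-ins for blinks and
  movement bursts (their waveform morphology is *not* modelled).
* **Evoked activity** — every event adds a fixed biphasic response (a
  negative deflection at 0.10 s and a positive one at 0.25 s, 4 µV peak
  scale) on its own smooth topography; condition "B" events additionally
  add the condition difference: a Gaussian bump at 0.35 s (SD 50 ms),
  6 µV, scaled by a per-subject amplitude (between-subject SD 1 µV), a
  ±20% uniform per-trial jitter, and a smooth random topography
  $w_c = 1 + 0.3\,g_c$ where $g$ is a unit Gaussian field with
  squared-exponential covariance (length 1 on the unit sphere) over a
  deterministic spherical-spiral electrode layout. The smooth, mostly
  same-sign topography is a cheap stand-in for volume conduction: the
  effect is visible on most channels, which is the premise the metric
  rests on.
* **Events** — the two conditions alternate pseudo-randomly with
  inter-stimulus intervals uniform in [1.8, 2.2] s, so default 1-s
  epochs never overlap (3-s scan epochs do, as they would in a real
  paradigm of this cadence); generation fails loudly if the effect bump
  cannot fit inside the minimum interval.

Channels' background noise is independent across the scalp; real EEG
noise is spatially correlated. This makes per-channel tests *more*
informative per channel than reality, so passing direction tests on
synthetic cohorts demonstrates the machinery and the signs of the
effects, not effect magnitudes on real data. Everything is deterministic
given `(seed, subjectIndex)`: subject $i$ runs on stream `seed + i`, so
per-subject data are reproducible independent of cohort order.

## The expected-metric oracle

On clean cohorts (no artifacts) the metric's expectation is computable
without simulation, and `expectedMetric()` does so in four steps:

1. **Window-mean noise variance** $\sigma_w^2$, exactly, from the
   generator's circulant spectrum (1/f plus drift):
   $\sigma_w^2 = m^{-2} \sum_{|k|<m}(m-|k|)\,r(k)$ for an $m$-sample
   window, $r$ the autocovariance at the realized recording length.
2. **Inter-trial correlation correction** — long-memory noise correlates
   trial window means; the mean pairwise covariance over the event design
   (events ~2 s apart) is subtracted, an equicorrelation approximation.
3. **Finite-pool resampling correction** — with replacement, the
   unconditional variance of a resampled group mean is
   $\sigma^2(1/n + (n-1)/(nm))$ while the variance estimate tracks
   $\sigma^2 (n-1)/n / m$; the tail probability is evaluated as a
   noncentral-$t$ with the critical value scaled accordingly. Without a
   pool size the classic iid power is returned (so a zero effect gives
   exactly $100\alpha$, and the single-channel case matches
   `stats::power.t.test`, which the tests assert).
4. **Per-channel effect sizes** — the realized topography and subject
   amplitude (ground truth from the generator) times the bump's
   window-mean, with the per-trial jitter entering the effect-bearing
   condition's variance.

The finite-pool correction is first order, so the oracle-agreement
acceptance check runs with 500 trials per condition — inside the
generator's realistic range — where the residual approximation error is
well under the 2-percentage-point tolerance; the unit suite separately
pins the with-replacement null level against the same oracle at small
pool sizes.

## Numerical and design choices

* **Indexing** — 0-based sample indices; half-open windows everywhere
  (epochs, analysis windows, scan bins, baselines); time 0 is the event
  sample. Event onsets given in seconds are rounded to the nearest sample
  (tools that require on-sample latencies otherwise fail after off-line
  resampling); rounding collisions are an error rather than a silent
  merge.
* **t-test variant** — pooled variance by default (`varEqual = FALSE`
  gives Welch); the resampled groups have equal size by design, where the
  pooled test is standard.
* **Resampling reproducibility** — one `sample.int` stream per subject,
  seeded `seed + subjectIndex`; condition A's indices are drawn before
  condition B's, which is the documented contract a single-repetition
  run reproduces.
* **Filters** — Butterworth high-pass (order 4 per pass) and
  Hamming-windowed sinc FIR, both applied forward and backward by default
  (zero phase; the −3 dB cutoff attenuation doubles to −6 dB). The FIR
  transition bandwidth defaults to min(cutoff, 1 Hz): a wider band
  centered on a sub-hertz cutoff would leave DC at the transition edge
  with only ~25 dB attenuation, defeating the filter's purpose. The FIR
  length is the Hamming rule 3.3·srate/transition, rounded to even order.
  Single-pass FIR application compensates the linear-phase group delay.
* **Notch** — FIR band-stop with 2-Hz transitions at passband edges
  48–52 Hz, or a Butterworth band-stop (order 2 per pass).
* **Line-noise channel detection** — Welch-style averaged periodogram
  (1-s Hann segments, 50% overlap), mean power in ±1 Hz around the mains
  frequency, robust z-score of log-power against the other channels
  (median / 1.4826·MAD), flag above 4 SD by default. Log power keeps the
  z-scores meaningful under the strong right skew of narrowband power; a
  zero MAD (identical channels) flags nothing.
* **Spherical splines** — Perrin-style order-4 splines, Legendre terms to
  degree 7, regularization λ = 1e-5, with the interpolation operator
  factored once and applied to all samples. A constant field is
  reproduced exactly regardless of λ.
* **Trial rejection** — "abs" mode (any |x| > T, a −T..+T range rule,
  default T = 200 µV) and "ptp" mode (max − min > T) are both provided;
  the range formulation is the default because thresholded pipelines are
  usually specified as a symmetric microvolt range.
* **Containers** — a single-file store with fixed field names (data,
  times, srate, labels, positions, condition, subject_id) via R's native
  serialization; round trips are bit-exact and missing fields are
  reported by name. The format is R-specific — a deliberate trade for
  zero extra dependencies — with delimited-text import (`erpsig convert`,
  BIDS-style `*_events.tsv`) as the interchange path.

## Problem sizes used by the tests

The test-suite study designs are scaled-down versions of a realistic
cohort, chosen once: null calibration uses 8 subjects × 64 channels × 100
trials/condition (2000 resamples); oracle agreement 8 × 16 × 500 (1000
resamples); window recovery 40 cohorts of 3 × 24 × 50; preprocessing
direction tests a 12-subject, 32-channel, 60-trial cohort with 20-µV
drift; the comparison type-I sweep 600 null cohorts of 96 subjects with
reduced bootstrap depths. The acceptance script reruns the same designs
end to end and writes every quantity it computes to JSON.

## Known limitations

* Channel noise is spatially white; real EEG noise correlates across the
  scalp and with its sources, so absolute metric levels on synthetic data
  do not transfer to real recordings (directions of preprocessing effects
  are the transferable part).
* Artifact transients have realistic amplitude and sparsity but not
  blink/EMG morphology or frontal topographic structure.
* The oracle covers the clean regime only and refuses cohorts with
  artifacts; drift is handled analytically, line noise is ignored (a
  50-Hz sinusoid averages out over 100-ms windows at 250 Hz).
* The with-replacement metric is a *relative* instrument: its absolute
  level depends on trial counts (see the calibration section), so metric
  values should only be compared at matched pool sizes — which the
  all-trials mode and the exclusion rules are there to enforce.
* No multiple-comparison correction is applied across channels (by
  design, matching the reference protocol) or across comparisons (the
  trend band is the only guard).
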