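Package: erpsig
Title: Bootstrap Significance Metric for ERP Data Quality
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Quantifies the quality of event-related potential (ERP) data as
    the bootstrap-resampled percentage of EEG channels showing a significant
    evoked-potential difference between two experimental conditions within an
    automatically selected 100-ms window. Provides the trial-resampling
    statistic with per-channel unpaired t-tests, a latency scan with
    median/MAD summaries and maximum-effect window selection, a
    subject-paired bootstrap protocol for comparing preprocessing variants,
    the minimal preprocessing operators needed to benchmark them (zero-phase
    high-pass and notch filters, re-referencing, baseline subtraction,
    line-noise channel detection, spherical-spline interpolation,
    peak-to-peak trial rejection), and a synthetic multichannel EEG cohort
    generator with a closed-form expected-metric oracle.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    signal,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    knitr
biocViews: Software, Electrophysiology, QualityControl, StatisticalMethod
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllClasses.R'
    'AllGenerics.R'
    'accessors.R'
    'data-model.R'
    'metric.R'
    'scan.R'
    'compare.R'
    'preprocess.R'
    'interpolate.R'
    'synthetic.R'
    'oracle.R'
    'cli.R'
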