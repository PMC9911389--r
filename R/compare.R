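## Subject-paired bootstrap comparison of two preprocessing variants.

#' Apply the subject-exclusion rule for trial rejection
#'
#' A subject is excluded when strictly more than
#' \code{cfg@trialRejectionExclusionFrac} (default 75\%) of their trials
#' were rejected in any condition under either method; exactly 75\% is
#' retained. Exclusions are recorded with reasons.
#'
#' @param aResults,bResults lists of \linkS4class{MetricResult} for the two
#'   preprocessing variants, aligned by subject.
#' @param rejectedFrac data.frame with columns \code{subject_id} and
#'   \code{frac} (one row per subject x condition x method; extra columns
#'   are ignored), or NULL when no trials were rejected.
#' @param cfg a \linkS4class{ComparisonConfig}.
#' @return list with \code{retained} (subject ids) and \code{excluded}
#'   (data.frame subject_id, reason).
#' @export
applyExclusions <- function(aResults, bResults, rejectedFrac = NULL,
                            cfg = comparisonConfig()) {
  idsA <- vapply(aResults, function(r) r@subjectId, character(1))
  idsB <- vapply(bResults, function(r) r@subjectId, character(1))
  if (!identical(idsA, idsB))
    stop("result lists are not aligned by subject_id")
  excluded <- data.frame(subject_id = character(0), reason = character(0))
  bad <- character(0)
  if (!is.null(rejectedFrac) && nrow(rejectedFrac)) {
    stopifnot(all(c("subject_id", "frac") %in% names(rejectedFrac)))
    over <- rejectedFrac$frac > cfg@trialRejectionExclusionFrac
    bad <- unique(rejectedFrac$subject_id[over])
    if (length(bad))
      excluded <- data.frame(subject_id = bad,
                             reason = sprintf("trials_rejected>%d%%",
                                              round(100 * cfg@trialRejectionExclusionFrac)))
  }
  list(retained = setdiff(idsA, bad), excluded = excluded)
}

#' Subject-paired bootstrap comparison of two methods
#'
#' Computes per-subject differences d_i = a_i - b_i of the metric under two
#' preprocessing variants and bootstraps the mean difference by resampling
#' subjects (cases) with replacement \code{cfg@nBoot} times. The percentile
#' interval gives the CI; the two-sided p-value is
#' 2 min(P(mean* <= 0), P(mean* >= 0)) with ties included in both counts,
#' floored at 2/nBoot and capped at 1. This mirrors a paired t-test without
#' assuming normality. Labels: p <= 0.01 "significant", 0.01 < p <= 0.05
#' "trend", otherwise "ns". With fewer than \code{cfg@minSubjects} retained
#' subjects no significance is computed (label "not_computed").
#'
#' @param aVals,bVals aligned per-subject percentages (named numeric), or
#'   lists of \linkS4class{MetricResult}.
#' @param cfg a \linkS4class{ComparisonConfig}.
#' @param excluded optional data.frame(subject_id, reason) carried into the
#'   result (from \code{\link{applyExclusions}}).
#' @return a \linkS4class{ComparisonResult}.
#' @examples
#' a <- c(s1 = 60, s2 = 65, s3 = 58, s4 = 72, s5 = 66)
#' b <- a - 10
#' pairedBootstrapCompare(a, b, comparisonConfig(nBoot = 2000, seed = 1))
#' @export
pairedBootstrapCompare <- function(aVals, bVals, cfg = comparisonConfig(),
                                   excluded = NULL) {
  if (is.list(aVals) && length(aVals) && is(aVals[[1]], "MetricResult"))
    aVals <- metricValues(aVals)
  if (is.list(bVals) && length(bVals) && is(bVals[[1]], "MetricResult"))
    bVals <- metricValues(bVals)
  if (length(aVals) != length(bVals))
    stop("aVals and bVals must be aligned per subject")
  if (is.null(excluded))
    excluded <- data.frame(subject_id = character(0), reason = character(0))
  ids <- names(aVals)
  if (is.null(ids)) ids <- paste0("subject", seq_along(aVals))
  badA <- which(!is.finite(aVals))
  badB <- which(!is.finite(bVals))
  if (length(badA) || length(badB))
    stop(sprintf("non-finite metric value for subject(s): %s",
                 paste(unique(ids[union(badA, badB)]), collapse = ", ")))
  d <- as.numeric(aVals) - as.numeric(bVals)
  names(d) <- ids
  n <- length(d)
  if (n < cfg@minSubjects) {
    return(new("ComparisonResult", perSubjectDiff = d, meanDiff = NA_real_,
               ci95 = c(NA_real_, NA_real_), pValue = NA_real_,
               label = "not_computed", excludedSubjects = excluded))
  }
  set.seed(cfg@seed)
  idx <- matrix(sample.int(n, n * cfg@nBoot, replace = TRUE), n, cfg@nBoot)
  bootMeans <- colMeans(matrix(d[idx], n, cfg@nBoot))
  alphaCI <- (1 - cfg@ciLevel) / 2
  ci <- unname(stats::quantile(bootMeans, c(alphaCI, 1 - alphaCI)))
  p <- 2 * min(mean(bootMeans <= 0), mean(bootMeans >= 0))
  p <- min(max(p, 2 / cfg@nBoot), 1)
  label <- if (p <= cfg@trendBand[1]) "significant"
           else if (p <= cfg@trendBand[2]) "trend"
           else "ns"
  new("ComparisonResult", perSubjectDiff = d, meanDiff = mean(d),
      ci95 = ci, pValue = p, label = label, excludedSubjects = excluded)
}

#' Format comparison results for reporting
#'
#' Builds a machine-readable table (raw uncorrected p-values included) and a
#' human-readable line per comparison. Significant effects are rounded to
#' the nearest percent; p-values in (0.01, 0.05] are flagged as trends and
#' never reported as significant; p > 0.05 is reported as "ns" with no
#' highlighted effect size. P-values are uncorrected; the trend band stands
#' in for a Bonferroni-type correction when a figure shows fewer than five
#' comparisons (carried as the table's \code{note} attribute).
#'
#' @param results a \linkS4class{ComparisonResult} or list of them.
#' @param names optional comparison names.
#' @return data.frame with columns name, mean_diff, effect_pct (rounded,
#'   NA unless significant or trend), ci_low, ci_high, p_value, label,
#'   n_subjects, text; attribute \code{note} documents the p-value
#'   convention.
#' @examples
#' r <- pairedBootstrapCompare(c(a1 = 72, a2 = 75, a3 = 70, a4 = 74),
#'                             c(a1 = 60, a2 = 62, a3 = 59, a4 = 61),
#'                             comparisonConfig(nBoot = 1000, seed = 3))
#' formatReport(r)$text
#' @export
formatReport <- function(results, names = NULL) {
  if (is(results, "ComparisonResult")) results <- list(results)
  if (is.null(names))
    names <- paste0("comparison", seq_along(results))
  rows <- lapply(seq_along(results), function(i) {
    r <- results[[i]]
    if (r@label == "not_computed") {
      return(data.frame(name = names[i], mean_diff = NA_real_,
                        effect_pct = NA_real_, ci_low = NA_real_,
                        ci_high = NA_real_, p_value = NA_real_,
                        label = r@label, n_subjects = length(r@perSubjectDiff),
                        text = "not computed (fewer than the minimum retained subjects)"))
    }
    eff <- round(r@meanDiff)
    txt <- switch(r@label,
      significant = sprintf("%d%% (p = %.3g)", eff, r@pValue),
      trend = sprintf("%d%% (trend, p = %.3g)", eff, r@pValue),
      ns = sprintf("ns (p = %.3g)", r@pValue))
    data.frame(name = names[i], mean_diff = r@meanDiff,
               effect_pct = if (r@label %in% c("significant", "trend")) eff else NA_real_,
               ci_low = r@ci95[1], ci_high = r@ci95[2], p_value = r@pValue,
               label = r@label, n_subjects = length(r@perSubjectDiff),
               text = txt)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "note") <- paste(
    "p-values are uncorrected; effects with p <= 0.01 are reported as",
    "significant, p in (0.01, 0.05] as trends (a stand-in for a",
    "Bonferroni-type correction when fewer than 5 comparisons are shown",
    "together); p > 0.05 is never reported as significant.")
  out
}
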