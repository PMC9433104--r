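#' Immunohistochemistry H score
#'
#' Weighted staining score for a biopsy read in 10% increments:
#' `pct_mild * 1 + pct_moderate * 2 + pct_intense * 3`, ranging from 0
#' (no tumor cell stains at any intensity) to 300 (100% intense staining).
#'
#' @param pct_mild,pct_moderate,pct_intense Percentages of tumor cells
#'   staining at mild, moderate and intense intensity. Each must lie in
#'   `[0, 100]` and, per record, the three must sum to at most 100.
#' @return Numeric H score(s) in `[0, 300]`. Vectorized over records.
#' @examples
#' h_score(0, 0, 0)     # 0: fully negative case
#' h_score(0, 0, 100)   # 300: maximum attainable
#' h_score(20, 30, 10)  # 110
#' @export
h_score <- function(pct_mild, pct_moderate, pct_intense) {
  p <- cbind(pct_mild, pct_moderate, pct_intense)
  if (anyNA(p)) stop("staining percentages must not be missing")
  if (any(p < 0) || any(p > 100))
    stop("each staining percentage must lie in [0, 100]")
  tot <- rowSums(p)
  if (any(tot > 100 + 1e-8))
    stop("staining percentages sum to more than 100 in at least one record")
  as.numeric(p %*% c(1, 2, 3))
}

#' ROC-based cutoff selection for a continuous score
#'
#' Selects a dichotomizing cutoff from the empirical ROC of `scores` against
#' binary `labels` (1 = positive class, predicted positive when
#' `score >= cutoff`). Candidate cutoffs are midpoints between consecutive
#' sorted unique scores. Two modes:
#' \describe{
#'   \item{`youden`}{maximize sensitivity + specificity - 1; ties broken
#'     toward the lower cutoff.}
#'   \item{`target_specificity`}{smallest cutoff whose specificity is at
#'     least `target`.}
#' }
#'
#' @param scores Numeric scores.
#' @param labels Binary labels (0/1 or logical), both classes present.
#' @param mode "youden" or "target_specificity".
#' @param target Required specificity for `target_specificity` mode.
#' @return List with `cutoff`, `sensitivity`, `specificity`, `mode`.
#' @export
roc_cutoff <- function(scores, labels,
                       mode = c("youden", "target_specificity"),
                       target = 0.94) {
  mode <- match.arg(mode)
  scores <- as.numeric(scores)
  labels <- as.integer(as.logical(labels))
  if (length(scores) != length(labels)) stop("scores/labels length mismatch")
  if (anyNA(scores) || anyNA(labels)) stop("missing values are not allowed")
  if (length(unique(labels)) < 2L)
    stop("both classes must be present to compute a ROC")
  u <- sort(unique(scores))
  if (length(u) < 2L)
    stop("degenerate score set: all scores identical, no cutoff exists")
  cand <- (u[-length(u)] + u[-1L]) / 2
  sens <- vapply(cand, function(cc) mean(scores[labels == 1L] >= cc), 1)
  spec <- vapply(cand, function(cc) mean(scores[labels == 0L] < cc), 1)
  if (mode == "youden") {
    j <- sens + spec - 1
    # candidates ascend, so the first (near-)maximal J is the lowest cutoff;
    # the tolerance absorbs float noise between tied confusion tables
    i <- which(j >= max(j) - 1e-9)[1L]
  } else {
    ok <- which(spec >= target)
    if (length(ok) == 0L)
      stop(sprintf("no cutoff reaches specificity >= %.3f", target))
    i <- ok[1L]
  }
  list(cutoff = cand[i], sensitivity = sens[i], specificity = spec[i],
       mode = mode)
}

#' Kaplan-Meier survival curve
#'
#' Product-limit estimator with right censoring. The median is reported by
#' the convention "first time at which S(t) <= 0.5", undefined (`NA`) when
#' the curve never reaches 0.5.
#'
#' @param times Non-negative follow-up times.
#' @param events Event indicators (1 = event, 0 = censored).
#' @return An object of class `km_curve`: data frame `curve` with columns
#'   `time`, `n_risk`, `n_event`, `surv`, plus `median` and `n`.
#' @examples
#' km_estimate(c(1, 2, 3), c(1, 1, 1))$curve$surv  # 2/3, 1/3, 0
#' @export
km_estimate <- function(times, events) {
  times <- as.numeric(times); events <- as.integer(events)
  if (length(times) < 1L) stop("need at least one observation")
  if (any(times < 0)) stop("negative survival times")
  if (length(events) != length(times) || !all(events %in% c(0L, 1L)))
    stop("events must be 0/1 and match 'times' in length")
  fit <- survival::survfit(survival::Surv(times, events) ~ 1,
                           conf.type = "none")
  curve <- data.frame(time = fit$time, n_risk = fit$n.risk,
                      n_event = fit$n.event, surv = fit$surv)
  below <- which(curve$surv <= 0.5 & curve$n_event > 0)
  med <- if (length(below)) curve$time[below[1L]] else NA_real_
  structure(list(curve = curve, median = med, n = length(times)),
            class = "km_curve")
}

#' @export
print.km_curve <- function(x, ...) {
  cat(sprintf("Kaplan-Meier curve: n = %d, median = %s\n", x$n,
              if (is.na(x$median)) "not reached" else format(x$median)))
  invisible(x)
}

#' Two-group log-rank test
#'
#' Standard observed-minus-expected log-rank statistic over the pooled event
#' times, referred to chi-square with 1 df. A cohort with no events at all
#' is flagged and returns p = 1.
#'
#' @param times,events Follow-up times and 0/1 event indicators.
#' @param group Two-level grouping vector aligned with `times`.
#' @return A `timing_test` list (`statistic` is the chi-square).
#' @export
logrank_test <- function(times, events, group) {
  times <- as.numeric(times); events <- as.integer(events)
  group <- as.factor(group)
  if (nlevels(droplevels(group)) != 2L) stop("exactly two non-empty groups required")
  if (length(times) != length(group)) stop("length mismatch")
  n <- as.vector(table(droplevels(group)))
  if (sum(events) == 0L)
    return(new_timing_test(0, 1, "logrank", n, flag = "no_events"))
  sd <- survival::survdiff(survival::Surv(times, events) ~ group)
  stat <- unname(sd$chisq)
  new_timing_test(stat, stats::pchisq(stat, df = 1, lower.tail = FALSE),
                  "logrank", n)
}

#' Progression-free survival stratified by H score
#'
#' Splits a cohort at an H-score cutoff (high: `h_score >= cutoff`), fits a
#' Kaplan-Meier curve per stratum, and compares the strata with the log-rank
#' test.
#'
#' @param cohort A data frame with columns `h_score`, `pfs_months`, `event`
#'   (for example from [simulate_clinical_cohort()] or [read_cohort_csv()]).
#' @param cutoff H-score cutoff in `[0, 300]`. Default 80.
#' @return List: `km_high`, `km_low` (class `km_curve`), `median_high`,
#'   `median_low`, `logrank` (`timing_test`), `cutoff`, `n_high`, `n_low`.
#' @export
stratified_pfs <- function(cohort, cutoff = 80) {
  stopifnot(is.data.frame(cohort),
            all(c("h_score", "pfs_months", "event") %in% names(cohort)))
  if (cutoff < 0 || cutoff > 300) stop("cutoff must lie in [0, 300]")
  high <- cohort$h_score >= cutoff
  if (!any(high) || all(high))
    stop(sprintf("cutoff %.1f leaves an empty stratum (%d/%d high)",
                 cutoff, sum(high), nrow(cohort)))
  km_high <- km_estimate(cohort$pfs_months[high], cohort$event[high])
  km_low <- km_estimate(cohort$pfs_months[!high], cohort$event[!high])
  lr <- logrank_test(cohort$pfs_months, cohort$event,
                     ifelse(high, "high", "low"))
  list(km_high = km_high, km_low = km_low,
       median_high = km_high$median, median_low = km_low$median,
       logrank = lr, cutoff = cutoff,
       n_high = sum(high), n_low = sum(!high))
}

#' Read a clinical cohort CSV
#'
#' Expects columns `patient_id`, `pct_mild`, `pct_moderate`, `pct_intense`,
#' `response`, `pfs_months`, `event`; computes `h_score` if absent.
#'
#' @param path Path to a CSV file.
#' @return Data frame with an `h_score` column.
#' @export
read_cohort_csv <- function(path) {
  x <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("pct_mild", "pct_moderate", "pct_intense", "pfs_months", "event")
  if (!all(need %in% names(x)))
    stop("cohort CSV is missing columns: ",
         paste(setdiff(need, names(x)), collapse = ", "))
  if (!"h_score" %in% names(x))
    x$h_score <- h_score(x$pct_mild, x$pct_moderate, x$pct_intense)
  x
}
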