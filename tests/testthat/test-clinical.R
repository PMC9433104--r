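test_that("H score follows the weighted staining formula", {
  expect_equal(h_score(0, 0, 0), 0)
  expect_equal(h_score(0, 0, 100), 300)
  expect_equal(h_score(20, 30, 10), 110)
  expect_equal(h_score(100, 0, 0), 100)
  # additive in components, monotone when mass moves up in intensity
  expect_equal(h_score(10, 20, 30) - h_score(10, 20, 0), 90)
  expect_gt(h_score(0, 10, 20), h_score(10, 20, 0))
  expect_error(h_score(60, 30, 20), "sum")
  expect_error(h_score(-5, 0, 0), "\\[0, 100\\]")
})

test_that("ROC cutoff: youden equals exhaustive search, target-specificity honors its bound", {
  r <- roc_cutoff(c(1, 2, 10, 11), c(0, 0, 1, 1))
  expect_equal(r$cutoff, 6)
  expect_equal(r$sensitivity, 1)
  expect_equal(r$specificity, 1)
  expect_error(roc_cutoff(rep(5, 6), c(0, 0, 0, 1, 1, 1)), "degenerate")

  set.seed(11)
  for (i in 1:20) {
    scores <- round(runif(30, 0, 300), 1)
    labels <- rbinom(30, 1, plogis((scores - 150) / 60))
    if (length(unique(labels)) < 2) next
    got <- roc_cutoff(scores, labels, mode = "youden")
    expect_equal(got$cutoff, roc_youden_oracle(scores, labels))
    ts <- tryCatch(roc_cutoff(scores, labels, mode = "target_specificity",
                              target = 0.94),
                   error = function(e) NULL)
    if (!is.null(ts)) {
      expect_gte(ts$specificity, 0.94)
      # smallest qualifying cutoff: direct check
      expect_equal(ts$specificity,
                   mean(scores[labels == 0] < ts$cutoff))
    }
  }
})

test_that("Kaplan-Meier estimator matches closed form and a brute-force oracle", {
  km <- km_estimate(c(1, 2, 3), c(1, 1, 1))
  expect_equal(km$curve$surv, c(2 / 3, 1 / 3, 0))
  expect_equal(km$median, 2)

  all_cens <- km_estimate(c(4, 6, 9), c(0, 0, 0))
  expect_true(all(all_cens$curve$surv == 1))
  expect_true(is.na(all_cens$median))

  set.seed(21)
  for (i in 1:10) {
    n <- sample(4:12, 1)
    times <- round(rexp(n, 0.2), 2)
    events <- rbinom(n, 1, 0.7)
    if (sum(events) == 0) next
    km <- km_estimate(times, events)
    oracle <- km_oracle(times, events)
    got <- km$curve[km$curve$n_event > 0, c("time", "surv")]
    rownames(got) <- NULL
    expect_equal(got, oracle, tolerance = 1e-12)
  }
  expect_error(km_estimate(c(-1, 2), c(1, 1)), "negative")
})

test_that("log-rank test is symmetric, degenerate-safe, and near its permutation null", {
  t1 <- c(1, 3, 5, 7); e1 <- c(1, 1, 0, 1)
  t2 <- c(2, 4, 6, 8); e2 <- c(1, 0, 1, 1)
  times <- c(t1, t2); events <- c(e1, e2)
  grp <- rep(c("a", "b"), each = 4)
  lr <- logrank_test(times, events, grp)
  lr_sw <- logrank_test(times, events, rep(c("b", "a"), each = 4))
  expect_equal(lr$statistic, lr_sw$statistic)

  same <- logrank_test(rep(t1, 2), rep(e1, 2), rep(c("a", "b"), each = 4))
  expect_equal(same$statistic, 0, tolerance = 1e-12)
  expect_equal(same$p_two_sided, 1)

  none <- logrank_test(c(1, 2, 3, 4), rep(0, 4), c("a", "a", "b", "b"))
  expect_equal(none$p_two_sided, 1)
  expect_equal(none$flag, "no_events")

  # chi-square p versus a 1e4-shuffle permutation null on an n=12 cohort;
  # tolerance covers the chi-square approximation error at this n plus
  # Monte-Carlo noise
  set.seed(31)
  times <- round(rexp(12, 0.1), 1); events <- rbinom(12, 1, 0.8)
  grp <- rep(c("a", "b"), each = 6)
  obs <- logrank_test(times, events, grp)
  perm <- replicate(1e4,
    logrank_test(times, events, sample(grp))$statistic)
  p_perm <- mean(perm >= obs$statistic - 1e-12)
  expect_lt(abs(obs$p_two_sided - p_perm), 0.06)
})

test_that("stratified PFS splits at the cutoff and degenerates as constructed", {
  # high group all censored at 30, low group all events at 5
  coh <- data.frame(h_score = c(rep(200, 5), rep(10, 5)),
                    pfs_months = c(rep(30, 5), rep(5, 5)),
                    event = c(rep(0, 5), rep(1, 5)))
  s <- stratified_pfs(coh, cutoff = 80)
  expect_true(is.na(s$median_high))
  expect_equal(s$median_low, 5)
  expect_equal(s$n_high, 5)
  # group assignment equals the brute-force threshold filter
  expect_equal(s$n_high, sum(coh$h_score >= 80))
  expect_error(stratified_pfs(coh, cutoff = 301), "\\[0, 300\\]")
  expect_error(stratified_pfs(coh, cutoff = 0), "empty stratum")
})

test_that("clinical cohort simulator respects censoring, nullity and effect direction", {
  coh0 <- simulate_clinical_cohort(50, censor_rate = 0, seed = 5)
  expect_true(all(coh0$event == 1))
  expect_true(all(coh0$h_score == h_score(coh0$pct_mild, coh0$pct_moderate,
                                          coh0$pct_intense)))
  expect_true(all(coh0$pct_mild %% 10 == 0))
  expect_error(simulate_clinical_cohort(1), "at least 2")
  expect_error(simulate_clinical_cohort(10, hazard_ratio = 0), "positive")
  expect_error(simulate_clinical_cohort(10, cutoff = 400), "\\[0, 300\\]")

  # null: log-rank p approximately uniform across seeds (KS)
  ps <- vapply(1:150, function(s) {
    coh <- simulate_clinical_cohort(40, hazard_ratio = 1, seed = 100 + s)
    if (length(unique(coh$h_score >= 80)) < 2) return(NA_real_)
    stratified_pfs(coh, 80)$logrank$p_two_sided
  }, 1)
  ps <- ps[!is.na(ps)]
  expect_gt(stats::ks.test(ps, "punif")$p.value, 0.01)

  # effect: with hazard_ratio = 4 the low-score group dies sooner
  ordered_ok <- vapply(1:60, function(s) {
    coh <- simulate_clinical_cohort(40, hazard_ratio = 4, censor_rate = 0.2,
                                    seed = 500 + s)
    if (length(unique(coh$h_score >= 80)) < 2) return(NA)
    st <- stratified_pfs(coh, 80)
    med_hi <- st$median_high; med_lo <- st$median_low
    if (is.na(med_hi)) med_hi <- Inf
    med_lo < med_hi
  }, TRUE)
  expect_gte(mean(ordered_ok, na.rm = TRUE), 0.9)
})
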