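#' Simulate a clinical IHC/survival cohort
#'
#' Draws per-patient staining-percentage triplets (in 10% increments, with a
#' fraction of completely negative biopsies), computes the H score, and
#' generates progression-free survival with an exponential hazard that is
#' multiplied by `hazard_ratio` for patients below the H-score cutoff
#' (higher target-antigen expression, better response). Censoring times are
#' independent exponentials calibrated so each patient is censored with
#' probability `censor_rate`. The day-90 response label (CR/PD) is drawn
#' with probability increasing in the H score.
#'
#' @param n Number of patients (>= 2).
#' @param cutoff H-score threshold in `[0, 300]` splitting the hazard
#'   groups. Default 80.
#' @param hazard_ratio Hazard multiplier (> 0) for the low-score group;
#'   1 means no association between score and survival.
#' @param censor_rate Per-patient censoring probability in `[0, 1)`.
#' @param median_high Median PFS (months) of the high-score group.
#' @param p_negative Probability of a completely negative biopsy (H = 0).
#' @param seed Integer seed.
#' @return A data frame of class `clinical_cohort`: `patient_id`,
#'   `pct_mild`, `pct_moderate`, `pct_intense`, `h_score`, `response`
#'   ("CR"/"PD"), `pfs_months`, `event`.
#' @export
simulate_clinical_cohort <- function(n, cutoff = 80, hazard_ratio = 1,
                                     censor_rate = 0.3, median_high = 26,
                                     p_negative = 0.3, seed = 1L) {
  if (n < 2) stop("need at least 2 patients")
  if (hazard_ratio <= 0) stop("hazard_ratio must be positive")
  if (cutoff < 0 || cutoff > 300) stop("cutoff must lie in [0, 300]")
  if (censor_rate < 0 || censor_rate >= 1) stop("censor_rate must be in [0, 1)")
  with_seed(seed, {
    pct <- t(vapply(seq_len(n), function(i) {
      if (stats::runif(1) < p_negative) return(c(0, 0, 0))
      total <- 10 * sample(1:10, 1)               # % stained, 10% increments
      split <- stats::rmultinom(1, total / 10, prob = stats::runif(3))
      as.numeric(10 * split)
    }, numeric(3)))
    h <- h_score(pct[, 1], pct[, 2], pct[, 3])
    lambda0 <- log(2) / median_high
    lambda <- lambda0 * ifelse(h < cutoff, hazard_ratio, 1)
    t_event <- stats::rexp(n, lambda)
    if (censor_rate > 0) {
      t_cens <- stats::rexp(n, lambda * censor_rate / (1 - censor_rate))
    } else {
      t_cens <- rep(Inf, n)
    }
    event <- as.integer(t_event <= t_cens)
    response <- ifelse(stats::runif(n) < stats::plogis((h - cutoff) / 40),
                       "CR", "PD")
    structure(data.frame(
      patient_id = sprintf("p%03d", seq_len(n)),
      pct_mild = pct[, 1], pct_moderate = pct[, 2], pct_intense = pct[, 3],
      h_score = h, response = response,
      pfs_months = pmin(t_event, t_cens), event = event,
      stringsAsFactors = FALSE), class = c("clinical_cohort", "data.frame"))
  })
}
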