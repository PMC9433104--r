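# Independent brute-force oracles used to verify the analytic
# implementations. These deliberately avoid the code paths they check.

# Exact two-sided Mann-Whitney p by full enumeration of all labelings.
mw_enum_oracle <- function(x, y) {
  nx <- length(x)
  pooled <- c(x, y)
  n <- length(pooled)
  u_stat <- function(idx) {
    xx <- pooled[idx]; yy <- pooled[-idx]
    sum(outer(xx, yy, ">")) + 0.5 * sum(outer(xx, yy, "=="))
  }
  obs <- u_stat(seq_len(nx))
  all_u <- apply(utils::combn(n, nx), 2, u_stat)
  p <- 2 * min(mean(all_u <= obs + 1e-12), mean(all_u >= obs - 1e-12))
  list(u = obs, p = min(1, p))
}

# Kaplan-Meier survival by direct product over risk sets.
km_oracle <- function(times, events) {
  tt <- sort(unique(times[events == 1]))
  surv <- numeric(length(tt))
  s <- 1
  for (i in seq_along(tt)) {
    at_risk <- sum(times >= tt[i])
    d <- sum(times == tt[i] & events == 1)
    s <- s * (1 - d / at_risk)
    surv[i] <- s
  }
  data.frame(time = tt, surv = surv)
}

# Step-up Benjamini-Hochberg by the textbook formula.
bh_oracle <- function(p) {
  m <- length(p)
  ord <- order(p)
  q <- numeric(m)
  for (k in seq_len(m)) {
    i <- ord[k]
    q[i] <- min(vapply(k:m, function(j) m * p[ord[j]] / j, 1))
  }
  pmin(q, 1)
}

# Youden-optimal ROC cutoff by exhaustive threshold search (all midpoints,
# recomputing the confusion table from scratch).
roc_youden_oracle <- function(scores, labels) {
  u <- sort(unique(scores))
  cand <- (u[-length(u)] + u[-1]) / 2
  best <- -Inf; best_c <- NA
  for (cc in cand) {
    tp <- sum(scores >= cc & labels == 1); fn <- sum(scores < cc & labels == 1)
    tn <- sum(scores < cc & labels == 0); fp <- sum(scores >= cc & labels == 0)
    j <- tp / (tp + fn) + tn / (tn + fp) - 1
    if (j > best + 1e-12) { best <- j; best_c <- cc }
  }
  best_c
}

# Directional runs by per-start maximal extension, recomputed from scratch
# with complex-number angles (independent of the package's greedy code).
runs_enum_oracle <- function(x, y, tol_deg) {
  n <- length(x)
  if (n < 2) return(list())
  z <- complex(real = x, imaginary = y)
  max_end <- function(i) {
    j <- i + 1
    while (j < n) {
      v <- sum(diff(z[i:j]))          # cumulative displacement so far
      s <- z[j + 1] - z[j]
      if (Mod(s) >= 1e-9 && Mod(v) >= 1e-9 &&
          abs(Arg(s / v)) * 180 / pi > tol_deg) break
      j <- j + 1
    }
    j
  }
  runs <- list(); i <- 1
  while (i < n) {
    j <- max_end(i)
    runs[[length(runs) + 1]] <- c(i, j)
    i <- j
  }
  runs
}

# Per-frame contact recomputation for conjugation detection.
contact_frames_oracle <- function(eff, tgt, slack) {
  ok <- logical(0)
  for (k in seq_len(nrow(eff))) {
    d <- sqrt((eff$x_um[k] - tgt$x_um[k])^2 + (eff$y_um[k] - tgt$y_um[k])^2)
    r <- sqrt(eff$area_um2[k] / pi) + sqrt(tgt$area_um2[k] / pi)
    ok <- c(ok, d <= r + slack)
  }
  eff$frame[ok]
}
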