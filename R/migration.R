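#' Label effector frames as in-contact or out-of-contact
#'
#' A frame is in-contact exactly when its time lies inside one of the
#' effector's conjugation intervals (`start_min <= t < end_min`).
#'
#' @param chain Effector chain with `t_min`.
#' @param intervals Conjugation intervals (`start_min`, `end_min`).
#' @return Character vector, one label per frame: "in_contact" /
#'   "out_of_contact".
#' @export
partition_frames <- function(chain, intervals) {
  t <- chain$t_min
  lab <- rep("out_of_contact", length(t))
  for (i in seq_len(nrow(intervals)))
    lab[t >= intervals$start_min[i] & t < intervals$end_min[i]] <- "in_contact"
  lab
}

#' Directional runs along a centroid series
#'
#' A directional run is a maximal stretch of consecutive steps in which
#' each step stays within `angle_tol_deg` of the run's cumulative
#' displacement direction (updated as the run grows; near-zero steps are
#' treated as compatible pauses). A run is retained only when its net
#' displacement is at least one cell diameter -- the definition of
#' directional migration. Runs never span a change of contact state.
#'
#' @param chain Data frame with `t_min`, `x_um`, `y_um` (>= 3 frames for
#'   any run to exist).
#' @param cell_diameter_um Cell diameter used as the displacement floor.
#' @param angle_tol_deg Angular tolerance in degrees (default 45).
#' @param state Optional per-frame state labels (for example from
#'   [partition_frames()]); runs are computed within maximal same-state
#'   segments.
#' @return Data frame of retained runs: `start_min`, `end_min`,
#'   `displacement_um`, `state`.
#' @export
directional_runs <- function(chain, cell_diameter_um, angle_tol_deg = 45,
                             state = NULL) {
  n <- nrow(chain)
  empty <- data.frame(start_min = numeric(), end_min = numeric(),
                      displacement_um = numeric(), state = character(),
                      stringsAsFactors = FALSE)
  if (n < 3L) return(empty)
  if (is.null(state)) state <- rep("all", n)
  seg_id <- cumsum(c(1L, as.integer(state[-1] != state[-n])))
  out <- list()
  for (s in unique(seg_id)) {
    idx <- which(seg_id == s)
    if (length(idx) < 2L) next
    runs <- greedy_runs(chain$x_um[idx], chain$y_um[idx], angle_tol_deg)
    for (r in runs) {
      i0 <- idx[r[1L]]; i1 <- idx[r[2L]]
      disp <- sqrt((chain$x_um[i1] - chain$x_um[i0])^2 +
                   (chain$y_um[i1] - chain$y_um[i0])^2)
      if (disp >= cell_diameter_um)
        out[[length(out) + 1L]] <- data.frame(
          start_min = chain$t_min[i0], end_min = chain$t_min[i1],
          displacement_um = disp, state = state[i0],
          stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) return(empty)
  res <- do.call(rbind, out)
  res[order(res$start_min), , drop = FALSE]
}

# Greedy maximal runs over a position series: returns list of c(start_index,
# end_index) pairs (1-based within the series). A step joins the current run
# when its direction is within `tol` degrees of the run's cumulative
# displacement vector; zero-length steps always join.
greedy_runs <- function(x, y, tol) {
  n <- length(x)
  if (n < 2L) return(list())
  runs <- list()
  i <- 1L
  while (i < n) {
    vx <- x[i + 1L] - x[i]; vy <- y[i + 1L] - y[i]
    j <- i + 1L
    while (j < n) {
      sx <- x[j + 1L] - x[j]; sy <- y[j + 1L] - y[j]
      slen <- sqrt(sx^2 + sy^2); vlen <- sqrt(vx^2 + vy^2)
      ok <- if (slen < 1e-9) TRUE
        else if (vlen < 1e-9) TRUE
        else {
          cosang <- (vx * sx + vy * sy) / (slen * vlen)
          acos(pmin(pmax(cosang, -1), 1)) * 180 / pi <= tol
        }
      if (!ok) break
      vx <- vx + sx; vy <- vy + sy
      j <- j + 1L
    }
    runs[[length(runs) + 1L]] <- c(i, j)
    i <- j
  }
  runs
}

#' Migration rates per contact state
#'
#' Displacement rate per state: the summed net displacement of the retained
#' directional runs in that state divided by the total minutes spent in the
#' state. A state with zero frames yields `NA` for its rate.
#'
#' @param runs Output of [directional_runs()].
#' @param state Per-frame state labels for the effector chain.
#' @param frame_interval_min Imaging interval (default 5).
#' @param migratory_rule How `migratory_flag` is set: "any_run" (default:
#'   any retained out-of-contact run) or a numeric rate threshold in
#'   microns/min on the out-of-contact rate.
#' @return One-row data frame: `out_of_contact_rate`, `in_contact_rate`
#'   (microns/min), `migratory_flag`.
#' @export
migration_rates <- function(runs, state, frame_interval_min = 5,
                            migratory_rule = "any_run") {
  rate_for <- function(st) {
    minutes <- sum(state == st) * frame_interval_min
    if (minutes == 0) return(NA_real_)
    sum(runs$displacement_um[runs$state == st]) / minutes
  }
  out_rate <- rate_for("out_of_contact")
  in_rate <- rate_for("in_contact")
  flag <- if (identical(migratory_rule, "any_run"))
    any(runs$state == "out_of_contact")
  else isTRUE(!is.na(out_rate) && out_rate > as.numeric(migratory_rule))
  data.frame(out_of_contact_rate = out_rate, in_contact_rate = in_rate,
             migratory_flag = flag)
}

#' Track-median cell diameter
#'
#' Disc-equivalent diameter `2 sqrt(area / pi)`, summarized as the median
#' over the track (robust to frame-level segmentation noise).
#'
#' @param chain Data frame with `area_um2`.
#' @return Diameter in microns.
#' @export
cell_diameter <- function(chain) {
  stats::median(2 * sqrt(chain$area_um2 / pi))
}

#' Per-frame polarization (aspect-ratio) profile
#'
#' Major/minor axis ratio of the effector mask per frame; always >= 1.
#' Degenerate frames (missing or non-positive minor axis) are set to 1 and
#' flagged.
#'
#' @param chain Data frame with `axis_major_um` and `axis_minor_um`.
#' @return Data frame: `frame`, `aspect_ratio`, `degenerate`.
#' @export
aspect_ratio_profile <- function(chain) {
  if (!all(c("axis_major_um", "axis_minor_um") %in% names(chain)))
    stop("chain lacks ellipse axis columns")
  bad <- is.na(chain$axis_minor_um) | chain$axis_minor_um <= 0 |
    is.na(chain$axis_major_um)
  ar <- ifelse(bad, 1, pmax(chain$axis_major_um / chain$axis_minor_um, 1))
  data.frame(frame = chain$frame, aspect_ratio = ar, degenerate = bad)
}
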