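#' Detect effector-target conjugations on a shared frame clock
#'
#' A frame is a contact frame when the centroid distance is at most the sum
#' of the two disc-equivalent radii (from the per-frame areas) plus `slack`.
#' Maximal runs of contact frames, allowing gaps of up to one frame
#' (segmentation flicker), form candidate intervals; an interval's duration
#' is `n_contact_frames x frame_interval` and it is kept only when that
#' duration strictly exceeds `min_duration_min`, so a single contact frame
#' at 5-minute sampling (5 min) is excluded while two frames (10 min) pass.
#'
#' @param eff Effector chain: data frame with `frame`, `t_min`, `x_um`,
#'   `y_um`, `area_um2`.
#' @param targets List of target chains (same columns), named by target id,
#'   or a single chain data frame.
#' @param contact_slack_um Extra contact distance beyond touching discs
#'   (default 2).
#' @param min_duration_min Strict minimum conjugate duration (default 5).
#' @param frame_interval_min Imaging interval (default 5).
#' @param gap_frames Contact-run gaps bridged (default 1).
#' @return Data frame of conjugation intervals: `target_id`, `start_min`,
#'   `end_min`, `n_frames`. `end_min - start_min` is the duration.
#' @export
detect_conjugations <- function(eff, targets, contact_slack_um = 2,
                                min_duration_min = 5,
                                frame_interval_min = 5, gap_frames = 1) {
  if (is.data.frame(targets)) targets <- list(t1 = targets)
  out <- list()
  for (tid in names(targets)) {
    tgt <- targets[[tid]]
    common <- intersect(eff$frame, tgt$frame)
    if (!length(common)) next
    ei <- match(common, eff$frame); ti <- match(common, tgt$frame)
    if (!isTRUE(all.equal(eff$t_min[ei], tgt$t_min[ti])))
      stop("effector and target chains disagree on the frame clock")
    d <- sqrt((eff$x_um[ei] - tgt$x_um[ti])^2 +
              (eff$y_um[ei] - tgt$y_um[ti])^2)
    reach <- sqrt(eff$area_um2[ei] / pi) + sqrt(tgt$area_um2[ti] / pi) +
      contact_slack_um
    contact_frames <- common[d <= reach]
    runs <- contact_runs(contact_frames, gap_frames)
    for (r in runs) {
      n_fr <- length(r)  # counts true contact frames, not bridged gaps
      dur <- n_fr * frame_interval_min
      if (dur > min_duration_min) {
        out[[length(out) + 1L]] <- data.frame(
          target_id = tid,
          start_min = (min(r) - 1) * frame_interval_min,
          end_min = (min(r) - 1) * frame_interval_min + dur,
          n_frames = n_fr, stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(out))
    return(data.frame(target_id = character(), start_min = numeric(),
                      end_min = numeric(), n_frames = integer(),
                      stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  res[order(res$start_min, res$target_id), , drop = FALSE]
}

# Split a sorted vector of contact frame numbers into runs, bridging gaps
# of up to `gap_frames` missing frames.
contact_runs <- function(frames, gap_frames = 1) {
  if (!length(frames)) return(list())
  frames <- sort(unique(frames))
  brk <- c(0L, which(diff(frames) > gap_frames + 1L), length(frames))
  lapply(seq_len(length(brk) - 1L), function(i)
    frames[(brk[i] + 1L):brk[i + 1L]])
}

#' Kinetic parameters for one effector-target pair
#'
#' From the pair's conjugation intervals and the target's death time:
#' `t_Seek` is the time from assay start to the first conjugation;
#' `t_Death` the time from first contact to apoptosis onset; `t_Contact`
#' the cumulative conjugation time between first contact and death (total
#' conjugation time when the target survives, in which case `t_Death` is
#' `NA`).
#'
#' @param intervals Data frame of this pair's intervals (`start_min`,
#'   `end_min`), disjoint.
#' @param death_min Target apoptosis-onset time in minutes, or `NA`.
#' @param assay_start_min Assay start (default 0).
#' @return One-row data frame: `t_seek`, `t_contact`, `t_death`, `valid`.
#'   A death preceding first contact is flagged `valid = FALSE`.
#' @export
compute_kinetics <- function(intervals, death_min = NA,
                             assay_start_min = 0) {
  if (nrow(intervals) == 0L)
    return(data.frame(t_seek = NA_real_, t_contact = NA_real_,
                      t_death = NA_real_, valid = FALSE))
  intervals <- intervals[order(intervals$start_min), , drop = FALSE]
  first <- intervals$start_min[1L]
  t_seek <- first - assay_start_min
  if (is.na(death_min)) {
    return(data.frame(t_seek = t_seek,
                      t_contact = sum(intervals$end_min - intervals$start_min),
                      t_death = NA_real_, valid = TRUE))
  }
  if (death_min < first)
    return(data.frame(t_seek = t_seek, t_contact = NA_real_,
                      t_death = NA_real_, valid = FALSE))
  clipped <- pmin(intervals$end_min, death_min) -
    pmax(intervals$start_min, first)
  data.frame(t_seek = t_seek, t_contact = sum(pmax(clipped, 0)),
             t_death = death_min - first, valid = TRUE)
}

#' Select wells of interest at assay start
#'
#' Keeps wells whose frame-1 object counts satisfy the assay design: a
#' single live effector, `t_min`-`t_max` targets and at least `bead_min`
#' beads. An effector is live when it shows no annexin positivity at the
#' first frame.
#'
#' @param tracks Track table (simulated or segmented) with `well_id`,
#'   `role`, `frame`, `ch_annexin`.
#' @param e_count Required effector count (default 1).
#' @param t_min,t_max Target count bounds (defaults 1 and 5).
#' @param bead_min Minimum bead count (default 1).
#' @param annexin_threshold Live-effector annexin bound (default 0.5).
#' @return Character vector of well ids.
#' @export
select_wells <- function(tracks, e_count = 1, t_min = 1, t_max = 5,
                         bead_min = 1, annexin_threshold = 0.5) {
  f1 <- tracks[tracks$frame == min(tracks$frame), , drop = FALSE]
  ok <- vapply(unique(f1$well_id), function(w) {
    fw <- f1[f1$well_id == w, ]
    ne <- sum(fw$role == "effector"); nt <- sum(fw$role == "target")
    nb <- sum(fw$role == "bead")
    live <- ne > 0 && all(fw$ch_annexin[fw$role == "effector"] <=
                            annexin_threshold)
    ne == e_count && nt >= t_min && nt <= t_max && nb >= bead_min && live
  }, TRUE)
  sort(unique(f1$well_id)[ok])
}

#' Call IFN-gamma secretion from endpoint bead summaries
#'
#' A well is secretion-positive when its bead summary exceeds the control
#' mean plus `k` control standard deviations, the controls being bead-only
#' wells (no effector).
#'
#' @param summaries Data frame from [bead_endpoint_intensity()]
#'   (`well_id`, `bead_median`).
#' @param control_summaries Same format, for the control wells; at least
#'   `min_controls` rows with non-missing summaries.
#' @param k Threshold multiplier (default 3). Raising `k` never converts a
#'   negative well to positive.
#' @param min_controls Minimum number of control wells (default 10).
#' @return Logical vector named by `well_id` (`NA` where the summary is
#'   missing).
#' @export
call_secretion <- function(summaries, control_summaries, k = 3,
                           min_controls = 10) {
  ctrl <- control_summaries$bead_median
  ctrl <- ctrl[!is.na(ctrl)]
  if (length(ctrl) < min_controls)
    stop(sprintf("need at least %d control wells, got %d",
                 min_controls, length(ctrl)))
  thr <- mean(ctrl) + k * stats::sd(ctrl)
  stats::setNames(summaries$bead_median > thr, summaries$well_id)
}

#' Functional annotation of one effector
#'
#' Combines the kill count with the secretion flag into the killer class
#' (nonkiller / single_killer / serial_killer) and the four-way functional
#' taxonomy (see [taxonomy_class()]). Only effectors with at least one
#' conjugate belong to the baseline population; an unconjugated effector
#' returns `NA` classes with `conjugated = FALSE`.
#'
#' @param n_kills Number of targets whose death is attributed to the
#'   effector.
#' @param secretion Logical IFN-gamma secretion flag; missing (`NA`) is an
#'   error because the endpoint readout was not matched.
#' @param conjugated Logical: did the effector form any conjugate (> 5 min)?
#' @return One-row data frame: `killer_class`, `secretion`,
#'   `function_class`, `conjugated`.
#' @export
annotate_function <- function(n_kills, secretion, conjugated) {
  if (is.na(secretion)) stop("secretion flag missing (endpoint not matched)")
  if (!conjugated)
    return(data.frame(killer_class = NA_character_, secretion = secretion,
                      function_class = NA_character_, conjugated = FALSE,
                      stringsAsFactors = FALSE))
  killer <- c("nonkiller", "single_killer", "serial_killer")[
    min(n_kills, 2L) + 1L]
  data.frame(killer_class = killer, secretion = secretion,
             function_class = taxonomy_class(n_kills, secretion),
             conjugated = TRUE, stringsAsFactors = FALSE)
}

#' Attribute a target death to an effector
#'
#' A death is attributed when the pair shares a conjugation interval ending
#' no more than `max_latency_min` before the death (detachment precedes
#' apoptosis) or still ongoing at death.
#'
#' @param intervals The pair's conjugation intervals.
#' @param death_min Death time (minutes) or `NA`.
#' @param max_latency_min Maximum detachment-to-death latency (default 120).
#' @return Logical.
#' @export
attribute_kill <- function(intervals, death_min, max_latency_min = 120) {
  if (is.na(death_min) || nrow(intervals) == 0L) return(FALSE)
  any(intervals$start_min <= death_min &
        intervals$end_min >= death_min - max_latency_min)
}
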