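#' Simulate a nanowell TIMING chip with ground truth
#'
#' Generates per-frame object tracks for a grid of independent nanowells,
#' each holding effector(s), targets and capture beads, plus the endpoint
#' bead readout and a complete event-level ground truth. Effectors move as
#' persistent random walks; a conjugation begins when the effector touches a
#' live target, lasts a drawn duration (whole frames), and may kill; for
#' kills, annexin-V onset occurs a drawn latency after the final detachment,
#' so detachment precedes apoptosis. Bead endpoint intensity is
#' `baseline + secretion_rate x cumulative conjugated minutes + lognormal
#' noise`.
#'
#' @param config An [assay_config()].
#' @param behaviors List of [behavior_profile()]s (for example
#'   [behavior_presets()]).
#' @param weights Mixture weights over `behaviors`, summing to 1.
#' @return A `chip_dataset` list: `tracks` (tidy per-frame table), `endpoint`
#'   (per-bead intensities), `wells` (per-well metadata), `truth`
#'   (ground-truth event log: `wells`, `intervals`, `kills`), `config`.
#' @examples
#' chip <- simulate_chip(assay_config(wells = 4, rng_seed = 1),
#'                       behavior_presets()[c(1, 4)], c(0.5, 0.5))
#' head(chip$tracks)
#' @export
simulate_chip <- function(config, behaviors, weights = NULL) {
  stopifnot(inherits(config, "assay_config"))
  if (inherits(behaviors, "behavior_profile")) behaviors <- list(behaviors)
  if (is.null(weights)) weights <- rep(1 / length(behaviors), length(behaviors))
  if (length(weights) != length(behaviors))
    stop("one mixture weight per behavior profile is required")
  if (abs(sum(weights) - 1) > 1e-8) stop("mixture weights must sum to 1")
  if (config$wells < 1) stop("at least one well is required")

  with_seed(config$rng_seed, {
    n_wells <- config$wells + config$control_wells
    is_control <- c(rep(FALSE, config$wells), rep(TRUE, config$control_wells))
    phen_idx <- ifelse(is_control, NA_integer_,
                       sample.int(length(behaviors), n_wells, replace = TRUE,
                                  prob = weights))
    n_eff <- ifelse(is_control, 0L, draw_counts(config$e_per_well, n_wells))
    n_tgt <- ifelse(is_control, 0L, draw_counts(config$t_per_well, n_wells))
    n_bead <- pmax(draw_counts(config$beads_per_well, n_wells), 1L)

    track_cols <- vector("list", n_wells)
    well_rows <- vector("list", n_wells)
    int_rows <- list()
    kill_rows <- list()
    bead_rows <- vector("list", n_wells)

    for (w in seq_len(n_wells)) {
      wid <- sprintf("w%04d", w)
      beh <- if (is_control[w]) NULL else behaviors[[phen_idx[w]]]
      sim <- simulate_one_well(wid, config, beh,
                               n_eff[w], n_tgt[w], n_bead[w])
      track_cols[[w]] <- sim$tracks
      bead_rows[[w]] <- sim$beads
      if (nrow(sim$intervals)) int_rows[[length(int_rows) + 1L]] <- sim$intervals
      if (nrow(sim$kills)) kill_rows[[length(kill_rows) + 1L]] <- sim$kills
      conj_min <- sum(sim$intervals$end_min - sim$intervals$start_min)
      n_kills <- nrow(sim$kills)
      conjugated <- any((sim$intervals$end_min - sim$intervals$start_min) >
                          5)
      secretion <- !is_control[w] && !is.null(beh) &&
        beh$secretion_rate_per_contact_min > 0 && conj_min > 0
      well_rows[[w]] <- data.frame(
        well_id = wid, is_control = is_control[w],
        phenotype = if (is_control[w]) NA_character_ else beh$phenotype_label,
        n_eff = n_eff[w], n_targets = n_tgt[w], n_beads = n_bead[w],
        conj_min_total = conj_min, conjugated_true = conjugated,
        n_kills_true = n_kills, secretion_true = secretion,
        killer_class_true = if (!conjugated) NA_character_ else
          c("nonkiller", "single_killer", "serial_killer")[
            pmin(n_kills, 2L) + 1L],
        function_class_true = if (!conjugated) NA_character_ else
          taxonomy_class(n_kills, secretion),
        stringsAsFactors = FALSE)
    }

    tracks <- do.call(rbind, track_cols)
    rownames(tracks) <- NULL
    wells <- do.call(rbind, well_rows)
    endpoint <- do.call(rbind, bead_rows)
    truth <- list(
      wells = wells,
      intervals = if (length(int_rows)) do.call(rbind, int_rows) else
        empty_intervals(),
      kills = if (length(kill_rows)) do.call(rbind, kill_rows) else
        empty_kills())
    rownames(truth$intervals) <- rownames(truth$kills) <- NULL
    structure(list(tracks = tracks, endpoint = endpoint, wells = wells,
                   truth = truth, config = config),
              class = "chip_dataset")
  })
}

#' Functional taxonomy from kill count and secretion
#'
#' The four-way partition of conjugating effectors: serial killing (>= 2
#' kills) is multifunctional regardless of secretion; one kill plus
#' secretion is multifunctional; one kill without secretion kills only;
#' no kills splits on secretion into IFN-gamma-only versus nonfunctional.
#'
#' @param n_kills Number of targets killed (integer, vectorized).
#' @param secretion Logical, IFN-gamma secretion detected.
#' @return Character: "multifunctional", "monofunctional_kill",
#'   "monofunctional_ifng" or "nonfunctional".
#' @export
taxonomy_class <- function(n_kills, secretion) {
  ifelse(n_kills >= 2, "multifunctional",
  ifelse(n_kills == 1 & secretion, "multifunctional",
  ifelse(n_kills == 1, "monofunctional_kill",
  ifelse(secretion, "monofunctional_ifng", "nonfunctional"))))
}

empty_intervals <- function() {
  data.frame(well_id = character(), effector_id = character(),
             target_id = character(), start_min = numeric(),
             end_min = numeric(), n_frames = integer(), kill = logical(),
             stringsAsFactors = FALSE)
}

empty_kills <- function() {
  data.frame(well_id = character(), effector_id = character(),
             target_id = character(), detach_min = numeric(),
             death_min = numeric(), onset_frame = integer(),
             stringsAsFactors = FALSE)
}

# Place n points in [margin, L-margin]^2 at pairwise distance >= min_gap
# from each other and >= avoid_gap from `avoid` (rejection, best effort).
place_points <- function(n, L, margin, min_gap, avoid = NULL,
                         avoid_gap = min_gap) {
  pts <- matrix(numeric(0), 0, 2)
  avoid <- if (is.null(avoid)) matrix(numeric(0), 0, 2) else avoid
  mindist <- function(p, m) if (nrow(m) == 0) Inf else
    min(sqrt(rowSums(sweep(m, 2, p)^2)))
  for (i in seq_len(n)) {
    for (try in 1:200) {
      p <- stats::runif(2, margin, L - margin)
      if (mindist(p, pts) >= min_gap && mindist(p, avoid) >= avoid_gap) break
    }
    pts <- rbind(pts, p)
  }
  unname(pts)
}

reflect <- function(p, lo, hi) {
  if (p < lo) p <- lo + (lo - p)
  if (p > hi) p <- hi - (p - hi)
  min(max(p, lo), hi)
}

# Simulate a single well; returns per-frame track columns, bead endpoint
# rows, and the ground-truth conjugation/kill event log.
simulate_one_well <- function(wid, cfg, beh, n_e, n_t, n_b) {
  nf <- cfg$n_frames
  dt <- cfg$frame_interval_min
  L <- cfg$well_size_um
  r_e <- cfg$eff_radius_um; r_t <- cfg$tgt_radius_um; r_b <- cfg$bead_radius_um
  margin <- max(r_e, r_t) + 1

  ids <- c(if (n_e > 0) paste0("e", seq_len(n_e)),
           if (n_t > 0) paste0("t", seq_len(n_t)),
           if (n_b > 0) paste0("b", seq_len(n_b)))
  roles <- c(rep("effector", n_e), rep("target", n_t), rep("bead", n_b))
  n_obj <- length(ids)

  # frame-0 placement keeps every pair of objects non-touching
  tpos <- place_points(n_t, L, margin, 2 * r_t + 2)
  epos <- place_points(n_e, L, margin, 2 * r_e + 2, avoid = tpos,
                       avoid_gap = r_e + r_t + 2)
  bpos <- place_points(n_b, L, max(r_b + 0.5, 2), 2 * r_b + 2,
                       avoid = rbind(tpos, epos),
                       avoid_gap = r_b + max(r_e, r_t) + 2)

  X <- matrix(NA_real_, n_obj, nf); Y <- matrix(NA_real_, n_obj, nf)
  moved <- matrix(FALSE, n_obj, nf)   # moved a full step this frame
  conj_frame <- matrix(FALSE, n_obj, nf)  # effector conjugated this frame
  pos <- rbind(epos, tpos, bpos)
  X[, 1] <- pos[, 1]; Y[, 1] <- pos[, 2]

  tgt_rows <- which(roles == "target")
  onset_frame <- rep(NA_integer_, n_obj)   # annexin onset, target rows
  alive <- rep(TRUE, n_obj)                # contactable (live) targets

  intervals <- list(); kills <- list()

  if (nf < 2L) stop("assay must span at least two frames")
  if (n_e >= 1 && !is.null(beh)) {
    # conjugation dynamics are simulated for the first effector; any extra
    # effectors (a well-selection edge case) just walk
    e <- 1L
    dir <- stats::runif(1, 0, 2 * pi)
    state <- "free"; refractory <- 0L
    tgt_cur <- NA_integer_; frames_left <- 0L; contact_angle <- 0
    start_frame <- NA_integer_; will_kill <- FALSE
    kills_so_far <- 0L
    step_len <- beh$migration_speed_um_min * dt

    for (f in 2:nf) {
      # passive objects first
      for (j in tgt_rows) {
        if (alive[j] && !(state == "conjugated" && j == tgt_cur)) {
          X[j, f] <- reflect(X[j, f - 1] + stats::rnorm(1, 0, 0.2), margin, L - margin)
          Y[j, f] <- reflect(Y[j, f - 1] + stats::rnorm(1, 0, 0.2), margin, L - margin)
        } else {
          X[j, f] <- X[j, f - 1]; Y[j, f] <- Y[j, f - 1]
        }
      }
      if (state == "free") {
        if (stats::runif(1) > beh$directional_persistence)
          dir <- stats::runif(1, 0, 2 * pi)
        x <- reflect(X[e, f - 1] + step_len * cos(dir), margin, L - margin)
        y <- reflect(Y[e, f - 1] + step_len * sin(dir), margin, L - margin)
        X[e, f] <- x; Y[e, f] <- y
        moved[e, f] <- step_len > 0.5 * r_e
        if (refractory > 0L) {
          refractory <- refractory - 1L
        } else {
          cand <- tgt_rows[alive[tgt_rows]]
          if (length(cand)) {
            d <- sqrt((X[cand, f] - x)^2 + (Y[cand, f] - y)^2)
            hit <- which(d <= r_e + r_t + 1)
            if (length(hit)) {
              tgt_cur <- cand[hit[which.min(d[hit])]]
              state <- "conjugated"
              start_frame <- f
              dur <- draw_duration(beh$contact_duration_min, 1,
                                   min_value = 2 * dt)
              frames_left <- max(2L, as.integer(round(dur / dt)))
              will_kill <- kills_so_far < beh$max_kills &&
                stats::runif(1) < beh$kill_prob_per_contact
              contact_angle <- atan2(y - Y[tgt_cur, f], x - X[tgt_cur, f])
            }
          }
        }
      }
      if (state == "conjugated") {
        # snap to the target surface (touching discs)
        contact_angle <- contact_angle + stats::rnorm(1, 0, 0.05)
        X[e, f] <- X[tgt_cur, f] + (r_e + r_t) * cos(contact_angle)
        Y[e, f] <- Y[tgt_cur, f] + (r_e + r_t) * sin(contact_angle)
        conj_frame[e, f] <- TRUE
        frames_left <- frames_left - 1L
        if (frames_left == 0L || f == nf) {
          n_fr <- f - start_frame + 1L
          start_min <- (start_frame - 1) * dt
          end_min <- start_min + n_fr * dt
          intervals[[length(intervals) + 1L]] <- data.frame(
            well_id = wid, effector_id = ids[e], target_id = ids[tgt_cur],
            start_min = start_min, end_min = end_min, n_frames = n_fr,
            kill = FALSE, stringsAsFactors = FALSE)
          if (will_kill) {
            latency <- draw_duration(beh$death_latency_min, 1, min_value = dt)
            death_min <- end_min + latency
            onset <- as.integer(ceiling(death_min / dt) + 1)
            if (onset <= nf) {
              onset_frame[tgt_cur] <- onset
              alive[tgt_cur] <- FALSE
              kills_so_far <- kills_so_far + 1L
              intervals[[length(intervals)]]$kill <- TRUE
              kills[[length(kills) + 1L]] <- data.frame(
                well_id = wid, effector_id = ids[e],
                target_id = ids[tgt_cur], detach_min = end_min,
                death_min = (onset - 1) * dt, onset_frame = onset,
                stringsAsFactors = FALSE)
            } else {
              alive[tgt_cur] <- FALSE  # committed but past the window
            }
          }
          # detach: step away radially and pause one frame
          if (f < nf) {
            away <- contact_angle
            X[e, f] <- reflect(X[e, f] + 4 * cos(away), margin, L - margin)
            Y[e, f] <- reflect(Y[e, f] + 4 * sin(away), margin, L - margin)
          }
          state <- "free"; refractory <- 1L
          dir <- stats::runif(1, 0, 2 * pi)
          tgt_cur <- NA_integer_
        }
      }
    }
    # extra effectors: plain persistent walk
    if (n_e > 1) for (e2 in 2:n_e) {
      dir2 <- stats::runif(1, 0, 2 * pi)
      for (f in 2:nf) {
        if (stats::runif(1) > beh$directional_persistence)
          dir2 <- stats::runif(1, 0, 2 * pi)
        X[e2, f] <- reflect(X[e2, f - 1] + step_len * cos(dir2), margin, L - margin)
        Y[e2, f] <- reflect(Y[e2, f - 1] + step_len * sin(dir2), margin, L - margin)
      }
    }
  } else if (n_obj > 0) {
    for (f in 2:nf) { X[, f] <- X[, f - 1]; Y[, f] <- Y[, f - 1] }
  }
  # beads are static
  brows <- which(roles == "bead")
  for (j in brows) { X[j, ] <- X[j, 1]; Y[j, ] <- Y[j, 1] }
  if (n_t > 0) for (j in tgt_rows) {
    if (any(is.na(X[j, ]))) { # dead targets freeze (handled above), safety
      last <- max(which(!is.na(X[j, ])))
      X[j, (last + 1):nf] <- X[j, last]; Y[j, (last + 1):nf] <- Y[j, last]
    }
  }

  # intensities, areas, axes
  base_area <- c(rep(pi * r_e^2, n_e), rep(pi * r_t^2, n_t),
                 rep(pi * r_b^2, n_b))
  area <- sweep(matrix(stats::rnorm(n_obj * nf, 1, 0.05), n_obj, nf),
                1, base_area, `*`)
  area[area < 1] <- 1
  ch_eff <- matrix(stats::rnorm(n_obj * nf, 0.05, 0.01), n_obj, nf)
  ch_tgt <- matrix(stats::rnorm(n_obj * nf, 0.05, 0.01), n_obj, nf)
  ch_ann <- matrix(stats::rnorm(n_obj * nf, 0.05, 0.01), n_obj, nf)
  erows <- which(roles == "effector")
  if (length(erows))
    ch_eff[erows, ] <- stats::rnorm(length(erows) * nf, 0.9, 0.03)
  if (length(tgt_rows))
    ch_tgt[tgt_rows, ] <- stats::rnorm(length(tgt_rows) * nf, 0.9, 0.03)
  for (j in tgt_rows) if (!is.na(onset_frame[j]))
    ch_ann[j, onset_frame[j]:nf] <- stats::rnorm(nf - onset_frame[j] + 1,
                                                 0.85, 0.03)
  # polarization: elongated while taking full steps, rounded otherwise
  ratio <- matrix(1, n_obj, nf)
  if (length(erows)) {
    el <- moved[erows, , drop = FALSE]
    ratio[erows, ] <- ifelse(el,
      pmax(1.2, stats::rnorm(sum(dim(el)[1]) * nf, 1.8, 0.25)),
      pmax(1, stats::rnorm(sum(dim(el)[1]) * nf, 1.15, 0.08)))
  }
  if (length(tgt_rows))
    ratio[tgt_rows, ] <- pmax(1, stats::rnorm(length(tgt_rows) * nf, 1.05, 0.04))
  axis_major <- 2 * sqrt(area * ratio / pi)
  axis_minor <- 2 * sqrt(area / (ratio * pi))

  # orientation from displacement (effectors), 0 otherwise
  orient <- matrix(0, n_obj, nf)
  if (n_obj > 0 && nf > 1) {
    dx <- cbind(0, t(apply(X, 1, diff))); dy <- cbind(0, t(apply(Y, 1, diff)))
    orient <- atan2(dy, dx)
    orient[sqrt(dx^2 + dy^2) < 1e-9] <- 0
  }

  tmin <- (seq_len(nf) - 1) * dt
  tracks <- data.frame(
    well_id = wid,
    object_id = rep(ids, each = nf),
    role = rep(roles, each = nf),
    frame = rep(seq_len(nf), times = n_obj),
    t_min = rep(tmin, times = n_obj),
    x_um = as.vector(t(X)), y_um = as.vector(t(Y)),
    area_um2 = as.vector(t(area)),
    axis_major_um = as.vector(t(axis_major)),
    axis_minor_um = as.vector(t(axis_minor)),
    orientation_rad = as.vector(t(orient)),
    ch_eff = as.vector(t(ch_eff)),
    ch_tgt = as.vector(t(ch_tgt)),
    ch_annexin = as.vector(t(ch_ann)),
    stringsAsFactors = FALSE)

  ints <- if (length(intervals)) do.call(rbind, intervals) else empty_intervals()
  kls <- if (length(kills)) do.call(rbind, kills) else empty_kills()
  conj_total <- sum(ints$end_min - ints$start_min)
  rate <- if (is.null(beh)) 0 else beh$secretion_rate_per_contact_min
  beads <- data.frame(
    well_id = wid, bead_id = if (n_b > 0) paste0("b", seq_len(n_b)) else character(),
    intensity = cfg$bead_baseline + rate * conj_total +
      stats::rlnorm(n_b, meanlog = log(3), sdlog = 0.6),
    stringsAsFactors = FALSE)

  list(tracks = tracks, beads = beads, intervals = ints, kills = kls)
}

#' Write chip track and endpoint tables to CSV
#'
#' @param chip A `chip_dataset`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_chip_csv <- function(chip, dir) {
  stopifnot(inherits(chip, "chip_dataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(tracks = file.path(dir, "tracks.csv"),
             endpoint = file.path(dir, "endpoint.csv"),
             wells = file.path(dir, "wells.csv"),
             truth = file.path(dir, "ground_truth.json"))
  utils::write.csv(chip$tracks, paths["tracks"], row.names = FALSE)
  utils::write.csv(chip$endpoint, paths["endpoint"], row.names = FALSE)
  utils::write.csv(chip$wells, paths["wells"], row.names = FALSE)
  jsonlite::write_json(chip$truth, paths["truth"], dataframe = "rows",
                       auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
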