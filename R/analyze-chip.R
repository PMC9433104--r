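#' End-to-end analysis of a nanowell track table
#'
#' Runs the full single-cell analysis on an identified track table plus the
#' endpoint bead readout: selects wells of interest (one live effector, 1-5
#' targets, >= 1 bead), detects conjugations, calls target deaths from the
#' annexin channel, attributes kills, computes per-pair kinetics (t_Seek,
#' t_Contact, t_Death), calls IFN-gamma secretion against bead-only control
#' wells, annotates each effector's functional class, and quantifies
#' directional migration in and out of contact.
#'
#' @param tracks Track table (from [simulate_chip()]'s `$tracks` or
#'   [segment_chip()]): columns `well_id`, `object_id`, `role`, `frame`,
#'   `t_min`, `x_um`, `y_um`, `area_um2`, `ch_annexin`.
#' @param endpoint Per-bead endpoint intensities (`well_id`, `intensity`).
#' @param frame_interval_min Imaging interval in minutes (default 5).
#' @param contact_slack_um Contact slack beyond touching discs (default 2).
#' @param min_duration_min Strict conjugate duration floor (default 5).
#' @param annexin_threshold Annexin positivity threshold (default 0.5).
#' @param death_run_frames Consecutive positive frames required for a death
#'   call (default 2).
#' @param max_latency_min Maximum detachment-to-death latency for kill
#'   attribution (default 120).
#' @param secretion_k Control-SD multiplier for the secretion threshold
#'   (default 3).
#' @param angle_tol_deg Directional-run angular tolerance (default 45).
#' @param t_range Target-count bounds for well selection (default `c(1, 5)`).
#' @return A `timing_analysis` list: `wells` (selected ids), `conjugations`,
#'   `kinetics` (per effector-target pair), `annotation` (per effector),
#'   `migration` (per effector).
#' @export
analyze_chip <- function(tracks, endpoint, frame_interval_min = 5,
                         contact_slack_um = 2, min_duration_min = 5,
                         annexin_threshold = 0.5, death_run_frames = 2,
                         max_latency_min = 120, secretion_k = 3,
                         angle_tol_deg = 45, t_range = c(1, 5)) {
  wells <- select_wells(tracks, e_count = 1, t_min = t_range[1],
                        t_max = t_range[2], bead_min = 1,
                        annexin_threshold = annexin_threshold)
  # bead-only wells (no cells at frame 1) are the secretion controls
  f1 <- tracks[tracks$frame == min(tracks$frame), ]
  cells_by_well <- tapply(f1$role %in% c("effector", "target"),
                          f1$well_id, any)
  control_ids <- names(cells_by_well)[!cells_by_well]
  bead_sum <- bead_endpoint_intensity(endpoint)
  secretion <- call_secretion(
    bead_sum, bead_sum[bead_sum$well_id %in% control_ids, , drop = FALSE],
    k = secretion_k)

  conj_rows <- list(); kin_rows <- list(); ann_rows <- list()
  mig_rows <- list()
  for (w in wells) {
    tw <- tracks[tracks$well_id == w, ]
    eff <- tw[tw$role == "effector", ]
    eff <- eff[order(eff$frame), ]
    tchains <- split(tw[tw$role == "target", ],
                     tw$object_id[tw$role == "target"])
    tchains <- lapply(tchains, function(x) x[order(x$frame), ])
    ints <- detect_conjugations(eff, tchains,
                                contact_slack_um = contact_slack_um,
                                min_duration_min = min_duration_min,
                                frame_interval_min = frame_interval_min)
    if (nrow(ints)) {
      ints$well_id <- w
      conj_rows[[length(conj_rows) + 1L]] <- ints
    }
    deaths <- vapply(tchains, function(ch)
      call_death(ch, threshold = annexin_threshold,
                 k = death_run_frames), NA_integer_)
    death_min <- (deaths - 1) * frame_interval_min

    n_kills <- 0L
    for (tid in unique(ints$target_id)) {
      pair <- ints[ints$target_id == tid, , drop = FALSE]
      dmin <- death_min[[tid]]
      killed <- attribute_kill(pair, dmin, max_latency_min)
      kin <- compute_kinetics(pair, if (killed) dmin else NA)
      kin$well_id <- w; kin$target_id <- tid; kin$kill <- killed
      kin_rows[[length(kin_rows) + 1L]] <- kin
      if (killed && kin$valid) n_kills <- n_kills + 1L
    }
    conjugated <- nrow(ints) > 0L
    sec <- secretion[[w]]
    if (is.null(sec)) sec <- NA
    ann <- annotate_function(n_kills, sec, conjugated)
    ann$well_id <- w
    ann$n_kills <- n_kills
    ann$total_conjugation_min <- sum(ints$end_min - ints$start_min)
    ann_rows[[length(ann_rows) + 1L]] <- ann

    state <- partition_frames(eff, ints)
    dia <- cell_diameter(eff)
    runs <- directional_runs(eff, dia, angle_tol_deg = angle_tol_deg,
                             state = state)
    mig <- migration_rates(runs, state,
                           frame_interval_min = frame_interval_min)
    mig$well_id <- w; mig$cell_diameter_um <- dia
    mig_rows[[length(mig_rows) + 1L]] <- mig
  }
  bind <- function(rows, proto) if (length(rows)) {
    x <- do.call(rbind, rows); rownames(x) <- NULL; x
  } else proto
  structure(list(
    wells = wells,
    conjugations = bind(conj_rows,
      cbind(empty_intervals()[0, c("target_id", "start_min", "end_min",
                                   "n_frames")],
            data.frame(well_id = character()))),
    kinetics = bind(kin_rows, data.frame(
      t_seek = numeric(), t_contact = numeric(), t_death = numeric(),
      valid = logical(), well_id = character(), target_id = character(),
      kill = logical())),
    annotation = bind(ann_rows, data.frame(
      killer_class = character(), secretion = logical(),
      function_class = character(), conjugated = logical(),
      well_id = character(), n_kills = integer(),
      total_conjugation_min = numeric())),
    migration = bind(mig_rows, data.frame(
      out_of_contact_rate = numeric(), in_contact_rate = numeric(),
      migratory_flag = logical(), well_id = character(),
      cell_diameter_um = numeric()))),
    class = "timing_analysis")
}

#' @export
print.timing_analysis <- function(x, ...) {
  cat(sprintf(
    "timing_analysis: %d wells of interest, %d conjugations, %d kills\n",
    length(x$wells), nrow(x$conjugations), sum(x$kinetics$kill)))
  if (nrow(x$annotation))
    print(table(x$annotation$function_class, useNA = "ifany"))
  invisible(x)
}
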