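#' Nanowell assay configuration
#'
#' Describes a simulated TIMING run: a grid of independent nanowells, each
#' confining one effector (CAR T cell), one to five targets (tumor cells)
#' and at least one cytokine-capture bead, imaged at a fixed interval.
#'
#' @param frame_interval_min Imaging interval in minutes (default 5).
#' @param duration_h Assay duration in hours (default 6). The number of
#'   frames is `floor(duration_h * 60 / frame_interval_min) + 1`.
#' @param wells Number of cell-bearing nanowells.
#' @param control_wells Number of bead-only wells (no cells) used as the
#'   secretion-negative control population. Default 20.
#' @param well_size_um Side of the square well, microns (default 50).
#' @param e_per_well,t_per_well,beads_per_well Count distributions: a single
#'   integer, a named probability vector (names = counts), or `function(n)`.
#'   Defaults: exactly 1 effector; targets uniform on 1-5; 1-3 beads.
#' @param eff_radius_um,tgt_radius_um,bead_radius_um Disc-equivalent object
#'   radii in microns (defaults 6, 7, 2.5; beads are much smaller than
#'   cells, which is what the size-exclusion classifier exploits).
#' @param bead_baseline Endpoint bead fluorescence baseline (arbitrary
#'   units, default 100).
#' @param rng_seed Integer seed; fixed seeds give identical datasets.
#' @return An `assay_config` list.
#' @export
assay_config <- function(frame_interval_min = 5, duration_h = 6,
                         wells = 100, control_wells = 20,
                         well_size_um = 50,
                         e_per_well = 1,
                         t_per_well = stats::setNames(rep(0.2, 5), 1:5),
                         beads_per_well = c(`1` = 0.5, `2` = 0.3, `3` = 0.2),
                         eff_radius_um = 6, tgt_radius_um = 7,
                         bead_radius_um = 2.5,
                         bead_baseline = 100,
                         rng_seed = 1L) {
  if (frame_interval_min <= 0) stop("frame_interval_min must be positive")
  if (duration_h <= 0) stop("duration_h must be positive")
  if (wells < 1) stop("at least one well is required")
  if (control_wells < 0) stop("control_wells must be non-negative")
  if (2 * max(eff_radius_um, tgt_radius_um) >= well_size_um)
    stop("impossible geometry: cells larger than the well")
  cfg <- list(frame_interval_min = frame_interval_min,
              duration_h = duration_h,
              wells = as.integer(wells),
              control_wells = as.integer(control_wells),
              well_size_um = well_size_um,
              e_per_well = e_per_well,
              t_per_well = t_per_well,
              beads_per_well = beads_per_well,
              eff_radius_um = eff_radius_um,
              tgt_radius_um = tgt_radius_um,
              bead_radius_um = bead_radius_um,
              bead_baseline = bead_baseline,
              rng_seed = as.integer(rng_seed),
              n_frames = as.integer(
                floor(duration_h * 60 / frame_interval_min) + 1))
  structure(cfg, class = "assay_config")
}

#' Effector behavior profile
#'
#' Parameterizes one effector phenotype for the simulator: a persistent
#' random walk (direction retained with probability
#' `directional_persistence` per step, otherwise redrawn uniformly),
#' conjugation behavior, killing, and IFN-gamma secretion. Secretion is
#' accumulated onto the well's capture beads in proportion to cumulative
#' conjugation time.
#'
#' @param phenotype_label One of `"migratory_killer"`,
#'   `"nonmigratory_nonkiller"`, `"monofunctional_secretor"`,
#'   `"serial_killer"` (free-form labels are allowed).
#' @param migration_speed_um_min Free-motion speed, microns/minute.
#' @param directional_persistence Probability in `[0, 1]` of keeping the
#'   previous step direction.
#' @param kill_prob_per_contact Probability that a conjugation kills its
#'   target.
#' @param max_kills Cap on kills per effector (1 for single killers, `Inf`
#'   for serial killers).
#' @param contact_duration_min Conjugation duration distribution, minutes:
#'   a mean (gamma, shape 2) or `function(n)`.
#' @param death_latency_min Latency from final detachment to annexin-V
#'   onset, minutes: mean or `function(n)`. Must be positive for the
#'   detachment-before-death phenotype.
#' @param secretion_rate_per_contact_min Bead signal accrued per conjugated
#'   minute (arbitrary units/min; 0 = non-secretor).
#' @return A `behavior_profile` list.
#' @export
behavior_profile <- function(phenotype_label,
                             migration_speed_um_min,
                             directional_persistence,
                             kill_prob_per_contact,
                             max_kills = Inf,
                             contact_duration_min = 30,
                             death_latency_min = 25,
                             secretion_rate_per_contact_min = 0) {
  stopifnot(migration_speed_um_min >= 0,
            directional_persistence >= 0, directional_persistence <= 1,
            kill_prob_per_contact >= 0, kill_prob_per_contact <= 1,
            secretion_rate_per_contact_min >= 0)
  structure(list(phenotype_label = phenotype_label,
                 migration_speed_um_min = migration_speed_um_min,
                 directional_persistence = directional_persistence,
                 kill_prob_per_contact = kill_prob_per_contact,
                 max_kills = max_kills,
                 contact_duration_min = contact_duration_min,
                 death_latency_min = death_latency_min,
                 secretion_rate_per_contact_min = secretion_rate_per_contact_min),
            class = "behavior_profile")
}

#' Built-in behavior profiles
#'
#' The four effector phenotypes used throughout the package, chosen so that
#' (given conjugation) they realize the four functional classes of the
#' killing/secretion taxonomy:
#' \describe{
#'   \item{serial_killer}{fast, persistent, kills repeatedly with short
#'     conjugations; secretes. Multifunctional.}
#'   \item{migratory_killer}{fast, persistent, kills exactly one target, no
#'     secretion. Monofunctional (killing only).}
#'   \item{monofunctional_secretor}{slow, stays conjugated for long periods
#'     without killing; secretes. Monofunctional (IFN-gamma only).}
#'   \item{nonmigratory_nonkiller}{slow, low persistence, conjugates without
#'     killing or secreting. Nonfunctional.}
#' }
#'
#' @return Named list of [behavior_profile()] objects.
#' @export
behavior_presets <- function() {
  list(
    serial_killer = behavior_profile(
      "serial_killer", migration_speed_um_min = 4,
      directional_persistence = 0.85, kill_prob_per_contact = 0.8,
      max_kills = Inf, contact_duration_min = 25, death_latency_min = 25,
      secretion_rate_per_contact_min = 0.8),
    migratory_killer = behavior_profile(
      "migratory_killer", migration_speed_um_min = 3.5,
      directional_persistence = 0.8, kill_prob_per_contact = 0.8,
      max_kills = 1, contact_duration_min = 40, death_latency_min = 25,
      secretion_rate_per_contact_min = 0),
    monofunctional_secretor = behavior_profile(
      "monofunctional_secretor", migration_speed_um_min = 1,
      directional_persistence = 0.4, kill_prob_per_contact = 0,
      max_kills = 0, contact_duration_min = 150, death_latency_min = 25,
      secretion_rate_per_contact_min = 1),
    nonmigratory_nonkiller = behavior_profile(
      "nonmigratory_nonkiller", migration_speed_um_min = 0.5,
      directional_persistence = 0.2, kill_prob_per_contact = 0,
      max_kills = 0, contact_duration_min = 40, death_latency_min = 25,
      secretion_rate_per_contact_min = 0))
}
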