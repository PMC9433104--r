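# Small track-table builders used across tests.

make_chain <- function(x, y, dt = 5, area = 113, frame0 = 1,
                       annexin = NULL) {
  n <- length(x)
  data.frame(
    frame = seq(frame0, length.out = n),
    t_min = (seq(frame0, length.out = n) - 1) * dt,
    x_um = x, y_um = y, area_um2 = rep(area, n),
    ch_annexin = if (is.null(annexin)) rep(0.05, n) else annexin)
}

# Effector/target pair whose contact spans the given frame windows
# (targets touching: distance 0 during contact, far apart otherwise).
contact_fixture <- function(contact_frames_list, n_frames = 40, dt = 5) {
  eff <- make_chain(rep(0, n_frames), rep(0, n_frames), dt = dt)
  targets <- list()
  for (i in seq_along(contact_frames_list)) {
    xs <- rep(40, n_frames)
    xs[contact_frames_list[[i]]] <- 10  # within touching range of effector
    targets[[paste0("t", i)]] <- make_chain(xs, rep(0, n_frames), dt = dt,
                                            area = 154)
  }
  list(eff = eff, targets = targets)
}

# Medium simulated chip shared by the heavier tests (built once per run).
.test_cache <- new.env(parent = emptyenv())

cached_chip <- function(name, wells, seed, weights_names, t_per_well = NULL) {
  key <- paste(name, wells, seed, sep = "_")
  if (!is.null(.test_cache[[key]])) return(.test_cache[[key]])
  pres <- behavior_presets()[weights_names]
  cfg_args <- list(wells = wells, control_wells = 20, rng_seed = seed)
  if (!is.null(t_per_well)) cfg_args$t_per_well <- t_per_well
  chip <- simulate_chip(do.call(assay_config, cfg_args),
                        pres, rep(1 / length(pres), length(pres)))
  .test_cache[[key]] <- chip
  chip
}

cached_analysis <- function(chip, key) {
  akey <- paste0("ana_", key)
  if (is.null(.test_cache[[akey]]))
    .test_cache[[akey]] <- analyze_chip(chip$tracks, chip$endpoint)
  .test_cache[[akey]]
}

# The 500-well chip used by the headline kinetic/annotation/migration
# checks: equal mixture of all four phenotypes.
acceptance_chip <- function() {
  cached_chip("acc", 500, 20260101, c("serial_killer", "migratory_killer",
                                      "monofunctional_secretor",
                                      "nonmigratory_nonkiller"))
}

acceptance_analysis <- function() {
  cached_analysis(acceptance_chip(), "acc_500_20260101")
}
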