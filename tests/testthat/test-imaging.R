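# Build a simple tile by drawing discs into a blank 4-channel array.
draw_disc <- function(tile, x0, y0, r, ch, value) {
  n <- dim(tile)[1]
  for (i in 1:n) for (j in 1:n)
    if ((i - 0.5 - x0)^2 + (j - 0.5 - y0)^2 <= r^2)
      tile[i, j, ch] <- value
  tile
}

blank_tile <- function(n = 50) array(0.02, dim = c(n, n, 4))

test_that("blank tiles segment to nothing, with a warning", {
  expect_warning(obj <- segment_frame(blank_tile()), "blank")
  expect_equal(nrow(obj), 0)
})

test_that("a rendered well with known content is recovered object by object", {
  cfg <- assay_config(wells = 1, control_wells = 0, t_per_well = 3,
                      beads_per_well = 2, rng_seed = 5)
  chip <- simulate_chip(cfg, behavior_presets()["nonmigratory_nonkiller"], 1)
  rnd <- render_frames(chip, frames = 1)
  obj <- segment_frame(rnd$images[[1]][, , , 1])
  expect_equal(nrow(obj), 6)  # 1 effector + 3 targets + 2 beads
  expect_equal(sum(obj$role == "bead"), 2)
  expect_equal(sum(obj$class == "effector", na.rm = TRUE), 1)
  expect_equal(sum(obj$class == "target", na.rm = TRUE), 3)
  # centroids land near the simulated positions
  tr <- chip$tracks[chip$tracks$frame == 1 & chip$tracks$role == "effector", ]
  eff <- obj[which(obj$class == "effector"), ]
  expect_lt(sqrt((eff$x_um - tr$x_um)^2 + (eff$y_um - tr$y_um)^2), 1.5)
})

test_that("touching cells yield a single object flagged as merged", {
  tile <- blank_tile(70)
  tile <- draw_disc(tile, 15, 15, 7, 2, 0.9)   # two barely-touching targets
  tile <- draw_disc(tile, 15, 28, 7, 2, 0.9)
  tile <- draw_disc(tile, 45, 15, 7, 2, 0.9)   # reference singles
  tile <- draw_disc(tile, 45, 40, 7, 2, 0.9)
  tile <- draw_disc(tile, 15, 55, 7, 2, 0.9)
  obj <- segment_frame(tile)
  expect_equal(nrow(obj), 4)                   # the touching pair fuses
  expect_equal(sum(obj$merged), 1)
  expect_gt(max(obj$area_um2),
            1.8 * median(obj$area_um2[obj$role == "cell"]))
})

test_that("size exclusion separates beads from cells perfectly when areas are disjoint", {
  expect_equal(size_exclusion_classify(data.frame(area_um2 = 20), 40)$role, "bead")
  expect_equal(size_exclusion_classify(data.frame(area_um2 = 120), 40)$role, "cell")
  chip <- cached_chip("roundtrip", 20, 3, "nonmigratory_nonkiller",
                      t_per_well = c(`1` = 1/3, `2` = 1/3, `3` = 1/3))
  rnd <- render_frames(chip, frames = 1)
  seg <- segment_chip(rnd)
  truth1 <- chip$tracks[chip$tracks$frame == 1, ]
  # per-well object counts recovered exactly (objects start non-touching)
  expect_equal(table(seg$well_id), table(truth1$well_id))
  # role composition per well matches, i.e. bead/cell discrimination is exact
  expect_equal(table(seg$well_id, seg$role), table(truth1$well_id, truth1$role))
})

test_that("track linking follows single objects, bridges gaps and rejects duplicates", {
  obj <- data.frame(well_id = "w1", frame = 1:10, x_um = 10, y_um = 10,
                    role = "effector")
  out <- link_tracks(obj)
  expect_equal(length(unique(out$object_id)), 1)
  expect_equal(nrow(out), 10)

  gap <- obj[-5, ]
  out <- link_tracks(gap, gap_max = 1)
  expect_equal(length(unique(out$object_id)), 1)
  expect_equal(unname(attr(out, "gaps")["w1:e1"]), 1L)

  nogap <- link_tracks(gap, gap_max = 0)
  expect_equal(length(unique(nogap$object_id)), 2)

  expect_error(link_tracks(rbind(obj, obj[1, ])), "duplicate")
})

test_that("linking preserves identity for crossing objects and ignores row order", {
  set.seed(17)
  correct <- 0; total <- 0
  for (rep in 1:40) {
    n <- 20
    # two objects on crossing straight lines, steps of ~3 um
    a <- data.frame(well_id = "w1", frame = 1:n,
                    x_um = seq(5, 45, length.out = n),
                    y_um = seq(10, 40, length.out = n) + rnorm(n, 0, 0.3),
                    role = "target", true_id = "A")
    b <- data.frame(well_id = "w1", frame = 1:n,
                    x_um = seq(45, 5, length.out = n),
                    y_um = seq(12, 38, length.out = n) + rnorm(n, 0, 0.3),
                    role = "target", true_id = "B")
    out <- link_tracks(rbind(a, b), max_step_um = 10)
    for (tid in c("A", "B")) {
      sub <- out[out$true_id == tid, ]
      first <- sub$object_id[sub$frame == 1]
      correct <- correct + sum(sub$object_id == first)
      total <- total + nrow(sub)
    }
  }
  expect_gte(correct / total, 0.95)

  obj <- rbind(a, b)
  shuffled <- obj[sample(nrow(obj)), ]
  expect_equal(link_tracks(obj, max_step_um = 10),
               link_tracks(shuffled, max_step_um = 10),
               ignore_attr = TRUE)
})

test_that("death calling needs a sustained annexin run and is threshold-monotone", {
  ann <- rep(0.1, 30)
  chain <- make_chain(rep(0, 30), rep(0, 30), annexin = ann)
  expect_true(is.na(call_death(chain)))

  ann2 <- ann; ann2[12:13] <- 0.9
  expect_equal(call_death(make_chain(rep(0, 30), rep(0, 30), annexin = ann2)), 12L)
  # single-frame flicker is rejected at k = 2
  ann3 <- ann; ann3[12] <- 0.9
  expect_true(is.na(call_death(make_chain(rep(0, 30), rep(0, 30), annexin = ann3))))
  expect_error(call_death(chain[0, ]), "empty")

  set.seed(23)
  for (rep in 1:20) {
    ann <- runif(40)
    ch <- make_chain(rep(0, 40), rep(0, 40), annexin = ann)
    frames <- vapply(c(0.2, 0.4, 0.6, 0.8),
                     function(th) {
                       f <- call_death(ch, threshold = th)
                       if (is.na(f)) Inf else as.numeric(f)
                     }, 1)
    expect_true(all(diff(frames) >= 0))  # raising threshold never advances death
  }
})

test_that("death calls match the simulated onset frames", {
  chip <- acceptance_chip()
  kills <- chip$truth$kills
  idx <- seq_len(min(nrow(kills), 200))
  err <- vapply(idx, function(i) {
    k <- kills[i, ]
    ch <- chip$tracks[chip$tracks$well_id == k$well_id &
                        chip$tracks$object_id == k$target_id, ]
    called <- call_death(ch)
    if (is.na(called)) Inf else abs(called - k$onset_frame)
  }, 1)
  expect_gte(mean(err <= 1), 0.95)
})

test_that("endpoint bead summaries are per-well medians with missing wells flagged", {
  beads <- data.frame(well_id = rep(c("w1", "w2"), c(3, 1)),
                      intensity = c(80, 100, 120, 55))
  out <- bead_endpoint_intensity(beads, wells = c("w1", "w2", "w3"))
  expect_equal(out$bead_median, c(100, 55, NA))
  expect_equal(out$flag, c(NA, NA, "no_beads"))
  # brute-force recomputation from the raw table
  expect_equal(out$bead_median[1], median(beads$intensity[beads$well_id == "w1"]))
  uni <- bead_endpoint_intensity(data.frame(well_id = "w1", intensity = rep(100, 4)))
  expect_equal(uni$bead_median, 100)
})

test_that("endpoint matching joins on well id and reports unmatched wells", {
  tl <- data.frame(well_id = sprintf("w%02d", 1:10), a = 1:10)
  ep <- data.frame(well_id = sprintf("w%02d", 1:7), b = 1:7)
  j <- match_endpoint_to_timelapse(tl, ep)
  expect_equal(nrow(j), 7)
  expect_equal(attr(j, "unmatched_timelapse"), sprintf("w%02d", 8:10))
  expect_equal(attr(j, "unmatched_endpoint"), character(0))
  jp <- match_endpoint_to_timelapse(tl[sample(10), ], ep[sample(7), ])
  expect_equal(j, jp, ignore_attr = TRUE)
  expect_error(match_endpoint_to_timelapse(rbind(tl, tl[1, ]), ep), "duplicate")
})
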