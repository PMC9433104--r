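test_that("the conjugate filter is strict: contacts must exceed 5 minutes", {
  # three targets with contacts of 5, 10 and 30 minutes at 5-min sampling
  fx <- contact_fixture(list(5, 10:11, 20:25))
  ints <- detect_conjugations(fx$eff, fx$targets)
  expect_equal(nrow(ints), 2)                      # the 5-min contact is out
  expect_setequal(ints$target_id, c("t2", "t3"))
  expect_equal(sort(ints$end_min - ints$start_min), c(10, 30))
})

test_that("contact runs merge over 1-frame gaps and quantize duration by frame count", {
  # contact frames 10-15 inclusive: one interval of 6 frames = 30 min
  fx <- contact_fixture(list(10:15))
  ints <- detect_conjugations(fx$eff, fx$targets)
  expect_equal(nrow(ints), 1)
  expect_equal(ints$n_frames, 6L)
  expect_equal(ints$end_min - ints$start_min, 30)
  expect_equal(ints$start_min, 45)  # frame 10 at 5-min sampling

  # a single-frame dropout inside a contact is bridged
  fx2 <- contact_fixture(list(c(10:12, 14:16)))
  ints2 <- detect_conjugations(fx$eff, fx2$targets)
  expect_equal(nrow(ints2), 1)
  expect_equal(ints2$n_frames, 6L)  # bridged gap frame is not counted

  # a 3-frame separation splits the run
  fx3 <- contact_fixture(list(c(10:12, 16:18)))
  ints3 <- detect_conjugations(fx$eff, fx3$targets)
  expect_equal(nrow(ints3), 2)
  expect_error(
    detect_conjugations(fx$eff, list(t1 = transform(fx$targets$t1,
                                                    t_min = t_min + 1))),
    "frame clock")
})

test_that("conjugation detection equals a brute-force distance recomputation", {
  chip <- cached_chip("oracle", 40, 29, c("serial_killer", "migratory_killer"))
  dt <- chip$config$frame_interval_min
  checked <- 0
  for (w in select_wells(chip$tracks)[1:20]) {
    tw <- chip$tracks[chip$tracks$well_id == w, ]
    eff <- tw[tw$role == "effector", ]
    for (tid in unique(tw$object_id[tw$role == "target"])) {
      tgt <- tw[tw$object_id == tid, ]
      got <- detect_conjugations(eff, stats::setNames(list(tgt), tid))
      frames <- contact_frames_oracle(eff, tgt, slack = 2)
      runs <- contact_runs(frames, 1)
      keep <- Filter(function(r) length(r) * dt > 5, runs)
      expect_equal(nrow(got), length(keep))
      if (length(keep))
        expect_equal(got$start_min, vapply(keep, function(r) (min(r) - 1) * dt, 1))
      checked <- checked + 1
    }
  }
  expect_gt(checked, 30)
})

test_that("kinetic parameters follow their definitions", {
  # first contact 50, detachment 100, death 150
  ints <- data.frame(target_id = "t1", start_min = 50, end_min = 100)
  k <- compute_kinetics(ints, death_min = 150)
  expect_equal(k$t_seek, 50)
  expect_equal(k$t_contact, 50)
  expect_equal(k$t_death, 100)

  # continuous contact until death: equality case
  k2 <- compute_kinetics(data.frame(target_id = "t1", start_min = 20,
                                    end_min = 90), death_min = 80)
  expect_equal(k2$t_contact, 60)
  expect_equal(k2$t_death, 60)

  # no death: cumulative conjugation only
  k3 <- compute_kinetics(data.frame(target_id = "t1",
                                    start_min = c(10, 40),
                                    end_min = c(20, 70)))
  expect_equal(k3$t_contact, 40)
  expect_true(is.na(k3$t_death))

  # death before first contact is invalid
  k4 <- compute_kinetics(ints, death_min = 30)
  expect_false(k4$valid)
})

test_that("well selection applies the single-effector 1-5 target bead predicate", {
  chip <- acceptance_chip()
  sel <- select_wells(chip$tracks)
  truth <- chip$truth$wells
  oracle <- truth$well_id[truth$n_eff == 1 & truth$n_targets >= 1 &
                            truth$n_targets <= 5 & truth$n_beads >= 1]
  expect_setequal(sel, oracle)

  # constructed exclusions: two effectors, or no beads
  two_eff <- data.frame(well_id = "wx", frame = 1,
                        role = c("effector", "effector", "target", "bead"),
                        ch_annexin = 0.05)
  expect_equal(length(select_wells(two_eff)), 0)
  no_bead <- data.frame(well_id = "wx", frame = 1,
                        role = c("effector", "target", "target"),
                        ch_annexin = 0.05)
  expect_equal(length(select_wells(no_bead)), 0)
})

test_that("functional annotation implements the killing/secretion taxonomy", {
  expect_equal(annotate_function(2, FALSE, TRUE)$function_class, "multifunctional")
  expect_equal(annotate_function(2, FALSE, TRUE)$killer_class, "serial_killer")
  expect_equal(annotate_function(1, TRUE, TRUE)$function_class, "multifunctional")
  expect_equal(annotate_function(1, FALSE, TRUE)$function_class, "monofunctional_kill")
  ifng <- annotate_function(0, TRUE, TRUE)
  expect_equal(ifng$function_class, "monofunctional_ifng")
  expect_equal(ifng$killer_class, "nonkiller")
  expect_equal(annotate_function(0, FALSE, TRUE)$function_class, "nonfunctional")
  unconj <- annotate_function(0, TRUE, FALSE)
  expect_false(unconj$conjugated)
  expect_true(is.na(unconj$function_class))
  expect_error(annotate_function(1, NA, TRUE), "endpoint")
})

test_that("secretion calling thresholds against controls and is monotone in k", {
  ctrl <- data.frame(well_id = sprintf("c%02d", 1:12),
                     bead_median = c(100, 101, 99, 100, 102, 98,
                                     100, 101, 99, 100, 100, 100))
  s <- data.frame(well_id = c("w1", "w2"),
                  bead_median = c(mean(ctrl$bead_median), 130))
  call <- call_secretion(s, ctrl)
  expect_false(call[["w1"]])   # exactly at the control mean
  expect_true(call[["w2"]])
  expect_error(call_secretion(s, ctrl[1:5, ]), "control")
  for (k in c(1, 2, 4, 8)) {
    lo <- call_secretion(s, ctrl, k = k)
    hi <- call_secretion(s, ctrl, k = k + 1)
    expect_true(all(lo | !hi))  # raising k never flips negative to positive
  }
})

test_that("secretors separated from controls by 5 SD are labeled near-perfectly", {
  set.seed(77)
  noise <- function(n) rlnorm(n, log(3), 0.6)
  ctrl_pop <- 100 + noise(5000)
  sd5 <- 5 * sd(ctrl_pop)
  ctrl <- data.frame(well_id = sprintf("c%03d", 1:50),
                     bead_median = 100 + noise(50))
  wells <- data.frame(well_id = sprintf("w%03d", 1:500),
                      bead_median = c(100 + noise(250),          # silent
                                      100 + sd5 + noise(250)))   # secretors
  truth <- rep(c(FALSE, TRUE), each = 250)
  called <- call_secretion(wells, ctrl)
  expect_gte(mean(called == truth), 0.99)
})

test_that("t_Contact never exceeds t_Death for killer pairs", {
  ana <- acceptance_analysis()
  kk <- ana$kinetics[ana$kinetics$kill & ana$kinetics$valid, ]
  expect_gt(nrow(kk), 200)
  expect_true(all(kk$t_contact <= kk$t_death + 1e-9))
  # detachment precedes apoptosis at the group level
  expect_lt(median(kk$t_contact), median(kk$t_death))
})

test_that("the taxonomy is a partition over the baseline population", {
  ana <- acceptance_analysis()
  base <- ana$annotation[ana$annotation$conjugated, ]
  expect_true(all(base$function_class %in%
                    c("multifunctional", "monofunctional_kill",
                      "monofunctional_ifng", "nonfunctional")))
  expect_true(all(table(base$well_id) == 1))
  # serial killers never exceed the number of targets present
  chip <- acceptance_chip()
  m <- merge(ana$annotation, chip$truth$wells, by = "well_id")
  expect_true(all(m$n_kills <= m$n_targets))
})
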