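test_that("frame partition matches interval membership exactly", {
  chain <- make_chain(rep(0, 20), rep(0, 20))  # frames 1..20, t = 0..95
  none <- partition_frames(chain, data.frame(start_min = numeric(),
                                             end_min = numeric()))
  expect_true(all(none == "out_of_contact"))

  ints <- data.frame(start_min = 20, end_min = 50)  # frames 5..10 (t 20..45)
  lab <- partition_frames(chain, ints)
  expect_equal(which(lab == "in_contact"), 5:10)

  # brute-force membership recomputation
  oracle <- vapply(chain$t_min, function(t)
    any(t >= ints$start_min & t < ints$end_min), TRUE)
  expect_equal(lab == "in_contact", oracle)
})

test_that("directional runs capture straight motion and reject jitter", {
  d <- 12  # cell diameter for area 113
  straight <- make_chain(seq(0, 36, by = 4), rep(0, 10))
  runs <- directional_runs(straight, cell_diameter_um = d)
  expect_equal(nrow(runs), 1)
  expect_equal(runs$displacement_um, 36)

  set.seed(8)
  jitter <- make_chain(cumsum(rnorm(15, 0, 0.3)), cumsum(rnorm(15, 0, 0.3)))
  expect_equal(nrow(directional_runs(jitter, cell_diameter_um = d)), 0)

  expect_equal(nrow(directional_runs(straight[1:2, ], d)), 0)  # < 3 frames
})

test_that("greedy runs agree with per-start exhaustive extension on short series", {
  set.seed(19)
  for (rep in 1:60) {
    n <- sample(4:12, 1)
    x <- cumsum(rnorm(n, 0, 3)); y <- cumsum(rnorm(n, 0, 3))
    got <- nanotiming:::greedy_runs(x, y, 45)
    oracle <- runs_enum_oracle(x, y, 45)
    expect_equal(got, oracle)
  }
})

test_that("migration rates are displacement per minute in each contact state", {
  # single 30-um out-of-contact run over a 60-min out-of-contact span
  runs <- data.frame(start_min = 0, end_min = 30, displacement_um = 30,
                     state = "out_of_contact")
  state <- rep(c("out_of_contact", "in_contact"), c(12, 8))  # 60 + 40 min
  r <- migration_rates(runs, state)
  expect_equal(r$out_of_contact_rate, 0.5)
  expect_equal(r$in_contact_rate, 0)
  expect_true(r$migratory_flag)

  none <- migration_rates(runs[0, ], state)
  expect_equal(none$out_of_contact_rate, 0)
  expect_false(none$migratory_flag)

  # zero time in a state gives a missing rate
  allout <- migration_rates(runs, rep("out_of_contact", 10))
  expect_true(is.na(allout$in_contact_rate))
})

test_that("runs are invariant to rotation and rates scale with coordinates", {
  set.seed(4)
  n <- 30
  x <- cumsum(rnorm(n, 2, 1)); y <- cumsum(rnorm(n, 0.5, 1))
  chain <- make_chain(x, y)
  d <- cell_diameter(chain)
  base <- directional_runs(chain, d)

  th <- 0.7  # rotate the whole trajectory
  rot <- make_chain(x * cos(th) - y * sin(th), x * sin(th) + y * cos(th))
  rruns <- directional_runs(rot, d)
  expect_equal(nrow(base), nrow(rruns))
  expect_equal(base$displacement_um, rruns$displacement_um)

  cc <- 3  # scale coordinates and the diameter; rates scale by cc
  sc <- make_chain(cc * x, cc * y)
  sruns <- directional_runs(sc, cc * d)
  state <- rep("out_of_contact", n)
  expect_equal(migration_rates(sruns, state)$out_of_contact_rate,
               cc * migration_rates(base, state)$out_of_contact_rate)
})

test_that("runs never span contact-state changes", {
  x <- seq(0, 76, by = 4); n <- length(x)
  chain <- make_chain(x, rep(0, n))
  state <- rep(c("out_of_contact", "in_contact"), each = n / 2)
  runs <- directional_runs(chain, cell_diameter_um = 12, state = state)
  expect_equal(nrow(runs), 2)
  expect_setequal(runs$state, c("out_of_contact", "in_contact"))
  # straight line split in two: each segment's displacement below the total
  expect_true(all(runs$displacement_um < 76))
})

test_that("migratory killers out-migrate nonmigratory nonkillers", {
  chip <- cached_chip("mig", 200, 11, c("migratory_killer",
                                        "nonmigratory_nonkiller"))
  ana <- cached_analysis(chip, "mig_200_11")
  m <- merge(ana$migration, chip$truth$wells[, c("well_id", "phenotype")],
             by = "well_id")
  g1 <- m$out_of_contact_rate[m$phenotype == "migratory_killer"]
  g2 <- m$out_of_contact_rate[m$phenotype == "nonmigratory_nonkiller"]
  g1 <- g1[!is.na(g1)]; g2 <- g2[!is.na(g2)]
  expect_gte(min(length(g1), length(g2)), 80)
  expect_gt(median(g1), median(g2))
  expect_lt(mann_whitney_u(g1, g2)$p_two_sided, 0.05)
})

test_that("aspect-ratio profiles cover the chain and floor at 1", {
  chain <- data.frame(frame = 1:3,
                      axis_major_um = c(10, 14, 10),
                      axis_minor_um = c(10, 7, 0))
  prof <- aspect_ratio_profile(chain)
  expect_equal(nrow(prof), 3)
  expect_equal(prof$aspect_ratio, c(1, 2, 1))
  expect_equal(prof$degenerate, c(FALSE, FALSE, TRUE))
  expect_true(all(prof$aspect_ratio >= 1))
  expect_error(aspect_ratio_profile(data.frame(frame = 1)), "axis")
})
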