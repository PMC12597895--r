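# Engine-level behavior of the tumor-immune model: mechanics, migration,
# division/death, attacks, and the bookkeeping the trajectory exposes.

three_type_config <- function(attack_rate = 0.0003, duration_min = 720,
                              save_interval_min = 6, division_rate = 0.03,
                              kill_probability = 0.8) {
  simulation_config(
    types = list(
      cancer = cell_type_params(division_rate = division_rate,
                                apoptosis_rate = 0.004),
      healthy = cell_type_params(),
      CD8 = cell_type_params(motility_speed = 2, persistence_time = 10)),
    attack = attack_params(attack_rate = attack_rate,
                           kill_probability = kill_probability),
    duration_min = duration_min, save_interval_min = save_interval_min)
}

test_that("a frozen system never changes", {
  cfg <- single_type_config(cell_type_params(), duration_min = 1440,
                            save_interval_min = 60)
  # non-overlapping cells: no mechanics force either
  init <- initial_state(x = c(-30, 0, 30), y = c(0, 10, 0),
                        type = rep("cancer", 3),
                        domain = c(-100, 100, -100, 100))
  tr <- simulate_abm(init, cfg, seed = 1)
  for (s in tr$snapshots) {
    expect_identical(s$agents$x, init$cells$x)
    expect_identical(s$agents$y, init$cells$y)
  }
})

test_that("identical seeds give byte-identical summaries", {
  cfg <- three_type_config(attack_rate = 0.01, duration_min = 360,
                           save_interval_min = 60)
  set.seed(42)
  init <- init_well_mixed(c(cancer = 150, healthy = 50, CD8 = 40),
                          geom_disc(c(0, 0), 120),
                          domain = c(-200, 200, -200, 200))
  f1 <- tempfile(); f2 <- tempfile()
  write_timeseries_csv(simulate_abm(init, cfg, seed = 7), f1)
  write_timeseries_csv(simulate_abm(init, cfg, seed = 7), f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("pairwise repulsion has compact support and acts symmetrically", {
  one_substep <- function(x, y) {
    cfg <- single_type_config(cell_type_params(radius = 8),
                              duration_min = 0.5, dt_phen = 0.5,
                              dt_mech = 0.5, repulsion = 10,
                              save_interval_min = 0.5)
    init <- initial_state(x = x, y = y, type = rep("cancer", length(x)),
                          domain = c(-100, 100, -100, 100))
    tr <- simulate_abm(init, cfg, seed = 1)
    tr$snapshots[[2]]$agents
  }
  # beyond and exactly at the interaction radius r_i + r_j = 16: no motion
  apart <- one_substep(c(-10, 10), c(0, 0))
  expect_identical(apart$x, c(-10, 10))
  touching <- one_substep(c(-8, 8), c(0, 0))
  expect_identical(touching$x, c(-8, 8))
  # symmetric overlap: equal and opposite displacement, magnitude
  # dt * strength * (1 - d/R)^2 = 0.5 * 10 * (1 - 4/16)^2 = 2.8125
  over <- one_substep(c(-2, 2), c(0, 0))
  expect_equal(over$x, c(-2 - 2.8125, 2 + 2.8125))
  expect_equal(over$x[1] + over$x[2], 0)
  expect_equal(over$y, c(0, 0))
})

test_that("relaxation dissipates overlap energy monotonically", {
  set.seed(15)
  p <- sample_uniform_in_geometry(100, geom_disc(c(0, 0), 60))
  cfg <- single_type_config(cell_type_params(radius = 8),
                            duration_min = 60, save_interval_min = 6)
  init <- initial_state(p[, 1], p[, 2], rep("cancer", 100),
                        domain = c(-150, 150, -150, 150))
  tr <- simulate_abm(init, cfg, seed = 1)
  energy <- vapply(tr$snapshots, function(s) {
    d <- as.matrix(dist(cbind(s$agents$x, s$agents$y)))
    ov <- pmax(0, 1 - d / 16)
    sum(ov[upper.tri(ov)]^3)
  }, numeric(1))
  expect_true(all(diff(energy) <= 1e-9))
})

test_that("all agents stay inside the reflecting domain", {
  cfg <- three_type_config(attack_rate = 0.01, duration_min = 720,
                           save_interval_min = 60)
  set.seed(2)
  init <- init_well_mixed(c(cancer = 100, healthy = 30, CD8 = 30),
                          geom_disc(c(0, 0), 95),
                          domain = c(-100, 100, -100, 100))
  tr <- simulate_abm(init, cfg, seed = 2)
  for (s in tr$snapshots) {
    expect_true(all(abs(s$agents$x) <= 100 & abs(s$agents$y) <= 100))
  }
})

test_that("non-motile types never move by migration; motile steps are exact", {
  # persistence >> run length: direction is effectively fixed, so each
  # phenotype step displaces by exactly speed * dt_phen along it
  cfg <- simulation_config(
    types = list(CD8 = cell_type_params(motility_speed = 2,
                                        persistence_time = 1e12)),
    attack = attack_params(attack_rate = 0),
    attacker_type = "CD8", target_type = "CD8",
    duration_min = 30, save_interval_min = 6)
  init <- initial_state(0, 0, "CD8", domain = c(-1e4, 1e4, -1e4, 1e4))
  tr <- simulate_abm(init, cfg, seed = 3)
  pos <- t(vapply(tr$snapshots, function(s) c(s$agents$x, s$agents$y),
                  numeric(2)))
  steps <- diff(pos)
  expect_equal(sqrt(rowSums(steps^2)), rep(12, 5))
  for (k in 2:5) expect_equal(steps[k, ], steps[1, ])

  cfg0 <- single_type_config(cell_type_params(motility_speed = 0),
                             duration_min = 60)
  init0 <- initial_state(c(0, 40), c(0, 0), rep("cancer", 2),
                         domain = c(-100, 100, -100, 100))
  tr0 <- simulate_abm(init0, cfg0, seed = 4)
  expect_identical(tr0$snapshots[[length(tr0$snapshots)]]$agents$x,
                   c(0, 40))
})

test_that("migration follows the persistent-random-walk MSD closed form", {
  n_cells <- 400L
  n_steps <- 50L
  cfg <- simulation_config(
    types = list(CD8 = cell_type_params(motility_speed = 2,
                                        persistence_time = 10)),
    attack = attack_params(attack_rate = 0),
    mechanics = mechanics_params(repulsion_strength = 0),
    attacker_type = "CD8", target_type = "CD8",
    duration_min = n_steps * 6, save_interval_min = n_steps * 6)
  # spread starting points so cells are independent even in principle
  xs <- rep(seq(-9500, 9500, length.out = 20), 20)
  ys <- rep(seq(-9500, 9500, length.out = 20), each = 20)
  init <- initial_state(xs, ys, rep("CD8", n_cells),
                        domain = c(-11000, 11000, -11000, 11000))
  tr <- simulate_abm(init, cfg, seed = 5)
  fin <- tr$snapshots[[2]]$agents
  d2 <- (fin$x - xs)^2 + (fin$y - ys)^2
  expected <- prw_msd(n_steps, step = 2 * 6, p = 6 / 10)
  se <- stats::sd(d2) / sqrt(n_cells)
  expect_lt(abs(mean(d2) - expected), 3 * se)
})

test_that("contact inhibition blocks division in crowded neighborhoods", {
  # 25 cells within one contact radius of each other: everyone has 24
  # neighbors, far above the threshold, so a huge division rate does nothing
  th <- seq(0, 2 * pi, length.out = 26)[-26]
  cfg <- single_type_config(
    cell_type_params(division_rate = 9, max_neighbors_for_division = 5L),
    duration_min = 120, repulsion = 0)
  init <- initial_state(5 * cos(th), 5 * sin(th), rep("cancer", 25),
                        domain = c(-50, 50, -50, 50))
  tr <- simulate_abm(init, cfg, seed = 6)
  expect_equal(tr$summary$cancer, rep(25, nrow(tr$summary)))

  # an isolated cell with the same rate proliferates
  lone <- initial_state(0, 0, "cancer", domain = c(-200, 200, -200, 200))
  tr2 <- simulate_abm(lone, single_type_config(
    cell_type_params(division_rate = 9, max_neighbors_for_division = 5L),
    duration_min = 60), seed = 6)
  expect_gt(tr2$summary$cancer[nrow(tr2$summary)], 5)
  expect_equal(sum(tr2$log$divisions),
               tr2$summary$cancer[nrow(tr2$summary)] - 1)
})

test_that("healthy cells neither divide nor die under any scenario", {
  cfg <- three_type_config(attack_rate = 0.02, duration_min = 720,
                           save_interval_min = 60, division_rate = 0.1)
  set.seed(9)
  init <- init_well_mixed(c(cancer = 120, healthy = 60, CD8 = 50),
                          geom_disc(c(0, 0), 100),
                          domain = c(-150, 150, -150, 150))
  tr <- simulate_abm(init, cfg, seed = 9)
  expect_equal(tr$summary$healthy, rep(60, nrow(tr$summary)))
})

test_that("the attack state machine engages, locks, and kills on schedule", {
  cfg <- simulation_config(
    types = list(cancer = cell_type_params(),
                 CD8 = cell_type_params()),
    attack = attack_params(attack_rate = 0.15, attack_duration = 30,
                           kill_probability = 1),
    mechanics = mechanics_params(repulsion_strength = 0),
    duration_min = 120, save_interval_min = 6)
  init <- initial_state(x = c(10, 0), y = c(0, 0),
                        type = c("cancer", "CD8"),
                        domain = c(-50, 50, -50, 50))
  tr <- simulate_abm(init, cfg, seed = 1)
  ongoing <- tr$summary$ongoing_attacks
  expect_equal(max(ongoing), 1L)                  # one exclusive pair
  start <- which(ongoing == 1L)[1L]
  # the timer advances in the engaging epoch, so the pair is recorded in
  # attack_duration / dt_phen - 1 = 4 snapshots before the kill resolves
  expect_equal(sum(ongoing == 1L), 4L)
  expect_equal(tr$summary$cancer[start + 4L], 0L)
  expect_equal(sum(tr$log$kills), 1L)
  # pair symmetry while locked
  locked <- tr$snapshots[[start + 1L]]$agents
  expect_equal(locked$partner, c(1L, 0L))
  expect_equal(count_ongoing_attacks(tr$snapshots[[start + 1L]]), 1L)
})

test_that("equidistant targets resolve to the lowest agent id", {
  cfg <- simulation_config(
    types = list(cancer = cell_type_params(), CD8 = cell_type_params()),
    attack = attack_params(attack_rate = 0.15, attack_duration = 30,
                           kill_probability = 0),
    mechanics = mechanics_params(repulsion_strength = 0),
    duration_min = 6, save_interval_min = 6)
  init <- initial_state(x = c(-10, 10, 0), y = c(0, 0, 0),
                        type = c("cancer", "cancer", "CD8"),
                        domain = c(-50, 50, -50, 50))
  engaged <- 0L
  for (seed in 1:8) {
    tr <- simulate_abm(init, cfg, seed = seed)
    ag <- tr$snapshots[[2]]$agents
    cd8_partner <- ag$partner[ag$type == "CD8"]
    if (!is.na(cd8_partner)) {
      engaged <- engaged + 1L
      expect_equal(cd8_partner, 0L)  # the first cancer row, lower id
    }
  }
  expect_gt(engaged, 0L)
})

test_that("attacks never outnumber either population and free no ghosts", {
  cfg <- three_type_config(attack_rate = 0.05, duration_min = 720,
                           save_interval_min = 60,
                           kill_probability = 0.5)
  set.seed(10)
  init <- init_well_mixed(c(cancer = 80, healthy = 20, CD8 = 60),
                          geom_disc(c(0, 0), 90),
                          domain = c(-120, 120, -120, 120))
  tr <- simulate_abm(init, cfg, seed = 10)
  for (s in tr$snapshots) {
    expect_lte(s$ongoing_attacks, min(s$counts["cancer"], s$counts["CD8"]))
    paired <- which(!is.na(s$agents$partner))
    if (length(paired) > 0L) {
      # involution: my partner's partner is me
      idx <- match(s$agents$partner[paired], s$agents$id)
      expect_false(anyNA(idx))
      expect_equal(s$agents$partner[idx], s$agents$id[paired])
    }
  }
})

test_that("cancer count changes reconcile with the epoch log", {
  cfg <- three_type_config(attack_rate = 0.02, duration_min = 360,
                           save_interval_min = 6, division_rate = 0.2)
  set.seed(14)
  init <- init_well_mixed(c(cancer = 200, healthy = 40, CD8 = 60),
                          geom_disc(c(0, 0), 110),
                          domain = c(-150, 150, -150, 150))
  tr <- simulate_abm(init, cfg, seed = 14)
  # one epoch per saved snapshot here
  delta <- diff(tr$summary$cancer)
  with(tr$log, expect_equal(delta, divisions - deaths - kills))
})

test_that("probability overflow is rejected before a run starts", {
  expect_error(three_type_config(attack_rate = 0.2), "overflow")
  expect_error(single_type_config(cell_type_params(division_rate = 11),
                                  duration_min = 6), "overflow")
})
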