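## waters parked at fixed positions inside the default pore
make_water_traj <- function(positions, n_frames = 5, box = c(80, 80, 145),
                            extra_ion = NULL) {
  n_w <- nrow(positions)
  n <- n_w + if (is.null(extra_ion)) 0 else 1
  sys <- pore_system(data.frame(
    id = seq_len(n),
    role = c(rep("water_oxygen", n_w), if (!is.null(extra_ion)) "ion"),
    resname = c(rep("HOH", n_w), if (!is.null(extra_ion)) "K"),
    atom = c(rep("OW", n_w), if (!is.null(extra_ion)) "K"),
    element = c(rep("O", n_w), if (!is.null(extra_ion)) "K")))
  m <- rbind(positions, extra_ion)
  make_traj(rep(list(m), n_frames), system = sys, box = box)
}

test_that("occupancy map averages parked waters into the right bin", {
  pore <- default_pore_model()
  ## 10 waters inside one 1-A slice at z = 60.5, on the pore axis
  pos <- cbind(40 + runif(10, -1, 1), 40 + runif(10, -1, 1), 60.2 + runif(10, 0, 0.6))
  traj <- make_water_traj(pos, n_frames = 100)
  m <- water_occupancy_map(traj, pore, bin_width = 1)
  bin <- findInterval(60.5, m$breaks)
  expect_equal(m$average[bin], 10)
  expect_equal(sum(m$average), 10)
  ## degenerate cylinder: radius 0 counts nothing
  pore0 <- pore
  pore0$pore_radius <- 0
  expect_equal(sum(water_occupancy_map(traj, pore0)$average), 0)
})

test_that("uniform water slab gives flat per-bin averages within Poisson noise", {
  set.seed(31)
  n_w <- 400
  pos <- cbind(40 + runif(n_w, -3, 3), 40 + runif(n_w, -3, 3),
               runif(n_w, 40, 80))
  traj <- make_water_traj(pos, n_frames = 1)
  pore <- default_pore_model()
  m <- water_occupancy_map(traj, pore, z_range = c(40, 80), bin_width = 4)
  expected <- n_w / 10 / 4 # per 1 A
  expect_true(all(abs(m$average - expected) <= 3 * sqrt(expected * 4) / 4))
})

test_that("cavity water count agrees with the occupancy map and handles
           empty regions", {
  set.seed(32)
  pos <- cbind(40 + runif(85, -3, 3), 40 + runif(85, -3, 3),
               runif(85, 55.01, 69.99))
  traj <- make_water_traj(pos, n_frames = 4)
  cnt <- cavity_water_count(traj, 55, 70, pore_radius = 8)
  expect_equal(cnt$value, rep(85L, 4))
  pore <- default_pore_model()
  m <- water_occupancy_map(traj, pore, z_range = c(55, 70), bin_width = 1)
  expect_equal(sum(m$counts[1, ]), 85)
  expect_equal(cavity_water_count(traj, 100, 120, pore_radius = 8)$value,
               rep(0L, 4))
})

test_that("hydration numbers use a closed boundary and match brute force", {
  th <- seq(0, 288, by = 72) * pi / 180
  shell <- cbind(40 + 3 * cos(th), 40 + 3 * sin(th), 60)
  traj <- make_water_traj(shell, n_frames = 2, extra_ion = c(40, 40, 60))
  expect_equal(hydration_number(traj, 6)$value, rep(5L, 2))
  ## exactly at the cutoff counts
  att <- make_water_traj(matrix(c(40, 40, 63.5), 1), n_frames = 1,
                         extra_ion = c(40, 40, 60))
  expect_equal(hydration_number(att, 2)$value, 1L)
  expect_error(hydration_number(att, 99), "unknown")
  set.seed(33)
  for (rep in 1:100) {
    waters <- cbind(runif(30, 0, 80), runif(30, 0, 80), runif(30, 0, 145))
    ion <- c(runif(2, 0, 80), runif(1, 0, 145))
    traj <- make_water_traj(waters, n_frames = 1, extra_ion = ion)
    got <- hydration_number(traj, 31)$value
    expect_equal(got, oracle_hydration(ion, waters, c(80, 80, 145)))
  }
})

test_that("G-loop pass snapshots: cylinder membership and summary means", {
  pore <- default_pore_model()
  ## scaffolded trajectory with one ion parked in the gate cylinder and
  ## pair distances fixed by the static gate beads (aperture 6 A on one
  ## pair; the other pair is pushed out to 9 A)
  s <- script_scenario("single_crossing", list(n_frames = 10))
  traj <- s$trajectory
  gz <- mean(traj$coords[resolve_selection(traj$system,
                                           sel(resno = c(318, 319))), 3, 1])
  traj$coords[traj$system$role == "ion", 3, ] <- gz
  ## widen the B/D gate pair so the A/C pair (6 A) is the narrower one
  bd <- resolve_selection(traj$system,
                          sel(subunit = c("B", "D"), resno = 319, atom = "SD"))
  traj$coords[bd, 2, ] <- c(40 + 4.5, 40 - 4.5)
  gp <- gloop_pass_snapshots(
    traj, sel(resno = c(318, 319)),
    pair1 = list(sel(subunit = "A", resno = 316:320),
                 sel(subunit = "C", resno = 316:320)),
    pair2 = list(sel(subunit = "B", resno = 316:320),
                 sel(subunit = "D", resno = 316:320)))
  expect_equal(gp$summary$n_snapshots, 10)
  expect_equal(gp$summary$mean_distance, 6)
  ## an ion 4.1 A off-axis is outside the cylinder
  traj$coords[traj$system$role == "ion", 1, ] <- 40 + 4.1
  expect_warning(
    gp2 <- gloop_pass_snapshots(
      traj, sel(resno = c(318, 319)),
      pair1 = list(sel(subunit = "A", resno = 316:320),
                   sel(subunit = "C", resno = 316:320)),
      pair2 = list(sel(subunit = "B", resno = 316:320),
                   sel(subunit = "D", resno = 316:320))),
    "no G-loop pass")
  expect_equal(gp2$summary$n_snapshots, 0)
  expect_true(is.na(gp2$summary$mean_distance))
})

test_that("wetting state thresholds and fractions recount correctly", {
  w <- wetting_state(c(0, 0, 5, 5), threshold = 1)
  expect_equal(w$state, c("dry", "dry", "wet", "wet"))
  expect_equal(w$wet_fraction, 0.5)
  expect_equal(wetting_state(c(0, 0, 5, 5), threshold = 6)$wet_fraction, 0)
  set.seed(34)
  counts <- rpois(200, 3)
  w2 <- wetting_state(counts, threshold = 4)
  expect_equal(w2$wet_fraction, mean(counts >= 4))
  expect_error(wetting_state(counts, threshold = 0), ">= 1")
})

test_that("hydration of a bulk ion tracks the configured solvation shell", {
  cfg <- synthetic_pore_config(seed = 35, n_frames = 200, n_ions = 2,
                               n_waters = 60, mode = "rate",
                               target_rate_per_us = 0, solvation_shell = 6)
  g <- generate_pore_trajectory(cfg)
  ion_ids <- g$trajectory$system$id[g$trajectory$system$role == "ion"]
  h <- hydration_number(g$trajectory, ion_ids[1])
  expect_gte(mean(h$value), 6 - 1)
  expect_lte(mean(h$value), 6 + 2)
})
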