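test_that("generation is deterministic for a fixed seed", {
  cfg <- synthetic_pore_config(seed = 81, n_frames = 300, n_ions = 4,
                               n_waters = 40, mode = "rate",
                               target_rate_per_us = 20,
                               sf_single_occupancy = TRUE,
                               solvation_shell = 3)
  g1 <- generate_pore_trajectory(cfg)
  g2 <- generate_pore_trajectory(cfg)
  expect_identical(g1$trajectory$coords, g2$trajectory$coords)
  expect_identical(g1$ground_truth$planted_events,
                   g2$ground_truth$planted_events)
  ## and the emitted files are byte-identical
  d1 <- tempfile(); d2 <- tempfile()
  p1 <- write_pore_run(g1, d1)
  p2 <- write_pore_run(g2, d2)
  expect_identical(readLines(p1["frames"]), readLines(p2["frames"]))
})

test_that("a configuration without ions yields zero permeation events", {
  cfg <- synthetic_pore_config(seed = 82, n_frames = 200, n_ions = 0,
                               mode = "rate", target_rate_per_us = 50)
  g <- generate_pore_trajectory(cfg)
  expect_equal(g$ground_truth$n_planted_events, 0)
  expect_error(ion_traces(g$trajectory, cfg$pore), "no ions")
})

test_that("flat potential at zero field equilibrates to a uniform z
           distribution", {
  cfg <- synthetic_pore_config(seed = 83, n_frames = 5e4, n_ions = 8,
                               mode = "diffusion",
                               potential = data.frame(z = c(40, 90),
                                                      U = c(0, 0)),
                               voltage_mV = 0, include_scaffold = FALSE)
  g <- generate_pore_trajectory(cfg)
  ## subsample to decorrelate, then bin with 3-sigma Poisson bands
  z <- as.vector(g$trajectory$coords[, 3, seq(1, 5e4, by = 100)])
  counts <- table(cut(z, seq(40, 90, by = 5)))
  expected <- length(z) / 10
  expect_true(all(abs(counts - expected) <= 3 * sqrt(expected)))
  ## pre-registered KS threshold 0.05 against the exact stationary law
  ks <- suppressWarnings(ks.test(z, "punif", 40, 90))
  expect_lt(unname(ks$statistic), 0.05)
})

test_that("equilibrium sampling follows exp(-U/kT) on a linear ramp", {
  kT <- kT_kcal(310)
  cfg <- synthetic_pore_config(seed = 84, n_frames = 5e4, n_ions = 8,
                               mode = "diffusion",
                               potential = data.frame(z = c(40, 90),
                                                      U = c(0, 5 * kT)),
                               voltage_mV = 0, include_scaffold = FALSE)
  g <- generate_pore_trajectory(cfg)
  z <- as.vector(g$trajectory$coords[, 3, seq(1, 5e4, by = 100)])
  cdf <- function(q) (1 - exp(-(q - 40) / 10)) / (1 - exp(-5))
  ks <- suppressWarnings(ks.test(z, cdf))
  expect_lt(unname(ks$statistic), 0.05)
})

test_that("field-driven drift on a flat potential matches mobility x force", {
  kT <- kT_kcal(310)
  D <- 0.2
  cfg <- synthetic_pore_config(seed = 85, n_frames = 2000, n_ions = 64,
                               mode = "diffusion",
                               potential = data.frame(z = c(-1e5, 1e5),
                                                      U = c(0, 0)),
                               ion_z_range = c(-1e5, 1e5),
                               voltage_mV = 290, include_scaffold = FALSE)
  g <- generate_pore_trajectory(cfg)
  z <- g$trajectory$coords[, 3, ]
  T_ps <- (2000 - 1) * 20
  v_obs <- mean(z[, ncol(z)] - z[, 1]) / T_ps
  v_pred <- D / kT * 0.0230605 * 290 / 145
  expect_lt(abs(v_obs - v_pred) / v_pred, 0.10)
})

test_that("the knock-on rule conserves ions and never co-locates two in a
           site", {
  cfg <- synthetic_pore_config(seed = 86, n_frames = 10000, n_ions = 6,
                               mode = "rate", target_rate_per_us = 40,
                               sf_single_occupancy = TRUE,
                               include_scaffold = FALSE)
  g <- generate_pore_trajectory(cfg)
  pore <- cfg$pore
  z <- g$trajectory$coords[g$trajectory$system$role == "ion", 3, ]
  expect_equal(nrow(z), 6)
  expect_true(all(is.finite(z)))
  for (f in seq(1, 10000, by = 7)) {
    sites <- findInterval(z[, f], pore$z_sites)
    sites <- sites[z[, f] >= pore$z_sites[1] & z[, f] < pore$z_sites[6]]
    expect_equal(anyDuplicated(sites), 0)
  }
})

test_that("gate flicker follows the configured kinetics and moves the gate
           beads", {
  cfg <- synthetic_pore_config(
    seed = 87, n_frames = 20000, n_ions = 0,
    gate_flicker = list(gloop = list(open_rate = 5, close_rate = 5,
                                     open_radius = 4, closed_radius = 1.2)),
    mode = "rate", target_rate_per_us = 0)
  g <- generate_pore_trajectory(cfg)
  gt <- g$ground_truth$gate_open_fraction$gloop
  expect_equal(gt$analytic_open_fraction, 0.5)
  expect_lt(abs(gt$realized_open_fraction - 0.5), 0.05)
  ## opposing M319 side-chain beads sit at twice the gate radius
  d <- min_distance(g$trajectory,
                    sel(subunit = "A", resno = 319, atom = "SD"),
                    sel(subunit = "C", resno = 319, atom = "SD"))
  expect_setequal(round(unique(d$value), 6), c(8, 2.4))
  expect_lt(abs(mean(d$value == 8) - gt$realized_open_fraction), 1e-9)
})

test_that("water regions reproduce the configured density profile", {
  prof <- data.frame(z_low = c(10, 40, 80), z_high = c(30, 60, 120),
                     density = c(1, 2, 0.5))
  cfg <- synthetic_pore_config(seed = 88, n_frames = 50, n_ions = 0,
                               n_waters = 300,
                               water_density_profile = prof, mode = "rate",
                               target_rate_per_us = 0)
  g <- generate_pore_trajectory(cfg)
  z <- g$trajectory$coords[g$trajectory$system$role == "water_oxygen", 3, ]
  counts <- vapply(seq_len(3), function(r) {
    mean(colSums(z >= prof$z_low[r] & z <= prof$z_high[r]))
  }, numeric(1))
  w <- (prof$z_high - prof$z_low) * prof$density
  want <- 300 * w / sum(w)
  expect_equal(counts, want, tolerance = 0.02)
  ## chi-squared of per-region occupancy against the configured profile
  chi2 <- sum((counts - want)^2 / want)
  expect_lt(chi2, qchisq(0.999, df = 2))
})

test_that("configuration validation rejects inconsistent setups", {
  expect_error(synthetic_pore_config(
    potential = data.frame(z = c(50, 60), U = c(0, 0)), mode = "diffusion",
    ion_z_range = c(10, 100)), "span")
  expect_error(synthetic_pore_config(
    gate_flicker = list(gloop = list(open_rate = 1, close_rate = 1,
                                     open_radius = 1, closed_radius = 2))))
  expect_error(script_scenario("no_such_scenario"), "unknown scenario")
  expect_error(script_scenario("knockon_chain", list(n_ions = 6)),
               "capacity")
})
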