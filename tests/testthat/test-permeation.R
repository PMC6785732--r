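test_that("ion traces label compartments in order and unwrap wraps", {
  pore <- default_pore_model()
  sys <- make_ion_system(1)
  z <- seq(15, 110, length.out = 120)
  traj <- make_traj(lapply(z, function(zz) matrix(c(40, 40, zz), 1)),
                    system = sys, box = c(80, 80, 145))
  tr <- ion_traces(traj, pore)[[1]]
  comp <- unique(tr$compartment)
  expect_equal(comp, c("bulk_in", "CTD", "Gloop", "cavity", "S4", "S3",
                       "S2", "S1", "S0", "bulk_out"))
  ## stationary ion: constant trace
  traj0 <- make_traj(rep(list(matrix(c(40, 40, 60), 1)), 5), system = sys,
                     box = c(80, 80, 145))
  expect_equal(unique(ion_traces(traj0, pore)[[1]]$z), 60)
  ## wrapped ion: no unwrapped jump exceeds half the box
  zw <- seq(15, 300, length.out = 200) %% 145
  trajw <- make_traj(lapply(zw, function(zz) matrix(c(40, 40, zz), 1)),
                     system = sys, box = c(80, 80, 145))
  trw <- ion_traces(trajw, pore)[[1]]
  expect_true(all(abs(diff(trw$z_unwrapped)) < 145 / 2))
})

test_that("committed-crossing detection: scripted scenarios give exactly 1/0", {
  s <- script_scenario("single_crossing")
  pore <- s$ground_truth$pore
  tr <- ion_traces(s$trajectory, pore)
  expect_equal(nrow(detect_all_events(tr, pore, "SF_full")), 1)
  expect_equal(nrow(detect_all_events(tr, pore, "HBC")), 1)
  expect_equal(nrow(detect_all_events(tr, pore, "Gloop")), 1)
  ev <- detect_all_events(tr, pore, "SF_full")
  expect_equal(ev$direction, "outward")
  expect_lt(ev$entry_frame, ev$exit_frame)
  f <- script_scenario("flicker_no_crossing")
  trf <- ion_traces(f$trajectory, f$ground_truth$pore)
  expect_equal(nrow(detect_all_events(trf, f$ground_truth$pore, "Gloop")), 0)
  expect_equal(nrow(detect_all_events(trf, f$ground_truth$pore, "SF_full")), 0)
})

test_that("event detection is stride-robust and idempotent", {
  s <- script_scenario("single_crossing", list(n_frames = 201))
  pore <- s$ground_truth$pore
  full <- ion_traces(s$trajectory, pore)
  half <- ion_traces(subset_frames(s$trajectory, seq(1, 201, by = 2)), pore)
  expect_equal(nrow(detect_all_events(full, pore, "SF_full")),
               nrow(detect_all_events(half, pore, "SF_full")))
  k <- script_scenario("knockon_chain")
  porek <- k$ground_truth$pore
  n_full <- nrow(detect_all_events(ion_traces(k$trajectory, porek), porek,
                                   "SF_full"))
  idx <- seq(1, n_frames(k$trajectory), by = 2)
  n_half <- nrow(detect_all_events(
    ion_traces(subset_frames(k$trajectory, idx), porek), porek, "SF_full"))
  expect_equal(n_full, n_half)
})

test_that("net event balance matches the compartment census on synthetic runs", {
  ## all ions start in the bulk (no scripted filter residents), so the
  ## start/end census is a clean independent count of net transfer
  cfg <- synthetic_pore_config(seed = 41, n_frames = 20000, n_ions = 6,
                               mode = "rate", target_rate_per_us = 25,
                               include_scaffold = FALSE)
  g <- generate_pore_trajectory(cfg)
  pore <- cfg$pore
  traces <- ion_traces(g$trajectory, pore)
  ev <- detect_all_events(traces, pore, "SF_full")
  net <- sum(ev$direction == "outward") - sum(ev$direction == "inward")
  ## independent census: count ions above the SF top plane at start/end,
  ## accumulated over periodic wraps via the unwrapped coordinate
  top <- max(pore$z_sites) + 2
  census <- sum(vapply(traces, function(tr) {
    floor((tr$z_unwrapped[nrow(tr)] - top) / 145) -
      floor((tr$z_unwrapped[1] - top) / 145)
  }, numeric(1)))
  expect_equal(net, census)
})

test_that("rates, group statistics and conductance reproduce the reference
           run table", {
  runs <- girk2_run_table()
  sf <- runs[runs$interval == "SF_full", ]
  cr <- count_and_rates(sf$events, sf$duration_us, sf$voltage_mV,
                        group = ifelse(sf$restrained, "restrained",
                                       "unrestrained"),
                        run_id = sf$run_id)
  expect_equal(cr$total, 228)
  gu <- cr$groups[cr$groups$group == "unrestrained", ]
  gr <- cr$groups[cr$groups$group == "restrained", ]
  expect_equal(round(gu$mean_rate, 1), 14.2)
  expect_equal(round(gu$sd_rate, 1), 10.8)
  expect_equal(gr$mean_rate, 20)
  expect_equal(round(gr$sd_rate, 0), 10)
  ## run13: 27 events over 1 us at 290 mV -> 14.9 pS
  expect_equal(round(cr$per_run$conductance_pS[sf$run_id == "1us_run13"], 1),
               14.9)
  expect_warning(count_and_rates(c(3, 4), 1, c(0, 290)), "conductance")
  expect_error(count_and_rates(c(3), 0), "> 0")
})

test_that("residence times convert contiguous spans by the stride", {
  pore <- default_pore_model()
  sys <- make_ion_system(1)
  s3_mid <- mean(pore$z_sites[2:3])
  z <- c(rep(20, 10), rep(s3_mid, 250), rep(20, 10))
  traj <- make_traj(lapply(z, function(zz) matrix(c(40, 40, zz), 1)),
                    system = sys, box = c(80, 80, 145))
  tr <- ion_traces(traj, pore)[[1]]
  expect_equal(residence_times(tr, "S3"), 5) # 250 frames x 20 ps = 5 ns
  ## alternating labels dwell one stride each
  za <- rep(c(s3_mid, 20), 20)
  traja <- make_traj(lapply(za, function(zz) matrix(c(40, 40, zz), 1)),
                     system = sys, box = c(80, 80, 145))
  tra <- ion_traces(traja, pore)[[1]]
  expect_true(all(residence_times(tra, "S3") == 0.02))
  ## conservation: dwell total equals labelled-frame total
  expect_equal(sum(residence_times(tr, "S3")) / 0.02,
               sum(tr$compartment == "S3"))
  expect_error(residence_times(tr, "S9"), "unknown site")
})

test_that("cumulative flux is a non-decreasing step function ending at the
           event count", {
  ev <- data.frame(exit_time = c(0.5, 0.1, 0.9) * 1e6)
  fl <- cumulative_flux(ev, t_end = 1e6)
  expect_true(all(diff(fl$cumulative) >= 0))
  expect_equal(max(fl$cumulative), 3)
  fl0 <- cumulative_flux(data.frame(exit_time = numeric(0)), t_end = 1e6)
  expect_equal(max(fl0$cumulative), 0)
})

test_that("field-voltage conversion matches the simulation conditions", {
  expect_equal(field_to_voltage(40, 14.5), 580)
  expect_equal(field_to_voltage(20, 14.5), 290)
  expect_equal(field_to_voltage(0, 14.5), 0)
  expect_error(field_to_voltage(40, 0), "> 0")
})
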