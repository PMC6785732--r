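test_that("min_distance matches the exhaustive pairwise oracle", {
  ## two single atoms at a known separation
  traj <- make_traj(list(rbind(c(0, 0, 0), c(0, 4, 0))))
  expect_equal(min_distance(traj, 1, 2)$value, 4)
  ## random 20 x 20 clouds over several frames
  set.seed(21)
  for (rep in 1:5) {
    frames <- lapply(1:4, function(f) matrix(runif(120, 0, 30), 40))
    traj <- make_traj(frames)
    got <- min_distance(traj, 1:20, 21:40)$value
    want <- vapply(frames, function(m) {
      oracle_min_dist(m[1:20, , drop = FALSE], m[21:40, , drop = FALSE])
    }, numeric(1))
    expect_equal(got, want, tolerance = 1e-12)
  }
  expect_error(min_distance(traj, 1:20, 1:20), "self-pairing")
  expect_error(min_distance(traj, integer(0), 1:3), "empty|unknown")
})

test_that("narrower_pair_series takes the frame-wise smaller pair", {
  f1 <- rbind(c(0, 0, 0), c(5, 0, 0), c(0, 10, 0), c(9, 10, 0))
  traj <- make_traj(list(f1))
  s <- narrower_pair_series(traj, list(1, 2), list(3, 4))
  expect_equal(s$value, 5)
  ## symmetric frame
  s2 <- narrower_pair_series(traj, list(1, 2), list(1, 2))
  expect_equal(s2$value, 5)
  ## random frames equal elementwise minimum of the two series
  set.seed(22)
  frames <- lapply(1:6, function(f) matrix(runif(24, 0, 20), 8))
  traj <- make_traj(frames)
  d1 <- min_distance(traj, 1:2, 3:4)$value
  d2 <- min_distance(traj, 5:6, 7:8)$value
  np <- narrower_pair_series(traj, list(1:2, 3:4), list(5:6, 7:8))$value
  expect_equal(np, pmin(d1, d2))
})

test_that("calpha_distance reproduces the crystal-structure HBC marker", {
  sys <- pore_system(data.frame(
    id = 1:2, role = "protein", subunit = c("A", "C"), resno = 192,
    resname = "PHE", atom = "CA", element = "C"))
  traj <- make_traj(list(rbind(c(0, 0, 0), c(15.3, 0, 0))), system = sys)
  expect_equal(calpha_distance(traj, 192)$value, 15.3)
  traj0 <- make_traj(list(rbind(c(1, 2, 3), c(1, 2, 3))), system = sys)
  expect_equal(calpha_distance(traj0, 192)$value, 0)
  ## invariant under a global rotation
  R <- random_rotation()
  trajR <- make_traj(list(rbind(c(0, 0, 0), c(15.3, 0, 0)) %*% t(R)),
                     system = sys)
  expect_equal(calpha_distance(trajR, 192)$value, 15.3, tolerance = 1e-9)
})

test_that("series histograms bin left-closed and report threshold fractions", {
  h <- series_histogram(c(1, 1, 2, 3), bin_width = 1)
  expect_equal(h$counts, c(2, 1, 1))
  expect_equal(sum(h$counts), 4)
  h2 <- series_histogram(c(5, 6, 7, 8), bin_width = 1, threshold = 6.4)
  expect_equal(h2$fraction_above, 0.5)
  ## fraction from histogram equals direct count on the raw series
  set.seed(23)
  v <- runif(500, 0, 12)
  h3 <- series_histogram(v, bin_width = 0.25, threshold = 6.4)
  expect_equal(h3$fraction_above, mean(v > 6.4))
  expect_equal(sum(h3$counts), length(v))
  expect_error(series_histogram(v, bin_width = 0), "> 0")
})

test_that("backbone RMSD: zero for identity and translation, closed form for
           a known perturbation", {
  set.seed(24)
  base <- matrix(runif(60, 0, 20), 20)
  traj <- make_traj(list(base, base, sweep(base, 2, c(1, 1, 1), `+`)))
  r <- backbone_rmsd(traj, 1:20)
  expect_equal(r$value, c(0, 0, 0), tolerance = 1e-9)
  ## with the fit off, moving k atoms by delta gives sqrt(k delta^2 / N)
  pert <- base
  k <- 5; delta <- 2
  pert[1:k, 1] <- pert[1:k, 1] + delta
  traj2 <- make_traj(list(base, pert))
  r2 <- backbone_rmsd(traj2, 1:20, fit = FALSE)
  expect_equal(r2$value[2], sqrt(k * delta^2 / 20), tolerance = 1e-12)
})

test_that("dihedrals: planar references and random-quadruple oracle", {
  cis <- list(rbind(c(1, 1, 0), c(1, 0, 0), c(2, 0, 0), c(2, 1, 0)))
  expect_equal(dihedral_series(make_traj(cis), 1, 2, 3, 4)$value, 0)
  trans <- list(rbind(c(1, 1, 0), c(1, 0, 0), c(2, 0, 0), c(2, -1, 0)))
  expect_equal(abs(dihedral_series(make_traj(trans), 1, 2, 3, 4)$value), 180)
  set.seed(25)
  for (rep in 1:100) {
    m <- matrix(rnorm(12, sd = 3), 4)
    got <- dihedral_series(make_traj(list(m)), 1, 2, 3, 4)$value
    want <- oracle_dihedral(m[1, ], m[2, ], m[3, ], m[4, ])
    expect_equal(got, want, tolerance = 1e-6)
  }
})

test_that("psi angles use the N-CA-C-N+ backbone convention", {
  sys <- pore_system(data.frame(
    id = 1:4, role = "protein", subunit = "A", resno = c(157, 157, 157, 158),
    resname = c("TYR", "TYR", "TYR", "GLY"), atom = c("N", "CA", "C", "N"),
    element = c("N", "C", "C", "N")))
  m <- rbind(c(1, 1, 0), c(1, 0, 0), c(2, 0, 0), c(2, -1, 0))
  traj <- make_traj(list(m), system = sys)
  expect_equal(abs(psi_series(traj, 157, "A")$value), 180)
})

test_that("ctd_rotation recovers constructed rotations with the printed sign
           convention", {
  r0 <- script_scenario("rotated_ctd", list(angle = 0, n_frames = 2))
  tmd <- sel(resno = 71:75); ctd <- sel(resno = 241:245)
  tmd_a <- sel(subunit = "A", resno = 71:75)
  ctd_a <- sel(subunit = "A", resno = 241:245)
  expect_equal(ctd_rotation(r0$trajectory, tmd, ctd, tmd_a, ctd_a)$value[2], 0)
  for (ang in c(-4, 5, 12.5)) {
    r <- script_scenario("rotated_ctd", list(angle = ang))
    got <- ctd_rotation(r$trajectory, tmd, ctd, tmd_a, ctd_a)$value[2]
    expect_equal(got, ang, tolerance = 0.01)
  }
})

test_that("ctd_rotation composes additively on rigid bead clouds", {
  r1 <- script_scenario("rotated_ctd", list(angle = 3, n_frames = 2))
  r2 <- script_scenario("rotated_ctd", list(angle = 7, n_frames = 2))
  ## apply the 7-degree frame on top of the 3-degree reference
  traj <- r1$trajectory
  traj$coords[, , 1] <- r2$trajectory$coords[, , 2]
  tmd <- sel(resno = 71:75); ctd <- sel(resno = 241:245)
  got <- ctd_rotation(traj, tmd, ctd, sel(subunit = "A", resno = 71:75),
                      sel(subunit = "A", resno = 241:245))$value[2]
  expect_equal(got, 3 - 7, tolerance = 0.05)
})

test_that("cation-pi geometry matches the SVD plane oracle", {
  ## hexagonal ring in the xy plane, ion on the axis
  th <- seq(0, 300, by = 60) * pi / 180
  ring <- cbind(cos(th), sin(th), 0)
  sys <- pore_system(data.frame(
    id = 1:7, role = c(rep("protein", 6), "ion"),
    subunit = c(rep("A", 6), NA), resno = c(rep(192, 6), NA),
    resname = c(rep("PHE", 6), "K"),
    atom = c(paste0("C", 1:6), "K"), element = c(rep("C", 6), "K")))
  on_axis <- make_traj(list(rbind(ring, c(0, 0, 3))), system = sys)
  g <- cation_pi_geometry(on_axis, sel(resno = 192), 7)
  expect_equal(g$distance, 3)
  expect_equal(g$angle, 0, tolerance = 1e-9)
  in_plane <- make_traj(list(rbind(ring, c(3, 0, 0))), system = sys)
  g2 <- cation_pi_geometry(in_plane, sel(resno = 192), 7)
  expect_equal(g2$angle, 90, tolerance = 1e-9)
  ## random rigid motions: distance preserved, angle matches a direct
  ## plane fit in the rotated frame
  set.seed(26)
  for (rep in 1:20) {
    R <- random_rotation(); t0 <- runif(3, -10, 10)
    ion <- c(runif(2, -2, 2), runif(1, 1, 4))
    m <- sweep(rbind(ring, ion) %*% t(R), 2, t0, `+`)
    g3 <- cation_pi_geometry(make_traj(list(m), system = sys),
                             sel(resno = 192), 7)
    expect_equal(g3$distance, sqrt(sum(ion^2)), tolerance = 1e-9)
    want <- acos(abs(ion[3]) / sqrt(sum(ion^2))) * 180 / pi
    expect_equal(g3$angle, want, tolerance = 1e-6)
  }
})

test_that("distance operators are invariant under global rigid motion", {
  set.seed(27)
  frames <- lapply(1:3, function(f) matrix(runif(60, 0, 25), 20))
  traj <- make_traj(frames)
  R <- random_rotation(); t0 <- c(3, -7, 11)
  trajR <- make_traj(lapply(frames, function(m) sweep(m %*% t(R), 2, t0, `+`)))
  expect_equal(min_distance(trajR, 1:10, 11:20)$value,
               min_distance(traj, 1:10, 11:20)$value, tolerance = 1e-9)
})
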