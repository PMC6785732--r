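## Fixture builders and independent brute-force oracles used across the
## suite. Oracles deliberately use the most naive formulation available
## (exhaustive loops, closed forms) so they stay independent of the
## package implementation paths they check.

## a bare system of n untyped ions (useful for coordinate-level tests)
make_ion_system <- function(n) {
  pore_system(data.frame(id = seq_len(n), role = "ion", resname = "K",
                         atom = "K", element = "K"))
}

## trajectory from a list of n x 3 coordinate matrices
make_traj <- function(coord_list, system = NULL, box = c(50, 50, 50),
                      stride = 20) {
  n <- nrow(coord_list[[1]])
  if (is.null(system)) system <- make_ion_system(n)
  coords <- array(NA_real_, dim = c(n, 3, length(coord_list)))
  for (f in seq_along(coord_list)) coords[, , f] <- coord_list[[f]]
  labeled_trajectory(system, coords, (seq_along(coord_list) - 1) * stride, box)
}

## random proper rotation matrix (QR of a Gaussian matrix, det +1)
random_rotation <- function() {
  q <- qr.Q(qr(matrix(rnorm(9), 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

## --- oracles ---------------------------------------------------------------

## exhaustive pairwise minimum distance
oracle_min_dist <- function(a, b) {
  best <- Inf
  for (i in seq_len(nrow(a))) {
    for (j in seq_len(nrow(b))) {
      best <- min(best, sqrt(sum((a[i, ] - b[j, ])^2)))
    }
  }
  best
}

## dihedral from the atan2-free arccos formulation plus explicit sign
oracle_dihedral <- function(p1, p2, p3, p4) {
  cross <- function(u, v) c(u[2] * v[3] - u[3] * v[2],
                            u[3] * v[1] - u[1] * v[3],
                            u[1] * v[2] - u[2] * v[1])
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- cross(b1, b2); n2 <- cross(b2, b3)
  cosang <- sum(n1 * n2) / sqrt(sum(n1^2) * sum(n2^2))
  ang <- acos(pmin(1, pmax(-1, cosang))) * 180 / pi
  if (sum(cross(n1, n2) * b2) < 0) ang <- -ang
  ang
}

## geometric hydrogen-bond check, one frame, one triple
oracle_hbond <- function(D, H, A, d_cut = 3.5, angle_cut = 30) {
  dDA <- sqrt(sum((D - A)^2))
  v1 <- H - D; v2 <- A - D
  ang <- acos(pmin(1, pmax(-1, sum(v1 * v2) /
                             sqrt(sum(v1^2) * sum(v2^2))))) * 180 / pi
  dDA <= d_cut && ang <= angle_cut
}

## exhaustive hydration count
oracle_hydration <- function(ion, waters, box, cutoff = 3.5) {
  n <- 0
  for (i in seq_len(nrow(waters))) {
    d <- waters[i, ] - ion
    d <- d - box * round(d / box)
    if (sqrt(sum(d^2)) <= cutoff) n <- n + 1
  }
  n
}

## exhaustive per-frame gap scan over an occupancy string: one flag per
## consecutive ion pair, TRUE when at least one W sits strictly between
## the two K symbols (an adjacent K pair is a waterless gap)
oracle_gap_wetness <- function(state) {
  s <- strsplit(state, "")[[1]]
  k <- which(s == "K")
  if (length(k) < 2) return(logical(0))
  out <- logical(length(k) - 1)
  for (j in seq_len(length(k) - 1)) {
    for (pos in seq(k[j], k[j + 1])) {
      if (s[pos] == "W") out[j] <- TRUE
    }
  }
  out
}

## minimum selection RMSD over a dense grid of rotations (no fit), for
## tiny point sets only
oracle_grid_rmsd <- function(mobile, ref, step_deg = 4) {
  grid <- seq(0, 360 - step_deg, by = step_deg) * pi / 180
  half <- seq(0, 180, by = step_deg) * pi / 180
  cm <- colMeans(mobile); cr <- colMeans(ref)
  m0 <- sweep(mobile, 2, cm)
  r0 <- sweep(ref, 2, cr)
  best <- Inf
  for (a in grid) for (b in half) for (c in grid) {
    Rz1 <- matrix(c(cos(a), -sin(a), 0, sin(a), cos(a), 0, 0, 0, 1), 3,
                  byrow = TRUE)
    Ry <- matrix(c(cos(b), 0, sin(b), 0, 1, 0, -sin(b), 0, cos(b)), 3,
                 byrow = TRUE)
    Rz2 <- matrix(c(cos(c), -sin(c), 0, sin(c), cos(c), 0, 0, 0, 1), 3,
                  byrow = TRUE)
    m <- m0 %*% t(Rz2 %*% Ry %*% Rz1)
    best <- min(best, sqrt(mean(rowSums((m - r0)^2))))
  }
  best
}

## minimal PDB text fixture writer (plain ATOM records)
write_mini_pdb <- function(path, resname, chain, resno, atom, xyz,
                           element = substr(trimws(atom), 1, 1)) {
  n <- length(resname)
  lines <- vapply(seq_len(n), function(i) {
    sprintf("ATOM  %5d %-4s %-3s %1s%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
            i, atom[i], resname[i], chain[i], resno[i],
            xyz[i, 1], xyz[i, 2], xyz[i, 3], element[i])
  }, character(1))
  writeLines(c(lines, "END"), path)
  path
}
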