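## Per-frame series are plain data.frames (frame, time_ps, value) so they
## feed straight into CSV output and plotting.
.series <- function(traj, values, name = NULL) {
  out <- data.frame(frame = seq_len(n_frames(traj)) - 1L,
                    time_ps = traj$times, value = values)
  if (!is.null(name)) attr(out, "series_name") <- name
  out
}

.cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

## minimum distance between two point sets (rows = points)
.min_cross_dist <- function(a, b) {
  a2 <- rowSums(a * a)
  b2 <- rowSums(b * b)
  d2 <- outer(a2, b2, `+`) - 2 * tcrossprod(a, b)
  sqrt(max(0, min(d2)))
}

#' Minimum distance between two selections
#'
#' Per frame, the minimum over all inter-selection atom pairs of the
#' Euclidean distance — the quantity used to monitor gate narrowness
#' between opposing subunits of a tetrameric channel.
#'
#' @param traj A [labeled_trajectory()].
#' @param sel_a,sel_b Selections; must be non-empty and not identical
#'   (self-pairing is ambiguous).
#' @return data.frame (frame, time_ps, value) of distances in A.
#' @export
min_distance <- function(traj, sel_a, sel_b) {
  ia <- resolve_selection(traj$system, sel_a)
  ib <- resolve_selection(traj$system, sel_b)
  if (!length(ia) || !length(ib)) stop("empty selection in min_distance")
  if (identical(sort(ia), sort(ib))) {
    stop("sel_a and sel_b select the same atoms; self-pairing is ambiguous")
  }
  vals <- vapply(seq_len(n_frames(traj)), function(f) {
    .min_cross_dist(.fcoords(traj, ia, f), .fcoords(traj, ib, f))
  }, numeric(1))
  .series(traj, vals, "min_distance")
}

#' Minimum distance of the narrower opposing-subunit pair
#'
#' A four-fold channel has two opposing subunit pairs (A,C) and (B,D); the
#' effective gate aperture at a given time is set by whichever pair is
#' narrower, so per frame the smaller of the two pair minimum distances is
#' reported.
#'
#' @param traj A [labeled_trajectory()].
#' @param pair1,pair2 Each a list of two selections (one per subunit of an
#'   opposing pair).
#' @return data.frame (frame, time_ps, value), A.
#' @export
narrower_pair_series <- function(traj, pair1, pair2) {
  d1 <- min_distance(traj, pair1[[1]], pair1[[2]])
  d2 <- min_distance(traj, pair2[[1]], pair2[[2]])
  .series(traj, pmin(d1$value, d2$value), "narrower_pair")
}

#' Distance between opposing Calpha atoms
#'
#' @param traj A [labeled_trajectory()].
#' @param resno Residue number (e.g. 192 for the HBC gate phenylalanine).
#' @param subunits Character vector of the two opposing subunits
#'   (default `c("A", "C")`).
#' @return data.frame (frame, time_ps, value), A.
#' @export
calpha_distance <- function(traj, resno, subunits = c("A", "C")) {
  stopifnot(length(subunits) == 2)
  idx <- lapply(subunits, function(su) {
    i <- resolve_selection(traj$system,
                           sel(subunit = su, resno = resno, atom = "CA"))
    if (length(i) != 1) {
      stop("subunit ", su, " residue ", resno, " has ", length(i),
           " CA atoms (need exactly 1)")
    }
    i
  })
  d2 <- matrix((traj$coords[idx[[1]], , ] - traj$coords[idx[[2]], , ])^2,
               nrow = 3)
  vals <- sqrt(colSums(d2))
  .series(traj, vals, paste0("ca_dist_", resno))
}

#' Histogram of a per-frame series
#'
#' Bins are left-closed, right-open and anchored at 0. Optionally reports
#' the fraction of values strictly above a threshold (e.g. the fraction of
#' simulation time a gate is wider than the mean aperture during
#' permeation).
#'
#' @param series data.frame with a `value` column, or a numeric vector.
#' @param bin_width Bin width (> 0).
#' @param threshold Optional threshold for the above-fraction.
#' @return List with `breaks`, `mids`, `counts`, `n` and (if `threshold`
#'   given) `fraction_above` / `fraction_below`.
#' @export
series_histogram <- function(series, bin_width, threshold = NULL) {
  v <- if (is.data.frame(series)) series$value else series
  v <- v[!is.na(v)]
  if (!length(v)) stop("empty series")
  if (!is.numeric(bin_width) || bin_width <= 0) stop("bin_width must be > 0")
  bin <- floor(v / bin_width)
  rng <- seq(min(bin), max(bin))
  counts <- tabulate(bin - min(bin) + 1L, nbins = length(rng))
  out <- list(breaks = c(rng, max(rng) + 1) * bin_width,
              mids = (rng + 0.5) * bin_width,
              counts = counts, n = length(v))
  if (!is.null(threshold)) {
    out$fraction_above <- mean(v > threshold)
    out$fraction_below <- mean(v <= threshold)
  }
  out
}

#' Per-frame RMSD to the first frame
#'
#' @param traj A [labeled_trajectory()].
#' @param selection Atoms to measure (>= 3).
#' @param fit Superpose each frame's selection onto the reference before
#'   measuring (default `TRUE`, removing rigid-body motion).
#' @return data.frame (frame, time_ps, value), A.
#' @export
backbone_rmsd <- function(traj, selection, fit = TRUE) {
  idx <- resolve_selection(traj$system, selection)
  if (length(idx) < 3) stop("RMSD selection needs at least 3 atoms")
  ref <- traj$coords[idx, , 1, drop = TRUE]
  vals <- vapply(seq_len(n_frames(traj)), function(f) {
    rmsd_pair(traj$coords[idx, , f, drop = TRUE], ref, fit = fit)
  }, numeric(1))
  .series(traj, vals, "rmsd")
}

.dihedral_angle <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1
  b2 <- p3 - p2
  b3 <- p4 - p3
  n1 <- .cross3(b1, b2)
  n2 <- .cross3(b2, b3)
  if (sum(n1 * n1) < 1e-20 || sum(n2 * n2) < 1e-20) return(NA_real_)
  ## IUPAC sign: atan2(b2_hat . (n1 x n2), n1 . n2)
  m1 <- .cross3(b2 / sqrt(sum(b2 * b2)), n1)
  ang <- atan2(sum(m1 * n2), sum(n1 * n2)) * 180 / pi
  ang <- ((ang + 180) %% 360) - 180
  if (ang <= -180) ang <- 180
  if (ang == -180) ang <- 180
  ang
}

#' Per-frame dihedral angle of four atoms
#'
#' Standard signed torsion in (-180, 180] degrees. For a backbone psi
#' angle pass N, CA, C of residue i and N of residue i+1 (see
#' [psi_series()]).
#'
#' @param traj A [labeled_trajectory()].
#' @param sel1,sel2,sel3,sel4 Selections each resolving to exactly one
#'   atom.
#' @return data.frame (frame, time_ps, value), degrees.
#' @export
dihedral_series <- function(traj, sel1, sel2, sel3, sel4) {
  idx <- vapply(list(sel1, sel2, sel3, sel4), function(s) {
    i <- resolve_selection(traj$system, s)
    if (length(i) != 1) stop("dihedral selection must resolve to exactly 1 atom")
    i
  }, integer(1))
  vals <- vapply(seq_len(n_frames(traj)), function(f) {
    .dihedral_angle(traj$coords[idx[1], , f], traj$coords[idx[2], , f],
                    traj$coords[idx[3], , f], traj$coords[idx[4], , f])
  }, numeric(1))
  .series(traj, vals, "dihedral")
}

#' Backbone psi angle series for one residue
#'
#' psi(i) = dihedral(N_i, CA_i, C_i, N_{i+1}).
#'
#' @param traj A [labeled_trajectory()].
#' @param resno Residue number.
#' @param subunit Subunit label.
#' @return data.frame (frame, time_ps, value), degrees.
#' @export
psi_series <- function(traj, resno, subunit) {
  dihedral_series(traj,
                  sel(subunit = subunit, resno = resno, atom = "N"),
                  sel(subunit = subunit, resno = resno, atom = "CA"),
                  sel(subunit = subunit, resno = resno, atom = "C"),
                  sel(subunit = subunit, resno = resno + 1, atom = "N"))
}

.weighted_com <- function(coords, weights = NULL) {
  if (is.null(weights)) return(colMeans(coords))
  colSums(coords * weights) / sum(weights)
}

#' Rotation of the cytoplasmic domain relative to the transmembrane domain
#'
#' Measures the torsion between two planes spanned by four centres of
#' mass: the whole TMD (point 1), the whole CTD (point 2), one subunit's
#' TMD (point 3) and the same subunit's CTD (point 4). Points 1-2-3
#' define the first plane and 1-2-4 the second; the per-frame torsion is
#' referenced to the same quantity in a reference structure (typically
#' the crystal structure, or frame 1). Sign convention: a rotation of the
#' CTD that is counterclockwise when viewed from the extracellular (top,
#' +z) side is negative.
#'
#' @param traj A [labeled_trajectory()].
#' @param tmd_sel,ctd_sel Selections for the whole TMD and CTD.
#' @param tmd_subunit_sel,ctd_subunit_sel Selections for one subunit's
#'   TMD and CTD.
#' @param reference Reference coordinates: an `n_atoms x 3` matrix
#'   matching the system, a 1-frame [labeled_trajectory()], or `NULL` to
#'   use frame 1 of `traj`.
#' @param weights Optional per-particle masses for the centres of mass
#'   (default: unit masses).
#' @return data.frame (frame, time_ps, value) of angles in degrees, in
#'   (-180, 180]; frames with degenerate (collinear) geometry are `NA`.
#' @export
ctd_rotation <- function(traj, tmd_sel, ctd_sel, tmd_subunit_sel,
                         ctd_subunit_sel, reference = NULL, weights = NULL) {
  sels <- list(tmd_sel, ctd_sel, tmd_subunit_sel, ctd_subunit_sel)
  idx <- lapply(sels, function(s) {
    i <- resolve_selection(traj$system, s)
    if (!length(i)) stop("empty selection in ctd_rotation")
    i
  })
  if (is.null(reference)) {
    ref_xyz <- traj$coords[, , 1, drop = TRUE]
  } else if (inherits(reference, "labeled_trajectory")) {
    ref_xyz <- reference$coords[, , 1, drop = TRUE]
  } else {
    ref_xyz <- as.matrix(reference)
  }
  stopifnot(nrow(ref_xyz) == nrow(traj$system))
  torsion_of <- function(xyz) {
    pts <- lapply(idx, function(i) {
      .weighted_com(xyz[i, , drop = FALSE],
                    if (is.null(weights)) NULL else weights[i])
    })
    ## torsion of plane(1,2,3) vs plane(1,2,4) about the 1-2 axis is the
    ## dihedral of the point sequence 3-1-2-4
    .dihedral_angle(pts[[3]], pts[[1]], pts[[2]], pts[[4]])
  }
  ref_t <- torsion_of(ref_xyz)
  vals <- vapply(seq_len(n_frames(traj)), function(f) {
    t_f <- torsion_of(traj$coords[, , f, drop = TRUE])
    if (is.na(t_f) || is.na(ref_t)) return(NA_real_)
    ## the torsion difference is negative for a counterclockwise CTD
    ## rotation viewed from +z, matching the reported sign convention
    d <- ((t_f - ref_t + 180) %% 360) - 180
    if (d == -180) d <- 180
    d
  }, numeric(1))
  if (anyNA(vals)) {
    warning(sum(is.na(vals)), " frame(s) with degenerate (collinear) ",
            "rotation geometry; returned NA")
  }
  .series(traj, vals, "ctd_rotation")
}

#' Cation-pi geometry between an aromatic ring and an ion
#'
#' Per frame: the distance from the ring centroid to the ion and the
#' angle between the best-fit ring plane normal (least-squares, via SVD)
#' and the centroid-to-ion vector, folded to \[0, 90\] degrees. 0 degrees
#' means the ion sits on the ring axis (the favourable cation-pi
#' arrangement); 90 degrees means it lies in the ring plane.
#'
#' @param traj A [labeled_trajectory()].
#' @param ring_sel Selection of the ring atoms (6 for a phenyl ring; at
#'   least 3 required).
#' @param ion_id Particle id of the ion.
#' @return data.frame (frame, time_ps, distance, angle).
#' @export
cation_pi_geometry <- function(traj, ring_sel, ion_id) {
  ring <- resolve_selection(traj$system, ring_sel)
  if (length(ring) < 3) stop("ring selection needs at least 3 atoms")
  ion <- resolve_selection(traj$system, as.integer(ion_id))
  n_fr <- n_frames(traj)
  dist <- ang <- numeric(n_fr)
  for (f in seq_len(n_fr)) {
    rc <- .fcoords(traj, ring, f)
    centroid <- colMeans(rc)
    s <- svd(sweep(rc, 2, centroid))
    normal <- s$v[, 3]
    u <- traj$coords[ion, , f] - centroid
    dist[f] <- sqrt(sum(u * u))
    cosang <- abs(sum(normal * u)) / max(dist[f], 1e-12)
    ang[f] <- acos(pmin(1, cosang)) * 180 / pi
  }
  data.frame(frame = seq_len(n_fr) - 1L, time_ps = traj$times,
             distance = dist, angle = ang)
}
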