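## map each donor heavy atom to its covalently attached hydrogens
## (distance criterion on frame 1; 1.25 A covers O-H and N-H bonds)
.attach_hydrogens <- function(traj, didx, hidx, bond_cut = 1.25) {
  if (!length(hidx)) return(rep(list(integer()), length(didx)))
  xyz <- traj$coords[, , 1, drop = TRUE]
  lapply(didx, function(d) {
    dd <- sweep(xyz[hidx, , drop = FALSE], 2, xyz[d, ])
    h <- hidx[sqrt(rowSums(dd * dd)) <= bond_cut]
    h[h != d] # a hydrogen never donates through itself
  })
}

.angle_deg <- function(v1, v2) {
  cosang <- sum(v1 * v2) / sqrt(sum(v1 * v1) * sum(v2 * v2))
  acos(pmin(1, pmax(-1, cosang))) * 180 / pi
}

## presence matrix (donors x acceptors) for one frame
.hb_frame <- function(xyz, didx, aidx, hlist, d_cut, angle_cut, mode) {
  dpos <- xyz[didx, , drop = FALSE]
  apos <- xyz[aidx, , drop = FALSE]
  d2 <- outer(rowSums(dpos^2), rowSums(apos^2), `+`) - 2 * tcrossprod(dpos, apos)
  ok <- d2 <= d_cut^2
  implicit <- is.null(hlist)
  if (implicit) return(ok)
  for (i in seq_along(didx)) {
    for (j in seq_along(aidx)) {
      if (!ok[i, j]) next
      if (didx[i] == aidx[j]) { ok[i, j] <- FALSE; next }
      hs <- hlist[[i]]
      if (!length(hs)) { ok[i, j] <- FALSE; next }
      pass <- FALSE
      for (h in hs) {
        ang <- if (mode == "HDA") {
          ## angle at the donor between D->H and D->A
          .angle_deg(xyz[h, ] - dpos[i, ], apos[j, ] - dpos[i, ])
        } else {
          ## deviation from D-H...A linearity (angle at the hydrogen)
          180 - .angle_deg(dpos[i, ] - xyz[h, ], apos[j, ] - xyz[h, ])
        }
        if (ang <= angle_cut) { pass <- TRUE; break }
      }
      ok[i, j] <- pass
    }
  }
  ok
}

#' Detect hydrogen bonds
#'
#' A bond is present in a frame when the donor-acceptor distance is at
#' most `d_cut` (3.5 A default) and the hydrogen-donor-acceptor angle is
#' at most `angle_cut` (30 degrees default) for some hydrogen covalently
#' attached to the donor. When the system carries no hydrogens (e.g.
#' heavy-atom-only synthetic data, or salt-bridge analysis on N/O atoms),
#' detection falls back to the distance criterion alone and the result is
#' flagged `implicit_hydrogen`.
#'
#' @param traj A [labeled_trajectory()].
#' @param donors,acceptors Selections of donor and acceptor heavy atoms.
#' @param d_cut Donor-acceptor distance cutoff (A).
#' @param angle_cut Angle cutoff (degrees).
#' @param angle_mode `"HDA"`: angle at the donor between the D-H and D-A
#'   vectors (the convention of the common trajectory tools);
#'   `"DHA_linearity"`: deviation of the D-H...A angle from 180 degrees.
#' @param hydrogens Selection of hydrogen atoms; default: particles whose
#'   atom name starts with H or whose role is `water_hydrogen`. Set
#'   `NULL` explicitly after checking to force implicit mode.
#' @return data.frame of class `hbond_records`: donor_id, acceptor_id,
#'   hydrogen_id (first attached, `NA` in implicit mode), occupancy
#'   (fraction of frames present); attribute `present` holds the frames x
#'   pairs logical matrix and `implicit_hydrogen` the mode flag. Only
#'   pairs present in at least one frame are returned.
#' @export
detect_hbonds <- function(traj, donors, acceptors, d_cut = 3.5,
                          angle_cut = 30,
                          angle_mode = c("HDA", "DHA_linearity"),
                          hydrogens = .default_hydrogens(traj)) {
  angle_mode <- match.arg(angle_mode)
  didx <- resolve_selection(traj$system, donors)
  aidx <- resolve_selection(traj$system, acceptors)
  if (!length(didx) || !length(aidx)) stop("empty donor/acceptor selection")
  hidx <- if (is.null(hydrogens)) integer() else
    resolve_selection(traj$system, hydrogens)
  hlist <- if (length(hidx)) .attach_hydrogens(traj, didx, hidx) else NULL
  implicit <- is.null(hlist)
  n_fr <- n_frames(traj)
  pres <- array(FALSE, dim = c(length(didx), length(aidx), n_fr))
  for (f in seq_len(n_fr)) {
    pres[, , f] <- .hb_frame(traj$coords[, , f, drop = TRUE], didx, aidx,
                             hlist, d_cut, angle_cut, angle_mode)
  }
  occ <- apply(pres, c(1, 2), mean)
  hit <- which(occ > 0, arr.ind = TRUE)
  hcol <- if (implicit) rep(NA_integer_, nrow(hit)) else
    vapply(hit[, 1], function(i) {
      if (length(hlist[[i]])) traj$system$id[hlist[[i]][1]] else NA_integer_
    }, integer(1))
  out <- data.frame(
    donor_id = traj$system$id[didx[hit[, 1]]],
    acceptor_id = traj$system$id[aidx[hit[, 2]]],
    hydrogen_id = hcol,
    occupancy = occ[hit]
  )
  out <- out[out$donor_id != out$acceptor_id, , drop = FALSE]
  rownames(out) <- NULL
  pm <- matrix(aperm(pres, c(3, 1, 2)), nrow = n_fr)
  attr(out, "present") <- pm
  attr(out, "implicit_hydrogen") <- implicit
  if (implicit) {
    message("no hydrogens available: implicit-hydrogen mode ",
            "(distance criterion only)")
  }
  class(out) <- c("hbond_records", "data.frame")
  out
}

.default_hydrogens <- function(traj) {
  has_h <- traj$system$role == "water_hydrogen" |
    grepl("^H", traj$system$atom) |
    (!is.na(traj$system$element) & traj$system$element == "H")
  if (!any(has_h)) return(NULL)
  traj$system$id[has_h]
}

#' Residue-pair hydrogen-bond occupancy table
#'
#' For each labelled residue pair, per-frame bond presence is the maximum
#' over all donor-acceptor atom pairs, and the reported occupancy is the
#' fraction of frames with at least one bond. Salt bridges are handled by
#' the same machinery via implicit-hydrogen (heavy-atom distance) mode.
#'
#' @param traj A [labeled_trajectory()].
#' @param pairs Named list; each element a list with elements `donor` and
#'   `acceptor` (selections).
#' @param ... Passed to [detect_hbonds()] (cutoffs, angle mode,
#'   hydrogens).
#' @return data.frame (pair, occupancy, n_atom_pairs).
#' @export
pairwise_occupancy_table <- function(traj, pairs, ...) {
  stopifnot(length(pairs) > 0)
  if (is.null(names(pairs))) names(pairs) <- paste0("pair", seq_along(pairs))
  rows <- lapply(names(pairs), function(nm) {
    p <- pairs[[nm]]
    didx <- resolve_selection(traj$system, p$donor)
    if (!length(didx)) stop("unresolved donor selection in pair '", nm, "'")
    aidx <- resolve_selection(traj$system, p$acceptor)
    if (!length(aidx)) stop("unresolved acceptor selection in pair '", nm, "'")
    hb <- suppressMessages(detect_hbonds(traj, p$donor, p$acceptor, ...))
    pm <- attr(hb, "present")
    per_frame <- if (ncol(pm)) apply(pm, 1, any) else
      rep(FALSE, n_frames(traj))
    data.frame(pair = nm, occupancy = mean(per_frame),
               n_atom_pairs = length(didx) * length(aidx))
  })
  do.call(rbind, rows)
}
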