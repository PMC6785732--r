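## Kabsch least-squares rotation: returns the proper rotation R and
## translation mapping `mobile` onto `ref` (rows = atoms). Reflections are
## forbidden by the determinant sign correction.
.kabsch <- function(mobile, ref) {
  cm <- colMeans(mobile)
  cr <- colMeans(ref)
  H <- crossprod(sweep(mobile, 2, cm), sweep(ref, 2, cr))
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  D <- diag(c(1, 1, d))
  R <- s$v %*% D %*% t(s$u)
  list(R = R, center_mobile = cm, center_ref = cr)
}

.apply_fit <- function(coords, fit) {
  sweep(sweep(coords, 2, fit$center_mobile) %*% t(fit$R), 2, fit$center_ref, `+`)
}

#' Superpose a trajectory onto its first frame
#'
#' Each frame is rigidly transformed (least-squares rotation plus
#' translation, reflections forbidden) so that the RMSD of the reference
#' selection to frame 1 is minimal; the transform is applied to all
#' particles. This is the standard pre-processing step before any
#' pore-axis analysis: channel trajectories are aligned on the
#' selectivity-filter backbone so that the pore frame of reference is
#' fixed.
#'
#' @param traj A [labeled_trajectory()].
#' @param reference_selection Selection defining the fit atoms (e.g. the
#'   SF backbone); must resolve to at least 3 particles.
#' @return The superposed [labeled_trajectory()].
#' @export
superpose <- function(traj, reference_selection) {
  idx <- resolve_selection(traj$system, reference_selection)
  if (length(idx) < 3) {
    stop("superposition needs at least 3 selected particles (got ",
         length(idx), ")")
  }
  ref <- traj$coords[idx, , 1, drop = TRUE]
  out <- traj$coords
  for (f in seq_len(n_frames(traj))) {
    fit <- .kabsch(traj$coords[idx, , f, drop = TRUE], ref)
    out[, , f] <- .apply_fit(traj$coords[, , f, drop = TRUE], fit)
  }
  traj$coords <- out
  traj
}

#' RMSD between two coordinate sets
#'
#' @param a,b `n x 3` coordinate matrices.
#' @param fit If `TRUE` (default), optimally superpose `a` onto `b` first.
#' @return RMSD in A.
#' @export
rmsd_pair <- function(a, b, fit = TRUE) {
  stopifnot(nrow(a) == nrow(b))
  if (fit) {
    k <- .kabsch(a, b)
    a <- .apply_fit(a, k)
  }
  sqrt(mean(rowSums((a - b)^2)))
}
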