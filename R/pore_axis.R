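#' Pore axis model
#'
#' Places the landmarks of a Kir-type channel pore along the z axis: the
#' intracellular entrance of the cytoplasmic domain, the G-loop gate, the
#' helix-bundle-crossing (HBC) gate, and the six boundaries delimiting
#' the five selectivity-filter ion-binding sites S4 (intracellular) to S0
#' (extracellular). All values in Angstrom. By convention the permeation
#' (outward) direction is +z; `axis_direction = "-z"` flips all landmark
#' comparisons instead of transforming coordinates.
#'
#' @param z_entrance z of the intracellular entrance.
#' @param z_gloop z of the G-loop gate (G318/M319 level).
#' @param z_hbc z of the HBC gate (F192 level).
#' @param z_sites 6 increasing z values delimiting sites S4..S0.
#' @param pore_radius Radial cutoff (A) defining "inside the pore" for
#'   water/ion counting (default 8).
#' @param sf_radius Radial cutoff (A) for selectivity-filter site
#'   assignment (default 4).
#' @param axis_direction `"+z"` or `"-z"`.
#' @return An object of class `pore_axis_model`.
#' @export
pore_axis_model <- function(z_entrance, z_gloop, z_hbc, z_sites,
                            pore_radius = 8, sf_radius = 4,
                            axis_direction = c("+z", "-z")) {
  axis_direction <- match.arg(axis_direction)
  stopifnot(length(z_sites) == 6)
  s <- if (axis_direction == "+z") 1 else -1
  ord <- s * c(z_entrance, z_gloop, z_hbc, z_sites)
  if (any(diff(ord) <= 0)) {
    stop("pore landmarks must be strictly ordered along the permeation direction")
  }
  structure(list(z_entrance = z_entrance, z_gloop = z_gloop, z_hbc = z_hbc,
                 z_sites = as.numeric(z_sites), pore_radius = pore_radius,
                 sf_radius = sf_radius, axis_direction = axis_direction),
            class = "pore_axis_model")
}

#' @export
print.pore_axis_model <- function(x, ...) {
  cat("pore_axis_model (", x$axis_direction, "): entrance ", x$z_entrance,
      " | G-loop ", x$z_gloop, " | HBC ", x$z_hbc, " | SF ",
      paste(x$z_sites, collapse = "/"), " A; pore radius ", x$pore_radius,
      " A\n", sep = "")
  invisible(x)
}

## Project landmarks onto the permeation direction (+z convention
## internally; "-z" models are mirrored).
.axis_z <- function(pore, z) if (pore$axis_direction == "+z") z else -z

.pore_landmarks <- function(pore) {
  s <- if (pore$axis_direction == "+z") 1 else -1
  list(z_entrance = s * pore$z_entrance, z_gloop = s * pore$z_gloop,
       z_hbc = s * pore$z_hbc, z_sites = sort(s * pore$z_sites))
}

#' Instantaneous pore axis position
#'
#' Returns the per-frame x-y centre of the pore, taken as the centroid of
#' the selectivity-filter selection when one is given (so lateral drift
#' of the channel is tracked), falling back to the box centre.
#'
#' @param traj A [labeled_trajectory()].
#' @param sf_selection Selection for the SF atoms, or `NULL`.
#' @return `n_frames x 2` matrix of (x, y).
#' @export
pore_axis_xy <- function(traj, sf_selection = NULL) {
  n_fr <- n_frames(traj)
  if (is.null(sf_selection)) {
    return(traj$box[, 1:2, drop = FALSE] / 2)
  }
  idx <- resolve_selection(traj$system, sf_selection)
  if (!length(idx)) stop("empty SF selection for pore axis")
  t(vapply(seq_len(n_fr), function(f) {
    colMeans(.fcoords(traj, idx, f)[, 1:2, drop = FALSE])
  }, numeric(2)))
}
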