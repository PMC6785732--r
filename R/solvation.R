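## radial (xy) distance of particles to the pore axis, one frame
.radial_dist <- function(xyz, axis_xy) {
  sqrt((xyz[, 1] - axis_xy[1])^2 + (xyz[, 2] - axis_xy[2])^2)
}

.default_axis <- function(traj, axis_xy) {
  if (is.null(axis_xy)) traj$box[, 1:2, drop = FALSE] / 2 else axis_xy
}

#' Water (or ion) occupancy map along the pore axis
#'
#' Counts particles of the requested role inside the pore cylinder
#' (radial distance from the pore axis no greater than `pore_radius`),
#' binned by z, for every frame, and reports the per-bin time average
#' normalised per 1 A. This is the standard picture of pore wetting: gaps
#' in the map are dewetted stretches (hydrophobic gates), and the average
#' profile shows how many waters populate each pore level.
#'
#' @param traj A [labeled_trajectory()].
#' @param pore A [pore_axis_model()]; `pore_radius` supplies the radial
#'   cutoff.
#' @param z_range Two z values (A) delimiting the map (default:
#'   intracellular entrance to the extracellular end of the SF).
#' @param bin_width Bin width in A (default 1 for water maps).
#' @param role Particle role to count (default `"water_oxygen"`).
#' @param axis_xy Pore axis as an `n_frames x 2` matrix (e.g. from
#'   [pore_axis_xy()]); default: box centre.
#' @return List with `breaks`, `mids`, per-frame `counts` matrix
#'   (frames x bins) and `average` (per-bin time-mean count per 1 A).
#' @export
water_occupancy_map <- function(traj, pore, z_range = NULL, bin_width = 1,
                                role = "water_oxygen", axis_xy = NULL) {
  if (bin_width <= 0) stop("bin_width must be > 0")
  lm <- .pore_landmarks(pore)
  if (is.null(z_range)) {
    z_range <- c(lm$z_entrance, max(lm$z_sites))
  } else {
    z_range <- sort(.axis_z(pore, z_range))
  }
  axis_xy <- .default_axis(traj, axis_xy)
  idx <- which(traj$system$role == role)
  breaks <- seq(z_range[1], z_range[2] + bin_width * 0.999, by = bin_width)
  n_bins <- length(breaks) - 1
  n_fr <- n_frames(traj)
  counts <- matrix(0L, n_fr, n_bins)
  for (f in seq_len(n_fr)) {
    if (!length(idx)) next
    xyz <- .fcoords(traj, idx, f)
    r <- .radial_dist(xyz, axis_xy[f, ])
    zz <- .axis_z(pore, xyz[, 3])
    inside <- r <= pore$pore_radius & zz >= breaks[1] & zz < breaks[n_bins + 1]
    if (any(inside)) {
      b <- floor((zz[inside] - breaks[1]) / bin_width) + 1L
      counts[f, ] <- tabulate(b, nbins = n_bins)
    }
  }
  list(breaks = breaks, mids = breaks[-length(breaks)] + bin_width / 2,
       counts = counts, average = colMeans(counts) / bin_width,
       bin_width = bin_width, role = role)
}

#' Per-frame water count in a pore slice
#'
#' Counts water oxygens inside the cylinder slice `z_low <= z <= z_high`,
#' radius `pore_radius`, per frame — the quantity used to follow wetting
#' and dewetting of the inner cavity over time.
#'
#' @param traj A [labeled_trajectory()].
#' @param z_low,z_high Slice boundaries (A), `z_low < z_high`.
#' @param pore_radius Radial cutoff (A).
#' @param axis_xy Optional pore axis (`n_frames x 2`); default box centre.
#' @return data.frame (frame, time_ps, value) of integer counts.
#' @export
cavity_water_count <- function(traj, z_low, z_high, pore_radius,
                               axis_xy = NULL) {
  if (z_low >= z_high) stop("z_low must be < z_high")
  axis_xy <- .default_axis(traj, axis_xy)
  idx <- which(traj$system$role == "water_oxygen")
  vals <- vapply(seq_len(n_frames(traj)), function(f) {
    if (!length(idx)) return(0L)
    xyz <- .fcoords(traj, idx, f)
    r <- .radial_dist(xyz, axis_xy[f, ])
    sum(r <= pore_radius & xyz[, 3] >= z_low & xyz[, 3] <= z_high)
  }, integer(1))
  .series(traj, vals, "cavity_waters")
}

#' Hydration number of an ion
#'
#' Number of water oxygens within `cutoff` of the ion per frame
#' (minimum-image in all three dimensions; the boundary is closed, so a
#' water at exactly the cutoff counts). The 3.5 A default is the first
#' hydration shell of K+.
#'
#' @param traj A [labeled_trajectory()].
#' @param ion_id Particle id of the ion.
#' @param cutoff Shell radius in A.
#' @return data.frame (frame, time_ps, value) of integer counts.
#' @export
hydration_number <- function(traj, ion_id, cutoff = 3.5) {
  ion <- resolve_selection(traj$system, as.integer(ion_id))
  if (traj$system$role[ion] != "ion") {
    stop("particle ", ion_id, " is not an ion")
  }
  wat <- which(traj$system$role == "water_oxygen")
  vals <- vapply(seq_len(n_frames(traj)), function(f) {
    if (!length(wat)) return(0L)
    d <- sweep(.fcoords(traj, wat, f), 2, traj$coords[ion, , f])
    for (k in 1:3) {
      L <- traj$box[f, k]
      d[, k] <- d[, k] - L * round(d[, k] / L)
    }
    sum(sqrt(rowSums(d * d)) <= cutoff)
  }, integer(1))
  .series(traj, vals, "hydration")
}

#' G-loop gate snapshots during ion passage
#'
#' Extracts every (frame, ion) combination in which an ion sits inside a
#' cylinder (default radius 4 A, height 4 A) centred on the centre of
#' mass of the G-loop gate-forming residues, and records for each
#' snapshot the narrower-opposing-pair minimum gate distance and the
#' ion's hydration number. The summary means characterise how narrow and
#' how hydrated the gate is while ions actually pass it.
#'
#' @param traj A [labeled_trajectory()].
#' @param gloop_sel Selection of the gate-forming residues of all four
#'   subunits (typically G318 + M319).
#' @param pair1,pair2 Opposing-subunit selection pairs for the narrowness
#'   measure (typically residues 316-320 of subunits A/C and B/D).
#' @param ion_ids Ions to consider (default: all ions in the system).
#' @param radius,height Cylinder dimensions in A.
#' @param hydration_cutoff Shell radius (A) for the water count.
#' @return List with `snapshots` (data.frame: frame, time_ps, ion_id,
#'   distance, hydration) and `summary` (mean_distance, mean_hydration,
#'   n_snapshots). An empty snapshot set yields `NA` means and a warning.
#' @export
gloop_pass_snapshots <- function(traj, gloop_sel, pair1, pair2,
                                 ion_ids = NULL, radius = 4, height = 4,
                                 hydration_cutoff = 3.5) {
  gidx <- resolve_selection(traj$system, gloop_sel)
  if (!length(gidx)) stop("empty G-loop selection")
  if (is.null(ion_ids)) ion_ids <- traj$system$id[traj$system$role == "ion"]
  if (!length(ion_ids)) stop("no ions in system")
  narrow <- narrower_pair_series(traj, pair1, pair2)
  n_fr <- n_frames(traj)
  rows <- vector("list", length(ion_ids))
  for (j in seq_along(ion_ids)) {
    ion <- resolve_selection(traj$system, as.integer(ion_ids[j]))
    hyd <- hydration_number(traj, ion_ids[j], cutoff = hydration_cutoff)
    inside <- logical(n_fr)
    for (f in seq_len(n_fr)) {
      com <- colMeans(.fcoords(traj, gidx, f))
      p <- traj$coords[ion, , f]
      inside[f] <- sqrt(sum((p[1:2] - com[1:2])^2)) <= radius &&
        abs(p[3] - com[3]) <= height / 2
    }
    if (any(inside)) {
      rows[[j]] <- data.frame(frame = which(inside) - 1L,
                              time_ps = traj$times[inside],
                              ion_id = ion_ids[j],
                              distance = narrow$value[inside],
                              hydration = hyd$value[inside])
    }
  }
  snapshots <- do.call(rbind, rows)
  if (is.null(snapshots) || nrow(snapshots) == 0) {
    warning("no G-loop pass snapshots found; summary undefined")
    snapshots <- data.frame(frame = integer(), time_ps = numeric(),
                            ion_id = integer(), distance = numeric(),
                            hydration = numeric())
    summary <- data.frame(mean_distance = NA_real_,
                          mean_hydration = NA_real_, n_snapshots = 0L)
  } else {
    snapshots <- snapshots[order(snapshots$frame, snapshots$ion_id), ]
    summary <- data.frame(mean_distance = mean(snapshots$distance),
                          mean_hydration = mean(snapshots$hydration),
                          n_snapshots = nrow(snapshots))
  }
  list(snapshots = snapshots, summary = summary)
}

#' Classify pore wetting state
#'
#' A region is `wet` in a frame when its water count reaches the
#' threshold, `dry` otherwise.
#'
#' @param counts data.frame from [cavity_water_count()] or a numeric
#'   vector of per-frame counts.
#' @param threshold Minimum count for the wet state (>= 1).
#' @return List with `state` (character vector per frame) and
#'   `wet_fraction`.
#' @export
wetting_state <- function(counts, threshold) {
  if (threshold < 1) stop("threshold must be >= 1")
  v <- if (is.data.frame(counts)) counts$value else counts
  state <- ifelse(v >= threshold, "wet", "dry")
  list(state = state, wet_fraction = mean(state == "wet"))
}
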