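## Frame-exact scripted scenarios: hand-constructed coordinate sequences
## with exactly known analysis outcomes (no noise), used to validate the
## detectors deterministically.

.scenario_base <- function(pore = default_pore_model(), box = c(80, 80, 145),
                           n_ions = 0, n_waters = 0, n_frames = 10,
                           stride = 20, scaffold = TRUE) {
  sc <- if (scaffold) .build_scaffold(pore, box)
  n_prot <- if (is.null(sc)) 0L else nrow(sc)
  sys_df <- data.frame(
    id = seq_len(n_prot + n_ions + n_waters),
    role = c(rep("protein", n_prot), rep("ion", n_ions),
             rep("water_oxygen", n_waters)),
    subunit = c(if (n_prot) sc$subunit, rep(NA, n_ions + n_waters)),
    resno = c(if (n_prot) sc$resno, seq_len(n_ions + n_waters) + 1000L),
    resname = c(if (n_prot) sc$resname, rep("K", n_ions),
                rep("HOH", n_waters)),
    atom = c(if (n_prot) sc$atom, rep("K", n_ions), rep("OW", n_waters)),
    element = c(if (n_prot) substr(sc$atom, 1, 1), rep("K", n_ions),
                rep("O", n_waters)))
  system <- pore_system(sys_df)
  coords <- array(0, dim = c(nrow(sys_df), 3, n_frames))
  coords[, 1, ] <- box[1] / 2
  coords[, 2, ] <- box[2] / 2
  if (n_prot) {
    coords[seq_len(n_prot), 1, ] <- sc$x
    coords[seq_len(n_prot), 2, ] <- sc$y
    coords[seq_len(n_prot), 3, ] <- sc$z
  }
  list(system = system, coords = coords, n_prot = n_prot, pore = pore,
       box = box, times = (seq_len(n_frames) - 1) * stride)
}

.finish_scenario <- function(base, truth) {
  list(trajectory = labeled_trajectory(base$system, base$coords, base$times,
                                       base$box),
       ground_truth = c(truth, list(pore = base$pore)))
}

#' Scripted analysis scenarios with exact outcomes
#'
#' Deterministic, noise-free coordinate constructions:
#' \describe{
#'   \item{single_crossing}{One ion moves linearly from the intracellular
#'     bulk to above the selectivity filter: exactly one committed
#'     permeation event at every level (G-loop, HBC, full SF).}
#'   \item{flicker_no_crossing}{One ion oscillates across the G-loop
#'     plane (default 20 recrossings) with an amplitude smaller than the
#'     committed margin: zero events.}
#'   \item{knockon_chain}{A single-file chain of ions (default 3), one
#'     site apart, advances through the filter with no interleaved
#'     waters: every event classifies as direct knock-on.}
#'   \item{soft_knockon_chain}{Alternating ion-water single file: every
#'     ion-ion gap holds a water, every event classifies as
#'     water-mediated with co-permeating waters.}
#'   \item{hbond_pair}{A static donor/hydrogen/acceptor triple at a set
#'     distance and hydrogen-donor-acceptor angle (optionally broken for
#'     a fraction of frames).}
#'   \item{rotated_ctd}{The CTD bead cloud rotated by a set angle about
#'     the pore axis relative to frame 1; the rotation analysis must
#'     recover the angle to 0.01 degrees.}
#' }
#'
#' @param name Scenario name.
#' @param params Named list of scenario parameters (see Details above;
#'   all have defaults).
#' @return List with `trajectory` and `ground_truth`.
#' @export
script_scenario <- function(name = c("single_crossing", "flicker_no_crossing",
                                     "knockon_chain", "soft_knockon_chain",
                                     "hbond_pair", "rotated_ctd"),
                            params = list()) {
  if (!is.character(name) || length(name) != 1 ||
      !name %in% c("single_crossing", "flicker_no_crossing", "knockon_chain",
                   "soft_knockon_chain", "hbond_pair", "rotated_ctd")) {
    stop("unknown scenario '", paste(name, collapse = "/"), "'")
  }
  switch(name,
         single_crossing = .scn_single_crossing(params),
         flicker_no_crossing = .scn_flicker(params),
         knockon_chain = .scn_knockon(params, soft = FALSE),
         soft_knockon_chain = .scn_knockon(params, soft = TRUE),
         hbond_pair = .scn_hbond(params),
         rotated_ctd = .scn_rotated_ctd(params))
}

.scn_single_crossing <- function(params) {
  n_frames <- params$n_frames %||% 101
  pore <- params$pore %||% default_pore_model()
  z0 <- pore$z_entrance - 10
  z1 <- pore$z_sites[6] + 6
  base <- .scenario_base(pore, n_ions = 1, n_frames = n_frames)
  base$coords[base$n_prot + 1, 3, ] <- seq(z0, z1, length.out = n_frames)
  .finish_scenario(base, list(expected_events = 1L,
                              expected_events_hbc = 1L,
                              expected_events_gloop = 1L))
}

.scn_flicker <- function(params) {
  n_recross <- params$n_recross %||% 20
  amplitude <- params$amplitude %||% 1.5
  pore <- params$pore %||% default_pore_model()
  g <- pore$z_gloop
  ## approach from committed-below, oscillate across the plane, retreat
  z <- c(g - 4, g - amplitude,
         rep(c(g + amplitude, g - amplitude), n_recross / 2),
         g - 4)
  base <- .scenario_base(pore, n_ions = 1, n_frames = length(z))
  base$coords[base$n_prot + 1, 3, ] <- z
  .finish_scenario(base, list(expected_events = 0L,
                              n_plane_crossings = n_recross))
}

.scn_knockon <- function(params, soft) {
  n_ions <- params$n_ions %||% if (soft) 2 else 3
  pore <- params$pore %||% default_pore_model()
  if (n_ions > 5) stop("scripted chain of ", n_ions,
                       " ions exceeds the filter site capacity (5)")
  site_h <- diff(pore$z_sites)[1]
  spacing <- if (soft) 2 * site_h else site_h
  step <- site_h / 2
  z_top <- pore$z_sites[6] + 4
  z_start <- pore$z_sites[1] - 4
  n_waters <- if (soft) n_ions else 0
  total <- (z_top - (z_start - (n_ions - 1) * spacing - if (soft) site_h else 0))
  n_frames <- ceiling(total / step) + 3
  base <- .scenario_base(pore, n_ions = n_ions, n_waters = n_waters,
                         n_frames = n_frames)
  adv <- (seq_len(n_frames) - 1) * step
  for (i in seq_len(n_ions)) {
    z0 <- z_start - (i - 1) * spacing
    base$coords[base$n_prot + i, 3, ] <- pmin(z0 + adv, z_top + (n_ions - i))
  }
  if (soft) {
    for (i in seq_len(n_waters)) {
      z0 <- z_start - (i - 1) * spacing - site_h # between ions i and i+1
      base$coords[base$n_prot + n_ions + i, 3, ] <-
        pmin(z0 + adv, z_top + n_ions + 0.5 * i)
    }
  }
  .finish_scenario(base, list(
    expected_events = n_ions,
    expected_class = if (soft) "water_mediated" else "direct_knock_on",
    expected_waters_per_event = if (soft) 1L else 0L))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.scn_hbond <- function(params) {
  d <- params$d %||% 2.9
  angle <- params$angle %||% 0
  n_frames <- params$n_frames %||% 10
  broken_fraction <- params$broken_fraction %||% 0
  box <- c(80, 80, 145)
  sys <- pore_system(data.frame(
    id = 1:3,
    role = "protein",
    subunit = c("A", "A", "B"),
    resno = c(10L, 10L, 20L),
    resname = c("SER", "SER", "GLU"),
    atom = c("OG", "HG", "OE1"),
    element = c("O", "H", "O")))
  coords <- array(0, dim = c(3, 3, n_frames))
  D <- c(40, 40, 70)
  th <- angle * pi / 180
  for (f in seq_len(n_frames)) {
    coords[1, , f] <- D
    coords[2, , f] <- D + c(cos(th), sin(th), 0) # H at 1 A from donor
    coords[3, , f] <- D + c(d, 0, 0)             # acceptor on the D-A axis
  }
  n_broken <- round(broken_fraction * n_frames)
  if (n_broken > 0) {
    for (f in seq_len(n_broken)) coords[3, 1, f] <- D[1] + 6
  }
  traj <- labeled_trajectory(sys, coords, (seq_len(n_frames) - 1) * 20, box)
  list(trajectory = traj,
       ground_truth = list(donor_id = 1L, hydrogen_id = 2L, acceptor_id = 3L,
                           expected_occupancy = 1 - n_broken / n_frames,
                           distance = d, hda_angle = angle))
}

.scn_rotated_ctd <- function(params) {
  angle <- params$angle %||% 5
  n_frames <- params$n_frames %||% 2
  pore <- params$pore %||% default_pore_model()
  base <- .scenario_base(pore, n_frames = n_frames)
  ctd <- which(base$system$resno %in% 241:245)
  cx <- base$box[1] / 2
  cy <- base$box[2] / 2
  ## the analysis reports counterclockwise-from-top as negative, so to
  ## make it return +angle the beads are rotated clockwise by `angle`
  ## when viewed from the extracellular (+z) side
  phi <- -angle * pi / 180
  R <- matrix(c(cos(phi), -sin(phi), sin(phi), cos(phi)), 2, 2, byrow = TRUE)
  for (f in 2:n_frames) {
    xy <- cbind(base$coords[ctd, 1, f] - cx, base$coords[ctd, 2, f] - cy)
    xy <- xy %*% t(R)
    base$coords[ctd, 1, f] <- xy[, 1] + cx
    base$coords[ctd, 2, f] <- xy[, 2] + cy
  }
  .finish_scenario(base, list(expected_angle = angle))
}
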