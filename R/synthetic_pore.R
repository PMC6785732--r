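## ---------------------------------------------------------------------------
## Synthetic pore generator: labeled trajectories with known ground truth.
## Two dynamic modes:
##   "diffusion" - overdamped Euler-Maruyama ions on a piecewise-linear
##                 potential U(z) with an optional uniform field; known
##                 stationary distribution exp(-(U + U_field)/kT).
##   "rate"      - ions perform scheduled pore transits at Poisson times
##                 (optionally through a single-file knock-on chain in the
##                 selectivity filter); the planted event list is exact.
## ---------------------------------------------------------------------------

#' Default pore geometry of the synthetic channel
#'
#' A four-fold pseudo-channel aligned with +z in a 80 x 80 x 145 A box
#' (the 14.5-nm box height typical of a solvated Kir channel system):
#' intracellular entrance at z = 30, G-loop gate at 52, HBC gate at 72,
#' and five 3-A selectivity-filter sites spanning z = 85..100.
#'
#' @return A [pore_axis_model()].
#' @export
default_pore_model <- function() {
  pore_axis_model(z_entrance = 30, z_gloop = 52, z_hbc = 72,
                  z_sites = seq(85, 100, by = 3), pore_radius = 8,
                  sf_radius = 4)
}

#' Synthetic pore configuration
#'
#' Full parameterization of the toy channel. Water density is described
#' by z regions with relative densities; zero-density regions (the
#' selectivity filter by default) stay dry, which is how dewetted gate
#' stretches are emulated. Gate flicker is a two-state Markov process per
#' gate with open/close rate constants in 1/ns; the gate-forming
#' side-chain marker beads sit at the current gate radius, so
#' minimum-distance analyses see an aperture of twice the radius.
#'
#' @param seed RNG seed.
#' @param n_frames Number of stored frames.
#' @param stride Time between stored frames (ps).
#' @param box Box lengths (A).
#' @param pore A [pore_axis_model()].
#' @param mode `"rate"` or `"diffusion"` (see Details).
#' @param potential data.frame (z, U) in A / kcal/mol: piecewise-linear
#'   potential for diffusion mode; default flat over `ion_z_range`.
#' @param voltage_mV Transmembrane voltage over the box height (drives a
#'   uniform +z force on ions in diffusion mode).
#' @param n_ions,n_waters Particle counts.
#' @param ion_diffusion,water_diffusion Diffusion coefficients (A^2/ps).
#' @param substeps Integrator substeps per stored frame (diffusion mode).
#' @param ion_z_range Reflecting bounds for diffusing ions; default the
#'   potential grid range, or entrance-20 .. SF end.
#' @param water_density_profile data.frame (z_low, z_high, density) of
#'   relative water densities per region; waters are confined to (and
#'   reflected within) their region.
#' @param gate_flicker Named list (`gloop`, `hbc`) of lists with
#'   `open_rate`, `close_rate` (1/ns), `open_radius`, `closed_radius`
#'   (A); `NULL` for static open gates.
#' @param sf_single_occupancy Enforce at most one ion per SF site; an ion
#'   entering S4 with S3/S2 occupied displaces the chain upward within
#'   the same frame interval (direct knock-on rule).
#' @param solvation_shell Number of waters re-seeded within 2.6-3.4 A of
#'   each ion while the ion is below the SF.
#' @param target_rate_per_us Rate-mode Poisson rate of scheduled pore
#'   transits (events / microsecond).
#' @param transit_ps Rate-mode time for an ion to travel from the bulk to
#'   the filter entrance (and for the displaced ion to exit).
#' @param include_scaffold Emit the 4 x N pseudo-protein marker scaffold
#'   (gate beads, SF planes, TMD/CTD bead clouds). Disable for very long
#'   ion-only runs to keep the coordinate array small.
#' @return Object of class `synthetic_pore_config`.
#' @export
synthetic_pore_config <- function(seed = 1, n_frames = 1000, stride = 20,
                                  box = c(80, 80, 145),
                                  pore = default_pore_model(),
                                  mode = c("rate", "diffusion"),
                                  potential = NULL, voltage_mV = 0,
                                  n_ions = 4, n_waters = 0,
                                  ion_diffusion = 0.2, water_diffusion = 0.2,
                                  substeps = 10, ion_z_range = NULL,
                                  water_density_profile = NULL,
                                  gate_flicker = NULL,
                                  sf_single_occupancy = FALSE,
                                  solvation_shell = 0,
                                  target_rate_per_us = 10,
                                  transit_ps = 500,
                                  include_scaffold = TRUE) {
  mode <- match.arg(mode)
  stopifnot(n_frames >= 1, stride > 0, length(box) == 3, all(box > 0),
            inherits(pore, "pore_axis_model"), n_ions >= 0, n_waters >= 0,
            substeps >= 1, ion_diffusion > 0, target_rate_per_us >= 0)
  if (is.null(ion_z_range)) {
    ion_z_range <- if (!is.null(potential)) range(potential$z) else
      c(pore$z_entrance - 20, max(pore$z_sites))
  }
  if (!is.null(potential)) {
    stopifnot(is.data.frame(potential), all(c("z", "U") %in% names(potential)),
              nrow(potential) >= 2, !is.unsorted(potential$z))
    if (potential$z[1] > ion_z_range[1] ||
        potential$z[nrow(potential)] < ion_z_range[2]) {
      stop("potential grid must span the ion z range")
    }
  }
  if (!is.null(gate_flicker)) {
    for (g in gate_flicker) {
      stopifnot(g$open_rate >= 0, g$close_rate >= 0,
                g$open_radius > g$closed_radius)
    }
  }
  if (is.null(water_density_profile)) {
    water_density_profile <- data.frame(
      z_low = c(5, pore$z_entrance, pore$z_sites[6] + 2),
      z_high = c(pore$z_entrance, pore$z_sites[1] - 1, box[3] - 5),
      density = c(1, 1, 1))
  }
  structure(list(seed = seed, n_frames = n_frames, stride = stride,
                 box = box, pore = pore, mode = mode, potential = potential,
                 voltage_mV = voltage_mV, n_ions = n_ions,
                 n_waters = n_waters, ion_diffusion = ion_diffusion,
                 water_diffusion = water_diffusion, substeps = substeps,
                 ion_z_range = ion_z_range,
                 water_density_profile = water_density_profile,
                 gate_flicker = gate_flicker,
                 sf_single_occupancy = sf_single_occupancy,
                 solvation_shell = solvation_shell,
                 target_rate_per_us = target_rate_per_us,
                 transit_ps = transit_ps,
                 include_scaffold = include_scaffold),
            class = "synthetic_pore_config")
}

## reflect positions into [lo, hi] (triangle-wave fold), vectorized
.fold <- function(x, lo, hi) {
  w <- hi - lo
  y <- (x - lo) %% (2 * w)
  lo + ifelse(y > w, 2 * w - y, y)
}

## ---- pseudo-protein scaffold ----------------------------------------------
## Four subunits A-D at 0/90/180/270 degrees. Marker beads:
##   G318 (CA, O) and M319 (CA, SD) at the G-loop; F192 (CA, CZ) at the
##   HBC (CA ring diameter 15.3 A, the crystal-structure gate width);
##   SF residues 154-159 with carbonyl O at the six site-boundary planes
##   plus CA beads (the superposition selection); TMD and CTD bead clouds
##   for the rotation analysis.
.build_scaffold <- function(pore, box) {
  cx <- box[1] / 2
  cy <- box[2] / 2
  subunits <- c("A", "B", "C", "D")
  angles <- c(0, 90, 180, 270) * pi / 180
  sf_res <- data.frame(resno = 154:159,
                       resname = c("THR", "THR", "ILE", "GLY", "TYR", "GLY"))
  rows <- list()
  add <- function(su, ang, resno, resname, atom, r, z, dynamic = NA) {
    rows[[length(rows) + 1L]] <<- data.frame(
      subunit = su, resno = resno, resname = resname, atom = atom,
      x = cx + r * cos(ang), y = cy + r * sin(ang), z = z,
      angle = ang, radius = r, dynamic = dynamic)
  }
  for (k in seq_along(subunits)) {
    su <- subunits[k]; ang <- angles[k]
    add(su, ang, 318, "GLY", "CA", 6.0, pore$z_gloop)
    add(su, ang, 318, "GLY", "O", 4.0, pore$z_gloop)
    add(su, ang, 319, "MET", "CA", 6.0, pore$z_gloop + 1)
    add(su, ang, 319, "MET", "SD", 3.0, pore$z_gloop, dynamic = "gloop")
    add(su, ang, 192, "PHE", "CA", 7.65, pore$z_hbc)
    add(su, ang, 192, "PHE", "CZ", 3.0, pore$z_hbc, dynamic = "hbc")
    for (j in 1:6) {
      add(su, ang, sf_res$resno[j], sf_res$resname[j], "O", 1.4,
          pore$z_sites[j])
      add(su, ang, sf_res$resno[j], sf_res$resname[j], "CA", 3.0,
          pore$z_sites[j])
    }
    for (j in 1:5) {
      add(su, ang, 70 + j, "ALA", "CA", 14, pore$z_hbc + 2 * j)       # TMD
      add(su, ang, 240 + j, "ALA", "CA", 14, pore$z_entrance + 2 * j) # CTD
    }
  }
  do.call(rbind, rows)
}

## two-state gate Markov chain sampled at the frame stride; returns the
## per-frame radius
.gate_radius_series <- function(g, n_frames, stride_ps) {
  if (is.null(g)) return(rep(NA_real_, n_frames))
  dt_ns <- stride_ps / 1000
  p_open <- 1 - exp(-g$open_rate * dt_ns)   # closed -> open
  p_close <- 1 - exp(-g$close_rate * dt_ns) # open -> closed
  eq_open <- if (g$open_rate + g$close_rate > 0) {
    g$open_rate / (g$open_rate + g$close_rate)
  } else 1
  state <- logical(n_frames) # TRUE = open
  state[1] <- runif(1) < eq_open
  if (n_frames > 1) {
    u <- runif(n_frames - 1)
    for (f in 2:n_frames) {
      state[f] <- if (state[f - 1]) u[f - 1] >= p_close else u[f - 1] < p_open
    }
  }
  ifelse(state, g$open_radius, g$closed_radius)
}

## region-confined random walks for waters, vectorized over frames
.water_positions <- function(config, n_frames) {
  prof <- config$water_density_profile
  n_w <- config$n_waters
  if (n_w == 0) {
    return(list(z = matrix(numeric(0), n_frames, 0),
                x = matrix(numeric(0), n_frames, 0),
                y = matrix(numeric(0), n_frames, 0)))
  }
  w <- (prof$z_high - prof$z_low) * prof$density
  counts <- floor(n_w * w / sum(w))
  rem <- n_w - sum(counts)
  if (rem > 0) counts[seq_len(rem)] <- counts[seq_len(rem)] + 1
  sigma <- sqrt(2 * config$water_diffusion * config$stride)
  cx <- config$box[1] / 2
  cy <- config$box[2] / 2
  half <- config$pore$pore_radius / sqrt(2) # inscribed square: r always < R
  zl <- xl <- yl <- list()
  for (r in seq_len(nrow(prof))) {
    nr <- counts[r]
    if (nr == 0) next
    z0 <- runif(nr, prof$z_low[r], prof$z_high[r])
    steps <- matrix(rnorm(n_frames * nr, sd = sigma), n_frames, nr)
    steps[1, ] <- 0
    zl[[r]] <- .fold(sweep(apply(steps, 2, cumsum), 2, z0, `+`),
                     prof$z_low[r], prof$z_high[r])
    for (axis in c("x", "y")) {
      p0 <- runif(nr, -half, half)
      st <- matrix(rnorm(n_frames * nr, sd = sigma), n_frames, nr)
      st[1, ] <- 0
      v <- .fold(sweep(apply(st, 2, cumsum), 2, p0, `+`), -half, half)
      if (axis == "x") xl[[r]] <- v + cx else yl[[r]] <- v + cy
    }
  }
  list(z = do.call(cbind, zl), x = do.call(cbind, xl), y = do.call(cbind, yl))
}

## piecewise-constant force from a piecewise-linear potential
.segment_forces <- function(potential) {
  -diff(potential$U) / diff(potential$z)
}

## ---- diffusion mode --------------------------------------------------------
.simulate_diffusion_ions <- function(config) {
  n_ions <- config$n_ions
  n_fr <- config$n_frames
  pore <- config$pore
  kT <- kT_kcal(310)
  D <- config$ion_diffusion
  dt <- config$stride / config$substeps
  zr <- config$ion_z_range
  pot <- config$potential
  Fseg <- if (!is.null(pot)) .segment_forces(pot) else NULL
  ## uniform field force on +1 charge: e * V / L_z, in kcal/mol/A
  f_field <- 0.0230605 * config$voltage_mV / config$box[3]
  sd_step <- sqrt(2 * D * dt)
  mob_dt <- D / kT * dt
  z <- runif(n_ions, zr[1], zr[2])
  zmat <- matrix(NA_real_, n_fr, max(n_ions, 1))
  if (n_ions == 0) return(zmat[, 0, drop = FALSE])
  zmat[1, ] <- z
  gate_block <- function(z_old, z_new, gate_z, closed) {
    if (!closed) return(z_new)
    crossed <- (z_old - gate_z) * (z_new - gate_z) < 0
    ifelse(crossed, z_old, z_new)
  }
  gl <- config$gate_flicker
  gl_r <- if (!is.null(gl$gloop)) attr(config, "gloop_radius") else NULL
  hb_r <- if (!is.null(gl$hbc)) attr(config, "hbc_radius") else NULL
  s_bounds <- .pore_landmarks(pore)$z_sites
  for (f in 2:n_fr) {
    for (s in seq_len(config$substeps)) {
      Fz <- rep(f_field, n_ions)
      if (!is.null(Fseg)) {
        seg <- findInterval(z, pot$z, all.inside = TRUE)
        Fz <- Fz + Fseg[seg]
      }
      z_new <- z + mob_dt * Fz + rnorm(n_ions, sd = sd_step)
      z_new <- .fold(z_new, zr[1], zr[2])
      if (!is.null(gl_r)) {
        z_new <- gate_block(z, z_new, pore$z_gloop, gl_r[f] < 2)
      }
      if (!is.null(hb_r)) {
        z_new <- gate_block(z, z_new, pore$z_hbc, hb_r[f] < 2)
      }
      z <- z_new
    }
    if (config$sf_single_occupancy) z <- .resolve_sf_occupancy(z, s_bounds)
    zmat[f, ] <- z
  }
  zmat
}

## single-occupancy rule: ions inside the SF are pushed upward so that no
## site holds two; an ion pushed beyond S0 exits above the filter
.resolve_sf_occupancy <- function(z, s_bounds) {
  centers <- s_bounds[-6] + diff(s_bounds) / 2
  in_sf <- z >= s_bounds[1] & z < s_bounds[6]
  if (sum(in_sf) < 2) return(z)
  ord <- order(z[in_sf])
  idx <- which(in_sf)[ord]
  sites <- findInterval(z[idx], s_bounds)
  for (j in seq_along(idx)) {
    if (j > 1 && sites[j] <= sites[j - 1]) sites[j] <- sites[j - 1] + 1
  }
  for (j in seq_along(idx)) {
    if (sites[j] > 5) {
      z[idx[j]] <- s_bounds[6] + 3 # knocked out above the filter
    } else if (findInterval(z[idx[j]], s_bounds) != sites[j]) {
      z[idx[j]] <- centers[sites[j]]
    }
  }
  z
}

## ---- rate mode -------------------------------------------------------------
## Ions wait in the bottom bulk and perform scheduled transits at Poisson
## times. With sf_single_occupancy, two resident ions sit at S3/S2 and an
## arriving ion displaces the chain (direct knock-on); otherwise the
## scheduled ion traverses the whole pore itself. Paths are built as
## piecewise-linear z(t) knots, then sampled at the frame times.
.simulate_rate_ions <- function(config) {
  n_fr <- config$n_frames
  pore <- config$pore
  lm <- .pore_landmarks(pore)
  s_bounds <- lm$z_sites
  centers <- s_bounds[-6] + diff(s_bounds) / 2
  T_ps <- (n_fr - 1) * config$stride
  box_z <- config$box[3]
  z_wait <- lm$z_entrance - 12
  z_top <- s_bounds[6] + 8
  rate_per_ps <- config$target_rate_per_us * 1e-6
  knock <- config$sf_single_occupancy && config$n_ions >= 3
  n_ions <- config$n_ions
  ## path knots per ion, in unwrapped z: each completed passage adds one
  ## box length (z_off), so knot sequences are monotone and the wrapped
  ## coordinate shows a clean periodic jump
  knots <- lapply(seq_len(n_ions), function(i) {
    list(t = 0, z = z_wait + (i %% 5) * 0.5)
  })
  z_off <- rep(0, n_ions)
  add_knot <- function(i, t, z) {
    knots[[i]]$t <<- c(knots[[i]]$t, t)
    knots[[i]]$z <<- c(knots[[i]]$z, z + z_off[i])
  }
  free_at <- rep(0, n_ions) # time from which each ion is available
  resident <- integer(0)    # ion ids at (S3, S2), bottom first
  ## initial residents start inside the filter, so their first exit is
  ## not a full bottom-to-top crossing of the recorded trajectory
  entered_from_bulk <- rep(TRUE, n_ions)
  if (knock) {
    resident <- c(1L, 2L)
    knots[[1]] <- list(t = 0, z = centers[2]) # S3
    knots[[2]] <- list(t = 0, z = centers[3]) # S2
    free_at[1:2] <- Inf
    entered_from_bulk[1:2] <- FALSE
  }
  events <- list()
  if (rate_per_ps > 0 && n_ions > length(resident)) {
    t_trig <- cumsum(rexp(max(10, ceiling(2 * rate_per_ps * T_ps + 30)),
                          rate = rate_per_ps))
    t_trig <- t_trig[t_trig < T_ps - 2 * config$transit_ps]
    for (tt in t_trig) {
      cand <- setdiff(which(free_at <= tt), resident)
      if (!length(cand)) next
      i <- cand[1]
      t_arr <- tt + config$transit_ps       # arrival at S4
      if (knock) {
        add_knot(i, tt, z_wait + (i %% 5) * 0.5)
        entered_from_bulk[i] <- TRUE
        add_knot(i, t_arr, centers[1])      # S4
        add_knot(i, t_arr + config$stride, centers[2]) # settles at S3
        ## chain: S3 resident -> S2; S2 resident exits
        r3 <- resident[1]; r2 <- resident[2]
        add_knot(r3, t_arr, centers[2])
        add_knot(r3, t_arr + config$stride, centers[3])
        add_knot(r2, t_arr, centers[3])
        ## the displaced ion clears S2 within one frame interval (rapid
        ## exit via S1/S0), so no stored frame ever shows two ions in a
        ## shared site
        t_out <- t_arr + config$transit_ps
        add_knot(r2, t_arr + config$stride, s_bounds[6] + 0.5)
        add_knot(r2, t_out, z_top)
        ## continue upward through the periodic boundary back to the
        ## bottom bulk (one full box length gained)
        t_back <- t_out + config$transit_ps
        z_off[r2] <- z_off[r2] + box_z
        add_knot(r2, t_back, z_wait + (r2 %% 5) * 0.5)
        resident <- c(i, r3)
        free_at[i] <- Inf
        free_at[r3] <- Inf
        free_at[r2] <- t_back + 5 * config$stride
        if (entered_from_bulk[r2]) {
          events[[length(events) + 1L]] <- data.frame(
            ion = r2, t_trigger = tt, t_exit = t_out)
        }
      } else {
        t_out <- t_arr + config$transit_ps  # straight through the filter
        add_knot(i, tt, z_wait + (i %% 5) * 0.5)
        add_knot(i, t_arr, s_bounds[1])
        add_knot(i, t_out, z_top)
        t_back <- t_out + config$transit_ps
        z_off[i] <- z_off[i] + box_z
        add_knot(i, t_back, z_wait + (i %% 5) * 0.5)
        free_at[i] <- t_back + 5 * config$stride
        events[[length(events) + 1L]] <- data.frame(
          ion = i, t_trigger = tt, t_exit = t_out)
      }
    }
  }
  times <- (seq_len(n_fr) - 1) * config$stride
  zmat <- matrix(NA_real_, n_fr, max(n_ions, 1))[, seq_len(n_ions), drop = FALSE]
  for (i in seq_len(n_ions)) {
    k <- knots[[i]]
    zraw <- if (length(k$t) < 2) rep(k$z[1], n_fr) else
      approx(k$t, k$z, xout = times, rule = 2)$y
    zmat[, i] <- zraw %% box_z # wrapped coordinate as a real box would store
  }
  planted <- if (length(events)) do.call(rbind, events) else
    data.frame(ion = integer(), t_trigger = numeric(), t_exit = numeric())
  list(z = zmat, planted = planted)
}

#' Generate a synthetic pore trajectory with ground truth
#'
#' Emits a [labeled_trajectory()] (pseudo-protein scaffold + ions +
#' waters) together with the ground truth needed to validate analyses:
#' the planted permeation events (rate mode), the true potential
#' (diffusion mode), and the per-gate open fractions. Deterministic for a
#' fixed seed.
#'
#' @param config A [synthetic_pore_config()].
#' @return List with elements `trajectory` and `ground_truth`.
#' @export
generate_pore_trajectory <- function(config) {
  stopifnot(inherits(config, "synthetic_pore_config"))
  set.seed(config$seed)
  n_fr <- config$n_frames
  pore <- config$pore
  times <- (seq_len(n_fr) - 1) * config$stride
  cx <- config$box[1] / 2
  cy <- config$box[2] / 2

  ## gate radii first so the diffusion stepper can read them
  gl_r <- .gate_radius_series(config$gate_flicker$gloop, n_fr, config$stride)
  hb_r <- .gate_radius_series(config$gate_flicker$hbc, n_fr, config$stride)
  attr(config, "gloop_radius") <- gl_r
  attr(config, "hbc_radius") <- hb_r

  planted <- data.frame(ion = integer(), t_trigger = numeric(),
                        t_exit = numeric())
  if (config$mode == "diffusion") {
    z_ions <- .simulate_diffusion_ions(config)
  } else {
    rt <- .simulate_rate_ions(config)
    z_ions <- rt$z
    planted <- rt$planted
  }
  wat <- .water_positions(config, n_fr)

  ## assemble the particle table
  scaffold <- if (config$include_scaffold) .build_scaffold(pore, config$box)
  n_prot <- if (is.null(scaffold)) 0L else nrow(scaffold)
  n_ions <- config$n_ions
  n_w <- ncol(wat$z)
  sys_df <- data.frame(
    id = seq_len(n_prot + n_ions + n_w),
    role = c(rep("protein", n_prot), rep("ion", n_ions),
             rep("water_oxygen", n_w)),
    subunit = c(if (n_prot) scaffold$subunit, rep(NA, n_ions + n_w)),
    resno = c(if (n_prot) scaffold$resno, seq_len(n_ions + n_w) + 1000L),
    resname = c(if (n_prot) scaffold$resname, rep("K", n_ions),
                rep("HOH", n_w)),
    atom = c(if (n_prot) scaffold$atom, rep("K", n_ions), rep("OW", n_w)),
    element = c(if (n_prot) substr(scaffold$atom, 1, 1), rep("K", n_ions),
                rep("O", n_w)))
  system <- pore_system(sys_df)

  coords <- array(NA_real_, dim = c(nrow(sys_df), 3, n_fr))
  if (n_prot) {
    coords[seq_len(n_prot), 1, ] <- scaffold$x
    coords[seq_len(n_prot), 2, ] <- scaffold$y
    coords[seq_len(n_prot), 3, ] <- scaffold$z
    for (gate in c("gloop", "hbc")) {
      r_series <- if (gate == "gloop") gl_r else hb_r
      if (all(is.na(r_series))) next
      dyn <- which(scaffold$dynamic %in% gate)
      for (d in dyn) {
        coords[d, 1, ] <- cx + r_series * cos(scaffold$angle[d])
        coords[d, 2, ] <- cy + r_series * sin(scaffold$angle[d])
      }
    }
  }
  if (n_ions) {
    ion_rows <- n_prot + seq_len(n_ions)
    ## small lateral jitter inside the pore cylinder; ions waiting in the
    ## bottom bulk spread out on a ring so their hydration shells stay
    ## distinct
    for (j in seq_len(n_ions)) {
      r <- sqrt(runif(n_fr)) * 1.5
      th <- runif(n_fr, 0, 2 * pi)
      x <- cx + r * cos(th)
      y <- cy + r * sin(th)
      if (config$mode == "rate" && n_ions > 1) {
        in_bulk <- z_ions[, j] < pore$z_entrance - 5
        ring <- 2 * pi * j / n_ions
        x[in_bulk] <- x[in_bulk] + 5 * cos(ring)
        y[in_bulk] <- y[in_bulk] + 5 * sin(ring)
      }
      coords[ion_rows[j], 1, ] <- x
      coords[ion_rows[j], 2, ] <- y
      coords[ion_rows[j], 3, ] <- z_ions[, j]
    }
  }
  if (n_w) {
    w_rows <- n_prot + n_ions + seq_len(n_w)
    coords[w_rows, 1, ] <- t(wat$x)
    coords[w_rows, 2, ] <- t(wat$y)
    coords[w_rows, 3, ] <- t(wat$z)
    ## solvation shell: the first shell waters follow their ion while it
    ## is below the selectivity filter
    n_shell <- min(config$solvation_shell * n_ions, n_w)
    if (n_shell > 0 && n_ions > 0) {
      sf_lo <- .pore_landmarks(pore)$z_sites[1]
      k <- 0
      for (j in seq_len(n_ions)) {
        for (s in seq_len(config$solvation_shell)) {
          k <- k + 1
          if (k > n_shell) break
          rr <- runif(n_fr, 2.6, 3.4)
          u <- matrix(rnorm(3 * n_fr), n_fr, 3)
          u <- u / sqrt(rowSums(u^2))
          follow <- z_ions[, j] < sf_lo
          row <- w_rows[k]
          coords[row, 1, follow] <- coords[n_prot + j, 1, follow] +
            (rr * u[, 1])[follow]
          coords[row, 2, follow] <- coords[n_prot + j, 2, follow] +
            (rr * u[, 2])[follow]
          coords[row, 3, follow] <- coords[n_prot + j, 3, follow] +
            (rr * u[, 3])[follow]
        }
      }
    }
  }
  traj <- labeled_trajectory(system, coords, times, config$box)
  gate_truth <- list()
  for (gate in c("gloop", "hbc")) {
    g <- config$gate_flicker[[gate]]
    if (is.null(g)) next
    r_series <- if (gate == "gloop") gl_r else hb_r
    gate_truth[[gate]] <- list(
      analytic_open_fraction = g$open_rate / (g$open_rate + g$close_rate),
      realized_open_fraction = mean(r_series == g$open_radius),
      open_radius = g$open_radius, closed_radius = g$closed_radius)
  }
  ground_truth <- list(
    mode = config$mode,
    expected_permeation_rate = if (config$mode == "rate")
      config$target_rate_per_us else NA_real_,
    n_planted_events = nrow(planted),
    planted_events = planted,
    true_potential = config$potential,
    gate_open_fraction = gate_truth,
    seed = config$seed)
  list(trajectory = traj, ground_truth = ground_truth)
}

#' Write a synthetic run to disk
#'
#' Emits the topology PDB, the columnar frame file and the ground truth
#' as a JSON sidecar, the on-disk interface consumed by
#' [run_pipeline()] manifests.
#'
#' @param run A list from [generate_pore_trajectory()].
#' @param dir Output directory (created if needed).
#' @param name Base file name.
#' @return Named character vector of the three file paths, invisibly.
#' @export
write_pore_run <- function(run, dir, name = "run") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  topo <- file.path(dir, paste0(name, "_topology.pdb"))
  frames <- file.path(dir, paste0(name, "_frames.tsv"))
  truth <- file.path(dir, paste0(name, "_truth.json"))
  traj1 <- subset_frames(run$trajectory, 1)
  write_frames(traj1, topo, format = "pdb")
  write_frames(run$trajectory, frames, format = "columnar")
  gt <- run$ground_truth
  gt$planted_events <- as.list(gt$planted_events)
  jsonlite::write_json(gt, truth, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(c(topology = topo, frames = frames, ground_truth = truth))
}
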