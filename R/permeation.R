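.compartments <- c("bulk_in", "CTD", "Gloop", "cavity",
                   "S4", "S3", "S2", "S1", "S0", "bulk_out")

.label_compartment <- function(z, lm, gloop_halfwidth = 2) {
  breaks <- c(-Inf, lm$z_entrance, lm$z_gloop - gloop_halfwidth,
              lm$z_gloop + gloop_halfwidth, lm$z_sites, Inf)
  .compartments[findInterval(z, breaks, left.open = FALSE)]
}

#' Per-ion z traces with compartment labels
#'
#' For every ion: the raw z coordinate, the unwrapped z (continuous
#' across periodic boundaries), and a per-frame compartment label
#' (bulk_in, CTD, Gloop, cavity, S4..S0, bulk_out) derived from the pore
#' landmarks. Compartment windows are left-closed; the G-loop compartment
#' spans `z_gloop +/- gloop_halfwidth`.
#'
#' @param traj A [labeled_trajectory()].
#' @param pore A [pore_axis_model()].
#' @param gloop_halfwidth Half-width (A) of the G-loop compartment.
#' @return List of data.frames (frame, time_ps, z, z_unwrapped,
#'   compartment), one per ion, named by ion id; each carries attributes
#'   `ion_id`, `stride_ps` and `box_z`.
#' @export
ion_traces <- function(traj, pore, gloop_halfwidth = 2) {
  ions <- which(traj$system$role == "ion")
  if (!length(ions)) stop("no ions in system")
  lm <- .pore_landmarks(pore)
  out <- lapply(ions, function(i) {
    z_raw <- .axis_z(pore, traj$coords[i, 3, ])
    z_un <- unwrap_coordinate(z_raw, traj$box[, 3])
    tr <- data.frame(frame = seq_len(n_frames(traj)) - 1L,
                     time_ps = traj$times, z = z_raw, z_unwrapped = z_un,
                     compartment = .label_compartment(z_raw, lm,
                                                     gloop_halfwidth))
    attr(tr, "ion_id") <- traj$system$id[i]
    attr(tr, "stride_ps") <- frame_stride(traj)
    attr(tr, "box_z") <- stats::median(traj$box[, 3])
    tr
  })
  names(out) <- traj$system$id[ions]
  out
}

.interval_bounds <- function(pore, interval) {
  lm <- .pore_landmarks(pore)
  switch(interval,
         SF_full = c(lm$z_sites[1], lm$z_sites[6]),
         HBC = c(lm$z_hbc, lm$z_hbc),
         Gloop = c(lm$z_gloop, lm$z_gloop),
         stop("unknown interval '", interval, "'"))
}

## committed-crossing scan of one (possibly image-shifted) interval
.scan_interval <- function(z, times, lo_c, hi_c) {
  side <- integer(length(z))
  side[z < lo_c] <- -1L
  side[z > hi_c] <- 1L
  keep <- which(side != 0L)
  if (length(keep) < 2) return(NULL)
  s <- side[keep]
  chg <- which(diff(s) != 0L) # s[chg] -> s[chg+1] is a committed transition
  if (!length(chg)) return(NULL)
  data.frame(entry_frame = keep[chg] - 1L,
             exit_frame = keep[chg + 1L] - 1L,
             entry_time = times[keep[chg]],
             exit_time = times[keep[chg + 1L]],
             direction = ifelse(s[chg + 1L] > 0, "outward", "inward"))
}

#' Detect committed permeation events on an ion trace
#'
#' Two-plane committed-crossing rule: an event is recorded only when the
#' unwrapped trace passes from below `lower boundary - margin` to above
#' `upper boundary + margin` (outward; the reverse for inward) without
#' first returning behind the plane it came from. Recrossings inside the
#' interval — gate flicker — therefore never create extra events. The
#' rule is applied to every periodic image of the interval, so an ion
#' that permeates repeatedly (re-entering through the periodic boundary)
#' is counted once per passage.
#'
#' @param trace One trace from [ion_traces()].
#' @param pore A [pore_axis_model()].
#' @param interval `"SF_full"` (below S4 to above S0), `"HBC"` or
#'   `"Gloop"` (single-landmark crossings).
#' @param margin Committed margin in A beyond each boundary (default 2).
#' @return data.frame of events (ion_id, interval, entry_frame,
#'   exit_frame, entry_time, exit_time, direction), possibly empty.
#' @export
detect_events <- function(trace, pore, interval = c("SF_full", "HBC", "Gloop"),
                          margin = 2) {
  interval <- match.arg(interval)
  if (margin < 0) stop("margin must be >= 0")
  b <- .interval_bounds(pore, interval)
  z <- trace$z_unwrapped
  L <- attr(trace, "box_z")
  if (is.null(L) || is.na(L)) L <- max(z) - min(z) + 2 * margin + 1
  k_lo <- floor((min(z) - b[2]) / L) - 1
  k_hi <- ceiling((max(z) - b[1]) / L) + 1
  evs <- list()
  for (k in k_lo:k_hi) {
    e <- .scan_interval(z, trace$time_ps, b[1] + k * L - margin,
                        b[2] + k * L + margin)
    if (!is.null(e)) evs[[length(evs) + 1L]] <- e
  }
  if (!length(evs)) {
    return(data.frame(ion_id = integer(), interval = character(),
                      entry_frame = integer(), exit_frame = integer(),
                      entry_time = numeric(), exit_time = numeric(),
                      direction = character()))
  }
  out <- do.call(rbind, evs)
  out <- out[order(out$exit_frame), ]
  data.frame(ion_id = attr(trace, "ion_id"), interval = interval,
             out[, c("entry_frame", "exit_frame", "entry_time", "exit_time",
                     "direction")],
             row.names = NULL)
}

#' Detect events for all ions of a trajectory
#'
#' @param traces List from [ion_traces()].
#' @inheritParams detect_events
#' @return Combined event data.frame, ordered by exit time.
#' @export
detect_all_events <- function(traces, pore,
                              interval = c("SF_full", "HBC", "Gloop"),
                              margin = 2) {
  interval <- match.arg(interval)
  out <- do.call(rbind, lapply(traces, detect_events, pore = pore,
                               interval = interval, margin = margin))
  out <- out[order(out$exit_time), ]
  rownames(out) <- NULL
  out
}

#' Per-run permeation counts, rates and conductance
#'
#' Converts per-run event counts into rates (events per microsecond) and
#' single-channel conductance g = N e / (t V) in picosiemens (e the
#' elementary charge), and summarises groups (e.g. restrained vs
#' unrestrained gate) by mean and sample standard deviation (n-1
#' denominator).
#'
#' @param counts Integer vector of per-run event counts.
#' @param duration_us Per-run simulated time in microseconds.
#' @param voltage_mV Per-run transmembrane voltage in mV (optional; zero
#'   or missing voltage yields `NA` conductance with a warning).
#' @param group Optional per-run group labels.
#' @param run_id Optional run identifiers.
#' @return List with `per_run` (run_id, count, duration_us, rate,
#'   voltage_mV, conductance_pS, group) and `groups` (group, n,
#'   mean_rate, sd_rate), plus `total` events.
#' @export
count_and_rates <- function(counts, duration_us, voltage_mV = NULL,
                            group = NULL, run_id = NULL) {
  n <- length(counts)
  if (any(duration_us <= 0)) stop("run durations must be > 0")
  duration_us <- rep_len(duration_us, n)
  if (is.null(run_id)) run_id <- paste0("run", seq_len(n))
  rate <- counts / duration_us
  cond <- rep(NA_real_, n)
  if (!is.null(voltage_mV)) {
    voltage_mV <- rep_len(voltage_mV, n)
    ok <- !is.na(voltage_mV) & voltage_mV != 0
    if (any(!ok)) warning("zero/missing voltage: conductance undefined for ",
                          sum(!ok), " run(s)")
    cond[ok] <- counts[ok] * .e_coulomb /
      (duration_us[ok] * 1e-6 * voltage_mV[ok] * 1e-3) * 1e12
  }
  per_run <- data.frame(run_id = run_id, count = as.numeric(counts),
                        duration_us = duration_us, rate = rate,
                        voltage_mV = if (is.null(voltage_mV)) NA_real_ else voltage_mV,
                        conductance_pS = cond,
                        group = if (is.null(group)) "all" else group)
  groups <- do.call(rbind, lapply(split(per_run, per_run$group), function(g) {
    data.frame(group = g$group[1], n = nrow(g), mean_rate = mean(g$rate),
               sd_rate = if (nrow(g) > 1) sd(g$rate) else NA_real_)
  }))
  rownames(groups) <- NULL
  list(per_run = per_run, groups = groups, total = sum(counts))
}

#' Dwell times of an ion in a pore compartment
#'
#' Maximal contiguous frame spans carrying the requested compartment
#' label, converted to nanoseconds via the frame stride.
#'
#' @param trace One trace from [ion_traces()].
#' @param site Compartment label (`"S0"`..`"S4"`, `"Gloop"`, `"cavity"`, ...).
#' @return Numeric vector of dwell durations in ns (possibly empty).
#' @export
residence_times <- function(trace, site) {
  if (!site %in% .compartments) stop("unknown site '", site, "'")
  stride <- attr(trace, "stride_ps")
  r <- rle(trace$compartment == site)
  r$lengths[r$values] * stride / 1000
}

#' Cumulative ion flux over time
#'
#' Step function of the cumulative permeation count versus time,
#' non-decreasing by construction, ending at the total event count.
#'
#' @param events Event data.frame from [detect_all_events()].
#' @param t_end Optional final time (ps) to extend the last step to.
#' @return data.frame (time_ps, cumulative), starting at (0, 0).
#' @export
cumulative_flux <- function(events, t_end = NULL) {
  t <- sort(events$exit_time)
  out <- data.frame(time_ps = c(0, t), cumulative = c(0, seq_along(t)))
  if (!is.null(t_end) && (nrow(out) == 0 || t_end > max(out$time_ps))) {
    out <- rbind(out, data.frame(time_ps = t_end,
                                 cumulative = length(t)))
  }
  out
}

#' Transmembrane voltage from a uniform applied field
#'
#' A constant electric field E applied over a periodic box of height L_z
#' corresponds to a transmembrane potential V = E * L_z.
#'
#' @param field_mV_per_nm Field strength in mV/nm.
#' @param box_z_nm Box height in nm.
#' @return Voltage in mV.
#' @examples
#' field_to_voltage(40, 14.5)  # 580 mV
#' @export
field_to_voltage <- function(field_mV_per_nm, box_z_nm) {
  if (any(field_mV_per_nm < 0) || any(box_z_nm <= 0)) {
    stop("field must be >= 0 and box height > 0")
  }
  field_mV_per_nm * box_z_nm
}
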