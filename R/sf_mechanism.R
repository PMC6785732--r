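#' Selectivity-filter site occupancy states
#'
#' Assigns every ion and water oxygen inside the selectivity filter
#' (radial distance from the pore axis no greater than `pore$sf_radius`,
#' z inside the site windows) to one of the five binding sites S4..S0 and
#' encodes each frame as a five-letter string over the alphabet K (at
#' least one ion), W (no ion, at least one water) and 0 (empty), ordered
#' S4 to S0. Site windows are the intervals between consecutive site
#' boundaries, left-closed. K takes priority over W when both occupy the
#' same site window.
#'
#' @param traj A [labeled_trajectory()].
#' @param pore A [pore_axis_model()].
#' @param axis_xy Optional pore axis (`n_frames x 2`); default box centre.
#' @return Object of class `site_occupancy`: list with `states`
#'   (character vector, one string per frame), `matrix` (frames x 5,
#'   colnames S4..S0), `multi_ion` (logical per frame: some site held
#'   more than one ion), `times`.
#' @export
assign_sites <- function(traj, pore, axis_xy = NULL) {
  lm <- .pore_landmarks(pore)
  bounds <- lm$z_sites
  if (any(diff(bounds) <= 0)) stop("site windows overlap or are empty")
  axis_xy <- .default_axis(traj, axis_xy)
  sites <- c("S4", "S3", "S2", "S1", "S0")
  ions <- which(traj$system$role == "ion")
  wats <- which(traj$system$role == "water_oxygen")
  n_fr <- n_frames(traj)
  mat <- matrix("0", n_fr, 5, dimnames = list(NULL, sites))
  multi <- logical(n_fr)
  site_of <- function(idx, f) {
    if (!length(idx)) return(integer())
    xyz <- .fcoords(traj, idx, f)
    r <- .radial_dist(xyz, axis_xy[f, ])
    zz <- .axis_z(pore, xyz[, 3])
    s <- findInterval(zz, bounds, left.open = FALSE)
    s[r > pore$sf_radius | s < 1 | s > 5 | zz >= bounds[6]] <- NA
    s[!is.na(s)]
  }
  for (f in seq_len(n_fr)) {
    si <- site_of(ions, f)
    sw <- site_of(wats, f)
    if (length(sw)) mat[f, unique(sw)] <- "W"
    if (length(si)) {
      mat[f, unique(si)] <- "K"
      multi[f] <- anyDuplicated(si) > 0
    }
  }
  structure(list(states = apply(mat, 1, paste, collapse = ""),
                 matrix = mat, multi_ion = multi, times = traj$times),
            class = "site_occupancy")
}

#' Water co-permeation with ion events
#'
#' For each detected full-SF permeation event, counts the water molecules
#' whose own traces commit across the SF interval (while inside the SF
#' cylinder) within the event's time window plus a tolerance. A direct
#' knock-on event carries zero co-permeating waters; soft (water-mediated)
#' knock-on carries one or more.
#'
#' @param traj A [labeled_trajectory()].
#' @param pore A [pore_axis_model()].
#' @param events Event data.frame from [detect_all_events()] (interval
#'   `"SF_full"`).
#' @param margin Committed margin (A), as used for the ion events.
#' @param tolerance_ps Time tolerance around each event window (default
#'   1000 ps; SF exits complete within a few ns).
#' @param axis_xy Optional pore axis; default box centre.
#' @return List with `per_event` (the events plus a `n_waters` column)
#'   and `water_crossings` (data.frame of committed water crossings:
#'   water_id, entry_time, exit_time, direction).
#' @export
water_copermeation <- function(traj, pore, events, margin = 2,
                               tolerance_ps = 1000, axis_xy = NULL) {
  lm <- .pore_landmarks(pore)
  axis_xy <- .default_axis(traj, axis_xy)
  wats <- which(traj$system$role == "water_oxygen")
  crossings <- list()
  for (i in wats) {
    xyz_z <- .axis_z(pore, traj$coords[i, 3, ])
    r <- sqrt((traj$coords[i, 1, ] - axis_xy[, 1])^2 +
              (traj$coords[i, 2, ] - axis_xy[, 2])^2)
    inside <- r <= pore$sf_radius & xyz_z >= lm$z_sites[1] - margin &
      xyz_z <= lm$z_sites[6] + margin
    if (!any(inside)) next
    z_un <- unwrap_coordinate(xyz_z, traj$box[, 3])
    tr <- data.frame(frame = seq_along(z_un) - 1L, time_ps = traj$times,
                     z = xyz_z, z_unwrapped = z_un)
    attr(tr, "ion_id") <- traj$system$id[i]
    attr(tr, "stride_ps") <- frame_stride(traj)
    attr(tr, "box_z") <- stats::median(traj$box[, 3])
    ev <- detect_events(tr, pore, interval = "SF_full", margin = margin)
    if (!nrow(ev)) next
    ## require the water to be observed inside the SF cylinder both in
    ## the bottom (S4) and top (S0) site windows during the crossing: a
    ## water must pass through the filter, not merely span its z
    ## interval elsewhere in the box
    keep <- vapply(seq_len(nrow(ev)), function(k) {
      w <- (ev$entry_frame[k] + 1):(ev$exit_frame[k] + 1)
      any(inside[w] & xyz_z[w] < lm$z_sites[2]) &&
        any(inside[w] & xyz_z[w] >= lm$z_sites[5])
    }, logical(1))
    ev <- ev[keep, , drop = FALSE]
    if (nrow(ev)) {
      crossings[[length(crossings) + 1L]] <-
        data.frame(water_id = traj$system$id[i],
                   ev[, c("entry_time", "exit_time", "direction")])
    }
  }
  wc <- if (length(crossings)) do.call(rbind, crossings) else
    data.frame(water_id = integer(), entry_time = numeric(),
               exit_time = numeric(), direction = character())
  n_waters <- vapply(seq_len(nrow(events)), function(k) {
    sum(wc$exit_time >= events$entry_time[k] - tolerance_ps &
        wc$entry_time <= events$exit_time[k] + tolerance_ps)
  }, integer(1))
  per_event <- events
  per_event$n_waters <- if (nrow(events)) n_waters else integer(0)
  list(per_event = per_event, water_crossings = wc)
}

## gap contents between consecutive K symbols of one state string
.k_gap_symbols <- function(state) {
  s <- strsplit(state, "")[[1]]
  k <- which(s == "K")
  if (length(k) < 2) return(list())
  lapply(seq_len(length(k) - 1), function(j) {
    if (k[j + 1] - k[j] <= 1) character(0) else s[(k[j] + 1):(k[j + 1] - 1)]
  })
}

#' Classify the conduction mechanism of permeation events
#'
#' For each full-SF event the frames between entry and exit are examined:
#' the event is `direct_knock_on` when no frame ever shows a water symbol
#' between two ion symbols in the site-occupancy string and no water
#' co-permeates; `water_mediated` when every ion-ion gap in every
#' multi-ion frame contains a water; `mixed` otherwise.
#'
#' @param states A `site_occupancy` object from [assign_sites()].
#' @param events Event data.frame (interval `"SF_full"`), optionally with
#'   a `n_waters` column from [water_copermeation()] (assumed 0 if
#'   absent).
#' @return List with `calls` (the events plus `class` and `n_waters`)
#'   and `summary` (per-class counts and the fraction of direct events).
#' @export
classify_mechanism <- function(states, events) {
  stopifnot(inherits(states, "site_occupancy"))
  n_waters <- if (!is.null(events$n_waters)) events$n_waters else
    rep(0L, nrow(events))
  cls <- character(nrow(events))
  for (k in seq_len(nrow(events))) {
    fr <- (events$entry_frame[k] + 1):(events$exit_frame[k] + 1)
    fr <- fr[fr >= 1 & fr <= length(states$states)]
    gaps <- unlist(lapply(states$states[fr], function(st) {
      g <- .k_gap_symbols(st)
      if (!length(g)) return(NULL)
      vapply(g, function(x) any(x == "W"), logical(1))
    }))
    if (is.null(gaps) || !length(gaps)) {
      ## never two ions simultaneously in the filter during the window
      cls[k] <- if (n_waters[k] == 0) "direct_knock_on" else "water_mediated"
    } else if (!any(gaps) && n_waters[k] == 0) {
      cls[k] <- "direct_knock_on"
    } else if (all(gaps)) {
      cls[k] <- "water_mediated"
    } else {
      cls[k] <- "mixed"
    }
  }
  calls <- events
  calls$class <- cls
  calls$n_waters <- n_waters
  tab <- table(factor(cls, levels = c("direct_knock_on", "water_mediated",
                                      "mixed")))
  list(calls = calls,
       summary = data.frame(class = names(tab), n = as.integer(tab),
                            fraction = if (nrow(events)) as.numeric(tab) /
                              nrow(events) else NA_real_))
}

#' Per-site ion occupancy fractions
#'
#' Fraction of frames in which each SF site holds an ion. For the
#' fine-grained 0.5-A ion occupancy histogram along the whole pore use
#' [water_occupancy_map()] with `role = "ion"` and `bin_width = 0.5`, or
#' [occupancy_profile()].
#'
#' @param states A `site_occupancy` object from [assign_sites()].
#' @return Named numeric vector (S4..S0) of fractions in \[0, 1\].
#' @export
site_ion_occupancy_profile <- function(states) {
  stopifnot(inherits(states, "site_occupancy"))
  colMeans(states$matrix == "K")
}
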