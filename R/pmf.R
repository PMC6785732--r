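#' Ion occupancy profile along the pore
#'
#' Time-averaged number of ions per 0.5-A z slice between the
#' intracellular entrance and the extracellular end of the selectivity
#' filter, counting ions within `pore$pore_radius` of the pore axis. The
#' trajectory should be superposed on the selectivity filter first (see
#' [superpose()]) so that the pore frame of reference is fixed.
#'
#' @param traj A [labeled_trajectory()] (aligned at the SF).
#' @param pore A [pore_axis_model()].
#' @param bin_width Slice thickness in A (default 0.5).
#' @param z_range Optional two z values overriding the default range.
#' @param axis_xy Optional pore axis (`n_frames x 2`); default box centre.
#' @return List of class `occupancy_profile`: `z` (bin centres), `n`
#'   (mean ion count per slice), `bin_width`, `n_frames`.
#' @export
occupancy_profile <- function(traj, pore, bin_width = 0.5, z_range = NULL,
                              axis_xy = NULL) {
  m <- water_occupancy_map(traj, pore, z_range = z_range,
                           bin_width = bin_width, role = "ion",
                           axis_xy = axis_xy)
  if (!length(m$mids)) stop("empty z range for occupancy profile")
  structure(list(z = m$mids, n = colMeans(m$counts), bin_width = bin_width,
                 n_frames = nrow(m$counts)),
            class = "occupancy_profile")
}

#' Boltzmann inversion of an occupancy profile
#'
#' Converts a mean ion occupancy profile n(z) into an effective-biased
#' free-energy profile G(z) = -kT ln n(z), shifted so that its minimum is
#' zero. Because the occupancy is sampled under an applied field, the
#' profile contains the bias by construction (hence "effective-biased").
#' Bins with zero occupancy are masked rather than pseudo-counted: the
#' profile shows finite barriers only where sampling occurred.
#'
#' @param profile An `occupancy_profile` (or a bare numeric vector of
#'   occupancies, in which case `z` may be supplied).
#' @param temperature Temperature in K (default 310; kT = 0.616 kcal/mol).
#' @param z Bin centres when `profile` is a bare vector.
#' @return data.frame of class `pmf_profile` (z, n, G, masked) with
#'   attribute `kT`; `G` in kcal/mol, `NA` on masked bins.
#' @export
boltzmann_invert <- function(profile, temperature = 310, z = NULL) {
  if (inherits(profile, "occupancy_profile")) {
    n <- profile$n
    z <- profile$z
  } else {
    n <- as.numeric(profile)
    if (is.null(z)) z <- seq_along(n)
  }
  if (any(n < 0)) stop("occupancies must be >= 0")
  if (all(n == 0)) stop("all bins have zero occupancy; PMF undefined")
  kT <- kT_kcal(temperature)
  G <- ifelse(n > 0, -kT * log(n), NA_real_)
  G <- G - min(G, na.rm = TRUE)
  out <- data.frame(z = z, n = n, G = G, masked = n == 0)
  attr(out, "kT") <- kT
  class(out) <- c("pmf_profile", "data.frame")
  out
}

#' Aggregate per-run free-energy profiles
#'
#' Per-bin mean and sample standard deviation of G over runs, using only
#' runs in which the bin is unmasked; bins unmasked in fewer than two
#' runs carry `NA` statistics.
#'
#' @param profiles List of `pmf_profile` objects on identical z grids.
#' @return data.frame (z, mean_G, sd_G, n_runs).
#' @export
aggregate_runs <- function(profiles) {
  stopifnot(length(profiles) >= 2)
  z0 <- profiles[[1]]$z
  for (p in profiles) {
    if (length(p$z) != length(z0) || any(abs(p$z - z0) > 1e-9)) {
      stop("profiles are not on identical bin grids")
    }
  }
  Gm <- sapply(profiles, function(p) p$G)
  n_runs <- rowSums(!is.na(Gm))
  mean_G <- ifelse(n_runs >= 2, rowMeans(Gm, na.rm = TRUE), NA_real_)
  sd_G <- ifelse(n_runs >= 2, apply(Gm, 1, sd, na.rm = TRUE), NA_real_)
  data.frame(z = z0, mean_G = mean_G, sd_G = sd_G, n_runs = n_runs)
}
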