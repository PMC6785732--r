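#' Construct a labeled trajectory
#'
#' A labeled trajectory couples a static particle system with a
#' time-ordered stack of coordinate frames and per-frame box dimensions.
#' Coordinates are stored as an `n_atoms x 3 x n_frames` array in
#' Angstrom; times are in picoseconds.
#'
#' @param system A [pore_system()].
#' @param coords Numeric array `n_atoms x 3 x n_frames` (a single
#'   `n_atoms x 3` matrix is promoted to one frame).
#' @param times Numeric vector of frame times (ps), strictly increasing.
#' @param box Numeric vector of 3 box lengths (A), or an `n_frames x 3`
#'   matrix for a fluctuating box.
#' @return An object of class `labeled_trajectory`.
#' @export
labeled_trajectory <- function(system, coords, times, box) {
  stopifnot(inherits(system, "pore_system"))
  if (is.matrix(coords)) coords <- array(coords, dim = c(dim(coords), 1))
  stopifnot(length(dim(coords)) == 3, dim(coords)[2] == 3)
  n_frames <- dim(coords)[3]
  if (dim(coords)[1] != nrow(system)) {
    stop("coords has ", dim(coords)[1], " particles but system has ", nrow(system))
  }
  if (length(times) != n_frames) stop("length(times) != number of frames")
  if (n_frames > 1 && any(diff(times) <= 0)) {
    stop("frame times must be strictly increasing")
  }
  if (is.null(dim(box))) box <- matrix(box, nrow = n_frames, ncol = 3, byrow = TRUE)
  stopifnot(nrow(box) == n_frames, ncol(box) == 3, all(box > 0))
  structure(list(system = system, coords = coords,
                 times = as.numeric(times), box = box),
            class = "labeled_trajectory")
}

#' @export
print.labeled_trajectory <- function(x, ...) {
  cat("labeled_trajectory:", n_frames(x), "frames x", nrow(x$system),
      "particles; t =", x$times[1], "..", x$times[n_frames(x)],
      "ps (stride", frame_stride(x), "ps)\n")
  cat("  roles:", paste(names(table(x$system$role)),
                        table(x$system$role), collapse = ", "), "\n")
  invisible(x)
}

#' Number of frames in a trajectory
#' @param traj A [labeled_trajectory()].
#' @return Integer frame count.
#' @export
n_frames <- function(traj) dim(traj$coords)[3]

#' Time between stored frames (ps)
#'
#' Inferred from the first two frame times; a single-frame trajectory has
#' stride `NA`.
#' @param traj A [labeled_trajectory()].
#' @return Stride in ps.
#' @export
frame_stride <- function(traj) {
  if (n_frames(traj) < 2) return(NA_real_)
  traj$times[2] - traj$times[1]
}

#' Coordinates of one frame
#' @param traj A [labeled_trajectory()].
#' @param i Frame index.
#' @return `n_atoms x 3` matrix (A).
#' @export
frame_coords <- function(traj, i) traj$coords[, , i, drop = TRUE]

#' Subset a trajectory by frame index
#' @param traj A [labeled_trajectory()].
#' @param idx Frame indices (increasing).
#' @return A [labeled_trajectory()].
#' @export
subset_frames <- function(traj, idx) {
  labeled_trajectory(traj$system, traj$coords[, , idx, drop = FALSE],
                     traj$times[idx], traj$box[idx, , drop = FALSE])
}

## ---- columnar frame format -------------------------------------------------
## header: frame time_ps id x y z box_x box_y box_z, one row per particle
## per frame, whitespace-separated.

.read_frames_columnar <- function(path, system) {
  dt <- data.table::fread(path, header = TRUE)
  need <- c("frame", "time_ps", "id", "x", "y", "z", "box_x", "box_y", "box_z")
  if (!all(need %in% names(dt))) {
    stop("columnar frame file lacks column(s): ",
         paste(setdiff(need, names(dt)), collapse = ", "))
  }
  if (nrow(dt) == 0) stop("frame file '", path, "' contains no frames")
  data.table::setorderv(dt, c("time_ps", "id"))
  frame_ids <- unique(dt$frame)
  n_fr <- length(frame_ids)
  ids0 <- sort(system$id)
  per <- nrow(dt) / n_fr
  if (per != nrow(system)) {
    stop("frame file particles (", per, "/frame) do not match system (",
         nrow(system), ")")
  }
  missing_ids <- setdiff(ids0, dt$id[seq_len(per)])
  if (length(missing_ids)) {
    stop("frame file missing particle id(s): ",
         paste(head(missing_ids, 10), collapse = ", "))
  }
  times <- unique(dt$time_ps)
  if (length(times) != n_fr) stop("inconsistent frame/time pairing")
  ord <- match(system$id, dt$id[seq_len(per)])
  coords <- array(NA_real_, dim = c(nrow(system), 3, n_fr))
  xm <- matrix(dt$x, nrow = per)
  ym <- matrix(dt$y, nrow = per)
  zm <- matrix(dt$z, nrow = per)
  coords[, 1, ] <- xm[ord, ]
  coords[, 2, ] <- ym[ord, ]
  coords[, 3, ] <- zm[ord, ]
  box <- cbind(dt$box_x[seq(1, nrow(dt), by = per)],
               dt$box_y[seq(1, nrow(dt), by = per)],
               dt$box_z[seq(1, nrow(dt), by = per)])
  labeled_trajectory(system, coords, times, box)
}

.read_frames_pdb <- function(path, system, stride) {
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  xyz <- pdb$xyz
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1)
  n_fr <- nrow(xyz)
  if (n_fr == 0) stop("no MODEL records in '", path, "'")
  ids <- pdb$atom$eleno
  idx <- match(system$id, ids)
  if (anyNA(idx)) {
    stop("PDB frames missing particle id(s): ",
         paste(head(system$id[is.na(idx)], 10), collapse = ", "))
  }
  coords <- array(NA_real_, dim = c(nrow(system), 3, n_fr))
  for (f in seq_len(n_fr)) {
    m <- matrix(xyz[f, ], ncol = 3, byrow = TRUE)
    coords[, , f] <- m[idx, ]
  }
  box <- .read_cryst1(path)
  if (is.null(box)) {
    box <- apply(coords, 2, max) - apply(coords, 2, min) + 1
  }
  labeled_trajectory(system, coords, times = (seq_len(n_fr) - 1) * stride, box = box)
}

.read_cryst1 <- function(path) {
  ln <- grep("^CRYST1", readLines(path, n = 2000), value = TRUE)
  if (!length(ln)) return(NULL)
  as.numeric(c(substr(ln[1], 7, 15), substr(ln[1], 16, 24), substr(ln[1], 25, 33)))
}

#' Read trajectory frames
#'
#' Reads frames from either the whitespace-separated columnar format
#' (header `frame time_ps id x y z box_x box_y box_z`) or a multi-model
#' PDB. Frames are sorted by time; the stride is inferred from the first
#' two frames. Multi-model PDB carries no time stamps, so frame `k` is
#' assigned time `(k-1) * stride`.
#'
#' @param path Frame file.
#' @param system The [pore_system()] the frames belong to; particle ids
#'   must match.
#' @param format `"auto"` (by extension), `"columnar"` or `"pdb"`.
#' @param stride Frame spacing in ps used for multi-model PDB input
#'   (default 20 ps, the usual coordinate-output interval for channel
#'   permeation runs).
#' @return A [labeled_trajectory()].
#' @export
read_frames <- function(path, system, format = c("auto", "columnar", "pdb"),
                        stride = 20) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.pdb$", path, ignore.case = TRUE)) "pdb" else "columnar"
  }
  switch(format,
         columnar = .read_frames_columnar(path, system),
         pdb = .read_frames_pdb(path, system, stride))
}

#' Write trajectory frames
#'
#' The columnar format round-trips exactly; PDB output is limited to the
#' format's fixed 3-decimal coordinate precision and requires uniformly
#' spaced frames (times are implicit in the model order).
#'
#' @param traj A [labeled_trajectory()].
#' @param path Output file.
#' @param format `"columnar"` or `"pdb"`.
#' @return `path`, invisibly.
#' @export
write_frames <- function(traj, path, format = c("columnar", "pdb")) {
  format <- tryCatch(match.arg(format),
                     error = function(e) stop("unsupported frame format: ",
                                              format[1], call. = FALSE))
  if (format == "columnar") {
    n_at <- nrow(traj$system)
    n_fr <- n_frames(traj)
    dt <- data.table::data.table(
      frame = rep(seq_len(n_fr) - 1L, each = n_at),
      time_ps = rep(traj$times, each = n_at),
      id = rep(traj$system$id, n_fr),
      x = as.vector(traj$coords[, 1, ]),
      y = as.vector(traj$coords[, 2, ]),
      z = as.vector(traj$coords[, 3, ]),
      box_x = rep(traj$box[, 1], each = n_at),
      box_y = rep(traj$box[, 2], each = n_at),
      box_z = rep(traj$box[, 3], each = n_at)
    )
    data.table::fwrite(dt, path, sep = " ")
  } else {
    if (n_frames(traj) > 1 && length(unique(round(diff(traj$times), 9))) != 1) {
      stop("PDB output requires uniformly spaced frames")
    }
    .write_frames_pdb(traj, path)
  }
  invisible(path)
}

.write_frames_pdb <- function(traj, path) {
  sys <- traj$system
  xyz <- do.call(rbind, lapply(seq_len(n_frames(traj)), function(f) {
    as.vector(t(frame_coords(traj, f)))
  }))
  resid <- ifelse(is.na(sys$resname), "UNK", sys$resname)
  chain <- ifelse(is.na(sys$subunit), "", sys$subunit)
  resno <- ifelse(is.na(sys$resno), 1L, sys$resno)
  elety <- ifelse(is.na(sys$atom), "X", sys$atom)
  tmp <- tempfile(fileext = ".pdb")
  on.exit(unlink(tmp))
  con <- file(path, "w")
  on.exit(close(con), add = TRUE)
  b <- traj$box[1, ]
  writeLines(sprintf("CRYST1%9.3f%9.3f%9.3f  90.00  90.00  90.00 P 1           1",
                     b[1], b[2], b[3]), con)
  for (f in seq_len(nrow(xyz))) {
    bio3d::write.pdb(file = tmp, xyz = xyz[f, ], resno = resno, resid = resid,
                     eleno = sys$id, elety = elety, chain = chain, end = FALSE)
    writeLines(sprintf("MODEL     %4d", f), con)
    writeLines(readLines(tmp), con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
}

## frame-slice of the coordinate array as a plain n x 3 matrix
.fcoords <- function(traj, idx, f) matrix(traj$coords[idx, , f], ncol = 3)

#' Unwrap a periodic coordinate series
#'
#' Minimum-image unwrapping along one axis: successive displacements
#' larger than half the box are treated as periodic jumps and removed, so
#' an ion crossing the box boundary keeps a continuous trace.
#'
#' @param z Numeric vector of wrapped positions (A).
#' @param box_z Box length along the axis (A), scalar or per-frame vector.
#' @return Numeric vector of unwrapped positions.
#' @export
unwrap_coordinate <- function(z, box_z) {
  if (length(z) < 2) return(z)
  if (length(box_z) == 1) box_z <- rep(box_z, length(z))
  dz <- diff(z)
  jump <- round(dz / box_z[-1])
  z + c(0, cumsum(-jump * box_z[-1]))
}
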