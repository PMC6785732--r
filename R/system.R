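## Particle roles recognised throughout the package.
.roles <- c("protein", "ion", "water_oxygen", "water_hydrogen", "lipid", "other")

.aa3 <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS",
          "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP",
          "TYR", "VAL", "HSD", "HSE", "HSP", "HID", "HIE", "HIP")
.ion_res <- c("K", "K+", "POT", "NA", "NA+", "SOD", "CL", "CL-", "CLA")
.water_res <- c("HOH", "SOL", "WAT", "TIP", "TIP3", "TIP4", "TIP5", "SPC")
.lipid_res <- c("POPC", "POPE", "POPG", "PIP", "PIP2", "DPPC", "DOPC", "CHL")

#' Construct a particle system
#'
#' A particle system is the static topology shared by every frame of a
#' trajectory: one row per particle with an id, a role (protein, ion,
#' water_oxygen, water_hydrogen, lipid, other), and for protein particles
#' a subunit label (A-D for a tetrameric channel), residue number, residue
#' name and atom name.
#'
#' @param df data.frame with columns `id`, `role`, `subunit`, `resno`,
#'   `resname`, `atom`, `element` (missing label columns are filled with
#'   `NA`).
#' @return A `pore_system` data.frame.
#' @export
pore_system <- function(df) {
  stopifnot(is.data.frame(df), all(c("id", "role") %in% names(df)))
  for (col in c("subunit", "resname", "atom", "element")) {
    if (is.null(df[[col]])) df[[col]] <- rep(NA_character_, nrow(df))
  }
  if (is.null(df$resno)) df$resno <- rep(NA_integer_, nrow(df))
  df$id <- as.integer(df$id)
  if (anyDuplicated(df$id)) stop("particle ids must be unique")
  bad <- !df$role %in% .roles
  if (any(bad)) {
    stop("unknown particle role(s): ", paste(unique(df$role[bad]), collapse = ", "))
  }
  df <- df[, c("id", "role", "subunit", "resno", "resname", "atom", "element")]
  class(df) <- c("pore_system", "data.frame")
  df
}

.role_from_resname <- function(resname, atom) {
  resname <- toupper(trimws(resname))
  role <- rep(NA_character_, length(resname))
  is_water <- resname %in% .water_res | substr(resname, 1, 3) %in% c("TIP", "SPC")
  role[is_water & grepl("^O", atom)] <- "water_oxygen"
  role[is_water & grepl("^H", atom)] <- "water_hydrogen"
  role[is_water & is.na(role)] <- "water_oxygen"
  role[resname %in% .ion_res] <- "ion"
  role[resname %in% .aa3] <- "protein"
  role[resname %in% .lipid_res] <- "lipid"
  role
}

#' Read a PDB topology into a particle system
#'
#' Parses ATOM/HETATM records (via bio3d) and assigns particle roles from
#' residue-name rules: K/POT become ions, HOH/SOL/TIP/SPC waters, the 20
#' standard amino acids protein, common phospholipids lipid. Unknown
#' residues are kept with role `other` and a warning. PDB chain
#' identifiers map positionally to subunits A-D.
#'
#' @param path Path to a PDB file (first MODEL used if multi-model).
#' @return A [pore_system()] data.frame.
#' @export
read_topology <- function(path) {
  pdb <- tryCatch(
    suppressWarnings(bio3d::read.pdb(path, verbose = FALSE)),
    error = function(e) stop("failed to parse PDB '", path, "': ",
                             conditionMessage(e), call. = FALSE)
  )
  at <- pdb$atom
  if (is.null(at) || nrow(at) == 0) {
    stop("failed to parse PDB '", path, "': no ATOM/HETATM records",
         call. = FALSE)
  }
  role <- .role_from_resname(at$resid, at$elety)
  unknown <- is.na(role)
  if (any(unknown)) {
    warning("unknown residue name(s) ",
            paste(unique(at$resid[unknown]), collapse = ", "),
            "; assigned role 'other'")
    role[unknown] <- "other"
  }
  element <- at$elesy
  if (is.null(element) || all(is.na(element) | element == "")) {
    element <- substr(trimws(at$elety), 1, 1)
  }
  pore_system(data.frame(
    id = at$eleno,
    role = role,
    subunit = ifelse(is.na(at$chain) | at$chain == "", NA_character_, at$chain),
    resno = at$resno,
    resname = trimws(at$resid),
    atom = trimws(at$elety),
    element = trimws(element),
    stringsAsFactors = FALSE
  ))
}

#' Particle selections
#'
#' A selection is a deterministic predicate over particle fields. All
#' given constraints must hold (logical AND); each constraint accepts a
#' vector of admissible values.
#'
#' @param role,subunit,resno,resname,atom,element Admissible values for
#'   the corresponding particle field, or `NULL` for no constraint.
#' @return An object of class `particle_selection`.
#' @seealso [parse_selection()] for the string form used by configs.
#' @examples
#' sel(role = "protein", subunit = "A", resno = 319, atom = "CA")
#' @export
sel <- function(role = NULL, subunit = NULL, resno = NULL, resname = NULL,
                atom = NULL, element = NULL) {
  s <- list(role = role, subunit = subunit,
            resno = if (is.null(resno)) NULL else as.integer(resno),
            resname = resname, atom = atom, element = element)
  s <- s[!vapply(s, is.null, logical(1))]
  structure(s, class = "particle_selection")
}

#' Parse a selection string
#'
#' Accepts the compact form used in configuration files, e.g.
#' `"role:protein subunit:A resid:319 name:CA"`. Values may be
#' comma-separated lists; `resid` additionally accepts ranges
#' (`resid:316-320`). Recognised keys: role, subunit, resid (or resno),
#' resname, name (or atom), element.
#'
#' @param text Selection string.
#' @return A [sel()] object.
#' @export
parse_selection <- function(text) {
  stopifnot(is.character(text), length(text) == 1)
  parts <- strsplit(trimws(text), "\\s+")[[1]]
  parts <- parts[nzchar(parts)]
  args <- list()
  for (p in parts) {
    kv <- strsplit(p, ":", fixed = TRUE)[[1]]
    if (length(kv) != 2) stop("malformed selection token '", p, "'")
    key <- c(role = "role", subunit = "subunit", resid = "resno",
             resno = "resno", resname = "resname", name = "atom",
             atom = "atom", element = "element")[kv[1]]
    if (is.na(key)) stop("unknown selection key '", kv[1], "'")
    vals <- strsplit(kv[2], ",", fixed = TRUE)[[1]]
    if (key == "resno") {
      vals <- unlist(lapply(vals, function(v) {
        if (grepl("-", v, fixed = TRUE)) {
          rng <- as.integer(strsplit(v, "-", fixed = TRUE)[[1]])
          seq(rng[1], rng[2])
        } else as.integer(v)
      }))
    }
    args[[key]] <- c(args[[key]], vals)
  }
  do.call(sel, args)
}

#' Resolve a selection to particle row indices
#'
#' @param system A [pore_system()].
#' @param selection A [sel()] object, a selection string (parsed with
#'   [parse_selection()]), or an integer vector of particle ids.
#' @return Integer vector of row indices into `system` (stable order).
#' @export
resolve_selection <- function(system, selection) {
  if (is.numeric(selection)) {
    idx <- match(as.integer(selection), system$id)
    if (anyNA(idx)) {
      stop("unknown particle id(s): ",
           paste(selection[is.na(idx)], collapse = ", "))
    }
    return(idx)
  }
  if (is.character(selection)) selection <- parse_selection(selection)
  stopifnot(inherits(selection, "particle_selection"))
  keep <- rep(TRUE, nrow(system))
  for (field in names(selection)) {
    keep <- keep & (system[[field]] %in% selection[[field]])
  }
  which(keep)
}
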