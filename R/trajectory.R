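# Trajectory container and file formats (multi-frame PDB, XYZ + JSON roster).
#
# A trajectory is a fixed particle roster plus a coordinate array. Particles
# are coarse beads: one backbone reference bead per residue (PDB atom name
# CA) and optionally one charge-site bead (atom name CB) carrying the sign
# of the side-chain charge. The sign rides in the B-factor column (+1 / -1 /
# 0), chains A/B/C are the chaperone, any other chain id is a substrate
# peptide. PDB coordinates are written at the standard 0.001 A precision;
# the XYZ writer keeps 1e-6 A.

#' Construct a trajectory
#'
#' @param roster data.frame with columns `entity` ("skp"/"peptide"),
#'   `chain`, `resno` (1-based), `resname` (3-letter), `role`
#'   ("backbone_ref"/"charge_site"), `sign` (-1, 0, +1); one row per bead.
#' @param coords numeric array `n_beads x 3 x n_frames`.
#' @param frame_time per-frame times (ns) or frame indices; defaults to
#'   `1:n_frames`.
#' @return object of class `skp_trajectory`.
#' @export
trajectory <- function(roster, coords, frame_time = NULL) {
  need <- c("entity", "chain", "resno", "resname", "role", "sign")
  if (!all(need %in% names(roster)))
    stop("roster must have columns ", paste(need, collapse = ", "))
  if (length(dim(coords)) != 3 || dim(coords)[2] != 3)
    stop("coords must be an n_beads x 3 x n_frames array")
  if (dim(coords)[1] != nrow(roster))
    stop("coords first dimension must match roster rows")
  if (any(!is.finite(coords))) stop("non-finite coordinates in trajectory")
  if (!all(roster$entity %in% c("skp", "peptide")))
    stop("entity must be 'skp' or 'peptide'")
  if (!all(roster$role %in% c("backbone_ref", "charge_site")))
    stop("role must be 'backbone_ref' or 'charge_site'")
  n_frames <- dim(coords)[3]
  if (is.null(frame_time)) frame_time <- seq_len(n_frames)
  if (length(frame_time) != n_frames)
    stop("frame_time length must equal the number of frames")
  roster$resno <- as.integer(roster$resno)
  roster$sign <- as.integer(roster$sign)
  rownames(roster) <- NULL
  structure(list(roster = roster, coords = coords,
                 frame_time = as.numeric(frame_time)),
            class = "skp_trajectory")
}

#' @export
print.skp_trajectory <- function(x, ...) {
  cat(sprintf(
    "<skp_trajectory> %d frames, %d beads (%d chaperone, %d peptide)\n",
    n_frames(x), nrow(x$roster), sum(x$roster$entity == "skp"),
    sum(x$roster$entity == "peptide")))
  invisible(x)
}

#' Number of frames in a trajectory
#' @param traj an [trajectory()].
#' @return integer.
#' @export
n_frames <- function(traj) dim(traj$coords)[3]

#' Coordinates of one frame
#' @param traj an [trajectory()].
#' @param frame frame index.
#' @return `n_beads x 3` matrix.
#' @export
frame_coords <- function(traj, frame) {
  stopifnot(frame >= 1, frame <= n_frames(traj))
  traj$coords[, , frame, drop = TRUE]
}

# bead ids used for roster-consistency checks and file round trips
.bead_ids <- function(roster) {
  paste(roster$chain, roster$resno,
        ifelse(roster$role == "backbone_ref", "CA", "CB"), sep = "/")
}

# ---- multi-frame PDB -----------------------------------------------------

#' Write a trajectory as a multi-frame PDB (MODEL/ENDMDL)
#'
#' @param traj an [trajectory()].
#' @param path output `.pdb` file.
#' @return `path`, invisibly.
#' @export
write_trajectory_pdb <- function(traj, path) {
  stopifnot(inherits(traj, "skp_trajectory"))
  r <- traj$roster
  name <- ifelse(r$role == "backbone_ref", "CA", "CB")
  con <- file(path, "w"); on.exit(close(con))
  for (f in seq_len(n_frames(traj))) {
    X <- frame_coords(traj, f)
    writeLines(sprintf("MODEL     %4d", f), con)
    writeLines(sprintf(
      "ATOM  %5d %4s %3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f",
      seq_len(nrow(r)), name, r$resname, r$chain, r$resno,
      X[, 1], X[, 2], X[, 3], 1, r$sign), con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

# Frame-by-frame roster consistency scan of a PDB file; errors name the
# offending frame and particle before the heavier parser runs.
.check_pdb_roster <- function(path) {
  lines <- readLines(path)
  model_starts <- grep("^MODEL", lines)
  if (length(model_starts) == 0) return(invisible(TRUE))
  ends <- grep("^ENDMDL", lines)
  if (length(ends) != length(model_starts))
    stop("unbalanced MODEL/ENDMDL records in ", path)
  ids <- lapply(seq_along(model_starts), function(i) {
    block <- lines[model_starts[i]:ends[i]]
    al <- block[grepl("^ATOM  |^HETATM", block)]
    paste(trimws(substr(al, 22, 22)), trimws(substr(al, 23, 26)),
          trimws(substr(al, 13, 16)), sep = "/")
  })
  ref <- ids[[1]]
  for (i in seq_along(ids)[-1]) {
    if (length(ids[[i]]) != length(ref) || !all(ids[[i]] == ref)) {
      missing <- setdiff(ref, ids[[i]])
      extra <- setdiff(ids[[i]], ref)
      stop(sprintf(
        "particle roster mismatch at frame %d: %s%s", i,
        if (length(missing)) paste("missing", missing[1]) else "",
        if (length(extra)) paste(" unexpected", extra[1]) else ""))
    }
  }
  invisible(TRUE)
}

#' Read a multi-frame PDB trajectory
#'
#' Uses \pkg{bio3d}'s multi-model PDB parser after a frame-roster
#' consistency scan. Chains A/B/C are assigned to the chaperone, any other
#' chain to the peptide; atom name CA marks the backbone reference bead, CB
#' a charge-site bead whose sign is read from the B-factor column.
#'
#' @param path `.pdb` file.
#' @return an [trajectory()].
#' @export
read_trajectory_pdb <- function(path) {
  .check_pdb_roster(path)
  p <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  at <- p$atom
  if (any(!at$elety %in% c("CA", "CB")))
    stop("unsupported atom name in ", path,
         " (expected CA backbone beads and CB charge beads)")
  chain <- at$chain
  if (anyNA(chain)) stop("missing chain identifiers in ", path)
  roster <- data.frame(
    entity = ifelse(chain %in% c("A", "B", "C"), "skp", "peptide"),
    chain = chain,
    resno = at$resno,
    resname = at$resid,
    role = ifelse(at$elety == "CA", "backbone_ref", "charge_site"),
    sign = as.integer(round(at$b)),
    stringsAsFactors = FALSE)
  nf <- nrow(p$xyz)
  coords <- array(NA_real_, c(nrow(roster), 3, nf))
  for (f in seq_len(nf))
    coords[, , f] <- matrix(p$xyz[f, ], ncol = 3, byrow = TRUE)
  trajectory(roster, coords)
}

# ---- XYZ + JSON sidecar --------------------------------------------------

.sidecar_path <- function(path)
  paste0(tools::file_path_sans_ext(path), ".roster.json")

#' Write a trajectory as XYZ plus a JSON roster sidecar
#'
#' The `.xyz` file holds per-frame blocks (bead name, x, y, z); the sidecar
#' `<stem>.roster.json` carries entity/chain/residue/role/sign for each bead
#' and the frame times.
#'
#' @param traj an [trajectory()].
#' @param path output `.xyz` file.
#' @return `path`, invisibly.
#' @export
write_trajectory_xyz <- function(traj, path) {
  stopifnot(inherits(traj, "skp_trajectory"))
  r <- traj$roster
  name <- ifelse(r$role == "backbone_ref", "CA", "CB")
  con <- file(path, "w"); on.exit(close(con))
  for (f in seq_len(n_frames(traj))) {
    X <- frame_coords(traj, f)
    writeLines(as.character(nrow(r)), con)
    writeLines(sprintf("frame %d time %.6f", f, traj$frame_time[f]), con)
    writeLines(sprintf("%-2s %.6f %.6f %.6f", name, X[, 1], X[, 2], X[, 3]),
               con)
  }
  jsonlite::write_json(
    list(atoms = r, frame_time = traj$frame_time),
    .sidecar_path(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read an XYZ + JSON sidecar trajectory
#'
#' @param path `.xyz` file written by [write_trajectory_xyz()]; the sidecar
#'   `<stem>.roster.json` must sit next to it.
#' @return an [trajectory()].
#' @export
read_trajectory_xyz <- function(path) {
  side <- .sidecar_path(path)
  if (!file.exists(side)) stop("missing roster sidecar ", side)
  meta <- jsonlite::read_json(side, simplifyVector = TRUE)
  roster <- as.data.frame(meta$atoms, stringsAsFactors = FALSE)
  lines <- readLines(path)
  n <- nrow(roster)
  block <- n + 2
  if (length(lines) %% block != 0)
    stop("XYZ file length inconsistent with roster size: ", path)
  nf <- length(lines) %/% block
  coords <- array(NA_real_, c(n, 3, nf))
  for (f in seq_len(nf)) {
    off <- (f - 1) * block
    cnt <- suppressWarnings(as.integer(trimws(lines[off + 1])))
    if (is.na(cnt) || cnt != n)
      stop(sprintf("frame %d declares %s particles, roster has %d",
                   f, lines[off + 1], n))
    body <- lines[(off + 3):(off + block)]
    parts <- do.call(rbind, strsplit(trimws(body), "\\s+"))
    coords[, , f] <- apply(parts[, 2:4, drop = FALSE], 2, as.numeric)
  }
  trajectory(roster, coords, frame_time = meta$frame_time)
}

#' Read / write a trajectory, dispatching on format
#'
#' @param path file path; format inferred from the extension (`.pdb` or
#'   `.xyz`) when `format = "auto"`.
#' @param format `"auto"`, `"pdb"` or `"xyz"`.
#' @return [read_trajectory()]: an [trajectory()].
#' @export
read_trajectory <- function(path, format = c("auto", "pdb", "xyz")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- switch(tolower(tools::file_ext(path)),
                     pdb = "pdb", xyz = "xyz",
                     stop("cannot infer trajectory format from ", path))
  if (format == "pdb") read_trajectory_pdb(path) else read_trajectory_xyz(path)
}

#' @rdname read_trajectory
#' @param traj an [trajectory()].
#' @export
write_trajectory <- function(traj, path, format = c("auto", "pdb", "xyz")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- switch(tolower(tools::file_ext(path)),
                     pdb = "pdb", xyz = "xyz",
                     stop("cannot infer trajectory format from ", path))
  if (format == "pdb") write_trajectory_pdb(traj, path)
  else write_trajectory_xyz(traj, path)
}
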