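#' Trajectory container
#'
#' A `pore_trajectory` couples an atom/particle table with per-frame
#' coordinates. Coordinates are in Angstrom; frames are 0-based (the first
#' frame is frame 0).
#'
#' @param atoms Atom table as for [channel_model()] (chain may be constant
#'   for solvent-only trajectories).
#' @param coords Numeric array `n_atoms x 3 x n_frames` (Angstrom).
#' @param box Optional box vector `c(Lx, Ly, Lz)` in Angstrom (used for
#'   periodic unwrapping along the channel axis).
#' @param dt Optional time between frames (ps); purely a label.
#' @return Object of class `pore_trajectory`.
#' @export
pore_trajectory <- function(atoms, coords, box = NULL, dt = NA_real_) {
  stopifnot(length(dim(coords)) == 3, dim(coords)[2] == 3)
  if (nrow(atoms) != dim(coords)[1]) {
    stop("atom table and coordinate array disagree on atom count")
  }
  structure(
    list(atoms = atoms, coords = coords, box = box, dt = dt),
    class = "pore_trajectory"
  )
}

#' @export
print.pore_trajectory <- function(x, ...) {
  cat("pore_trajectory:", dim(x$coords)[1], "atoms,", n_frames(x),
      "frames\n")
  invisible(x)
}

#' Number of frames in a trajectory
#' @param traj A `pore_trajectory`.
#' @return Integer frame count.
#' @export
n_frames <- function(traj) {
  dim(traj$coords)[3]
}

#' Coordinates of one frame
#' @param traj A `pore_trajectory`.
#' @param frame 0-based frame index.
#' @return `n_atoms x 3` matrix (Angstrom).
#' @export
frame_coords <- function(traj, frame) {
  if (frame < 0 || frame >= n_frames(traj)) {
    stop("frame index ", frame, " out of range [0, ", n_frames(traj) - 1, "]")
  }
  fc <- traj$coords[, , frame + 1]
  if (is.null(dim(fc))) {
    fc <- matrix(fc, ncol = 3)
  }
  fc
}

#' Read a multi-frame (multi-model) PDB trajectory
#'
#' Parsed with \pkg{bio3d}; all models must share the atom roster of the
#' first.
#'
#' @param path Multi-model PDB path.
#' @param box Optional box vector (Angstrom); PDB CRYST1 is used if present.
#' @return A `pore_trajectory`.
#' @export
read_trajectory_pdb <- function(path, box = NULL) {
  pdb <- tryCatch(
    bio3d::read.pdb(path, multi = TRUE, verbose = FALSE),
    error = function(e) stop("failed to parse trajectory PDB '", path, "': ",
                             conditionMessage(e))
  )
  a <- pdb$atom
  chain <- a$chain
  chain[is.na(chain) | chain == ""] <- "A"
  atoms <- data.frame(
    eleno = a$eleno, name = trimws(a$elety), resid = trimws(a$resid),
    resno = a$resno, chain = chain,
    x = a$x, y = a$y, z = a$z, stringsAsFactors = FALSE
  )
  el <- trimws(a$elesy)
  atoms$elem <- ifelse(is.na(el) | el == "", .infer_element(atoms$name),
                       toupper(el))
  nfr <- nrow(pdb$xyz)
  nat <- nrow(atoms)
  coords <- array(NA_real_, c(nat, 3, nfr))
  for (f in seq_len(nfr)) {
    coords[, , f] <- matrix(pdb$xyz[f, ], ncol = 3, byrow = TRUE)
  }
  if (is.null(box)) {
    cry <- grep("^CRYST1", readLines(path, n = 50), value = TRUE)
    if (length(cry) > 0) {
      box <- as.numeric(c(substr(cry[1], 7, 15), substr(cry[1], 16, 24),
                          substr(cry[1], 25, 33)))
    }
  }
  pore_trajectory(atoms, coords, box = box)
}

#' Write a multi-frame (multi-model) PDB trajectory
#'
#' @param traj A `pore_trajectory`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_trajectory_pdb <- function(traj, path) {
  a <- traj$atoms
  nfr <- n_frames(traj)
  xyz <- matrix(NA_real_, nrow = nfr, ncol = nrow(a) * 3)
  for (f in seq_len(nfr)) {
    xyz[f, ] <- as.numeric(t(traj$coords[, , f]))
  }
  bio3d::write.pdb(
    file = path, xyz = xyz,
    resno = a$resno, resid = a$resid, eleno = a$eleno,
    elety = a$name, chain = a$chain
  )
  if (!is.null(traj$box)) {
    # prepend a CRYST1 record so the box survives the round trip
    lines <- readLines(path)
    cry <- sprintf("CRYST1%9.3f%9.3f%9.3f%7.2f%7.2f%7.2f P 1           1",
                   traj$box[1], traj$box[2], traj$box[3], 90, 90, 90)
    writeLines(c(cry, lines), path)
  }
  invisible(path)
}

#' Select atom indices from a trajectory or model
#'
#' Simple declarative selection on the atom table.
#'
#' @param x A `pore_trajectory` or `channel_model`.
#' @param resid Residue name(s) to keep (e.g. `"SOL"`, `"CL"`).
#' @param name Atom name(s) to keep (e.g. `"OW"`, `"CA"`).
#' @param chain Chain/subunit id(s) to keep.
#' @param elem Element(s) to keep.
#' @return Integer vector of 1-based atom row indices.
#' @export
select_atoms <- function(x, resid = NULL, name = NULL, chain = NULL,
                         elem = NULL) {
  a <- x$atoms
  keep <- rep(TRUE, nrow(a))
  if (!is.null(resid)) keep <- keep & a$resid %in% resid
  if (!is.null(name)) keep <- keep & a$name %in% name
  if (!is.null(chain)) keep <- keep & a$chain %in% chain
  if (!is.null(elem)) keep <- keep & a$elem %in% elem
  which(keep)
}
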