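# Core containers: Structure (a topology with one set of coordinates) and
# Trajectory (a topology plus F frames of coordinates). Author residue
# numbering from the PDB columns is the single numbering used everywhere.

#' Construct a Structure
#'
#' @param atoms data.frame with columns \code{serial}, \code{atom_name},
#'   \code{residue_name}, \code{chain_id}, \code{residue_number},
#'   \code{element}, \code{alt_loc}, \code{hetatm}.
#' @param xyz numeric A x 3 matrix of coordinates, Angstrom.
#' @param source character label recording where the structure came from.
#' @param model model number the coordinates belong to.
#' @return an object of class \code{trn_structure}.
#' @export
new_structure <- function(atoms, xyz, source = "memory", model = 1L) {
  atoms <- as.data.frame(atoms, stringsAsFactors = FALSE)
  needed <- c("serial", "atom_name", "residue_name", "chain_id",
              "residue_number", "element", "alt_loc", "hetatm")
  missing_cols <- setdiff(needed, names(atoms))
  if (length(missing_cols))
    stop("new_structure: atoms table lacks columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  xyz <- as.matrix(xyz)
  if (nrow(atoms) != nrow(xyz) || ncol(xyz) != 3L)
    stop("new_structure: xyz must be an A x 3 matrix matching atoms",
         call. = FALSE)
  if (!all(is.finite(xyz)))
    stop("new_structure: coordinates must be finite", call. = FALSE)
  if (any(!nzchar(atoms$element)))
    stop("new_structure: every atom needs a non-empty element", call. = FALSE)
  key <- atom_key_string(atoms)
  dup <- duplicated(key)
  if (any(dup))
    stop("new_structure: duplicate atom key(s): ",
         paste(unique(key[dup]), collapse = "; "), call. = FALSE)
  rownames(atoms) <- NULL
  dimnames(xyz) <- NULL
  structure(list(atoms = atoms, xyz = xyz,
                 source = source, model = as.integer(model)),
            class = "trn_structure")
}

atom_key_string <- function(atoms) {
  paste(atoms$chain_id, atoms$residue_number, atoms$atom_name,
        ifelse(is.na(atoms$alt_loc) | atoms$alt_loc == "", "-", atoms$alt_loc),
        sep = ":")
}

#' Number of atoms in a structure
#' @param struct a \code{trn_structure}.
#' @return integer atom count.
#' @export
n_atoms <- function(struct) {
  stopifnot(inherits(struct, "trn_structure"))
  nrow(struct$atoms)
}

#' @export
print.trn_structure <- function(x, ...) {
  cat(sprintf("Structure [%s, model %d]: %d atoms, %d residues, chains: %s\n",
              x$source, x$model, nrow(x$atoms),
              length(unique(paste(x$atoms$chain_id, x$atoms$residue_number))),
              paste(sort(unique(x$atoms$chain_id)), collapse = " ")))
  invisible(x)
}

#' Look up one atom by its key
#'
#' The key (chain, residue number, atom name) identifies at most one atom.
#'
#' @param struct a \code{trn_structure}.
#' @param chain chain identifier (single character).
#' @param resno author residue number.
#' @param name PDB atom name, e.g. "CA", "OE1".
#' @param required error (rather than return NA) when the atom is absent.
#' @return integer index into the topology, or NA when absent and not required.
#' @export
find_atom <- function(struct, chain, resno, name, required = FALSE) {
  stopifnot(inherits(struct, "trn_structure"))
  a <- struct$atoms
  idx <- which(a$chain_id == chain & a$residue_number == resno &
                 a$atom_name == name)
  if (length(idx) == 0L) {
    if (required)
      stop(sprintf("atom %s not found (chain %s, residue %d)",
                   name, chain, as.integer(resno)), call. = FALSE)
    return(NA_integer_)
  }
  idx[1L]
}

#' Construct a Trajectory
#'
#' @param topology a \code{trn_structure} giving atom identities and order.
#' @param coords numeric array of dimension F x A x 3 (frames, atoms, xyz),
#'   Angstrom. A single A x 3 matrix is promoted to one frame.
#' @param times optional per-frame times in nanoseconds; strictly increasing.
#' @return an object of class \code{trn_trajectory}.
#' @export
new_trajectory <- function(topology, coords, times = NULL) {
  stopifnot(inherits(topology, "trn_structure"))
  if (is.matrix(coords)) coords <- array(coords, c(1L, dim(coords)))
  d <- dim(coords)
  if (length(d) != 3L || d[3L] != 3L)
    stop("new_trajectory: coords must be an F x A x 3 array", call. = FALSE)
  if (d[2L] != nrow(topology$atoms))
    stop("new_trajectory: coords atom count does not match topology",
         call. = FALSE)
  if (d[1L] < 1L)
    stop("new_trajectory: need at least one frame", call. = FALSE)
  if (!all(is.finite(coords)))
    stop("new_trajectory: coordinates must be finite", call. = FALSE)
  if (!is.null(times)) {
    if (length(times) != d[1L] || any(diff(times) <= 0))
      stop("new_trajectory: times must be strictly increasing, one per frame",
         call. = FALSE)
  }
  structure(list(topology = topology, coords = coords, times = times),
            class = "trn_trajectory")
}

#' Number of frames in a trajectory
#' @param traj a \code{trn_trajectory}.
#' @return integer frame count.
#' @export
n_frames <- function(traj) {
  stopifnot(inherits(traj, "trn_trajectory"))
  dim(traj$coords)[1L]
}

#' Extract one frame of a trajectory as a Structure
#' @param traj a \code{trn_trajectory}.
#' @param frame frame index (1-based).
#' @return a \code{trn_structure} with that frame's coordinates.
#' @export
trajectory_frame <- function(traj, frame) {
  stopifnot(inherits(traj, "trn_trajectory"))
  f <- as.integer(frame)
  if (f < 1L || f > n_frames(traj))
    stop("trajectory_frame: frame out of range", call. = FALSE)
  out <- traj$topology
  out$xyz <- traj$coords[f, , , drop = TRUE]
  dim(out$xyz) <- c(dim(traj$coords)[2L], 3L)
  out
}

#' @export
print.trn_trajectory <- function(x, ...) {
  cat(sprintf("Trajectory: %d frames x %d atoms%s\n",
              n_frames(x), nrow(x$topology$atoms),
              if (is.null(x$times)) "" else
                sprintf(", %.3f-%.3f ns", min(x$times), max(x$times))))
  invisible(x)
}

#' Structure from a trajectory's first frame
#' @param traj a \code{trn_trajectory}.
#' @return the topology with frame-1 coordinates.
#' @export
as_structure <- function(traj) trajectory_frame(traj, 1L)
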