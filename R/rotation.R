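# Inter-lobe rotation via virtual dihedrals: torsions over four chosen
# Calpha atoms spanning the N-lobe, the central helix and the C-lobe.

#' Virtual dihedral definition
#'
#' Four Calpha anchors used as an inter-lobe rotation coordinate. The
#' defaults follow the two standard choices for troponin C: VD1 anchors
#' residues 131, 104, 73, 15 and VD2 anchors residues 131, 104, 73, 54.
#'
#' @param label \code{"VD1"}, \code{"VD2"} or \code{"custom"}.
#' @param chain chain id carrying TnC.
#' @param residues four residue numbers (required for \code{"custom"}).
#' @return an object of class \code{virtual_dihedral}.
#' @export
virtual_dihedral <- function(label = c("VD1", "VD2", "custom"), chain,
                             residues = NULL) {
  label <- match.arg(label)
  if (is.null(residues))
    residues <- switch(label,
                       VD1 = c(131L, 104L, 73L, 15L),
                       VD2 = c(131L, 104L, 73L, 54L),
                       stop("virtual_dihedral: custom label needs residues",
                            call. = FALSE))
  residues <- as.integer(residues)
  if (length(residues) != 4L || anyDuplicated(residues))
    stop("virtual_dihedral: need four distinct residue anchors", call. = FALSE)
  structure(list(label = label, chain = chain, residues = residues,
                 atom_name = "CA"),
            class = "virtual_dihedral")
}

#' @export
print.virtual_dihedral <- function(x, ...) {
  cat(sprintf("virtual dihedral %s: Calpha %s (chain %s)\n", x$label,
              paste(x$residues, collapse = ", "), x$chain))
  invisible(x)
}

vd_indices <- function(struct, vd) {
  vapply(vd$residues, function(r)
    find_atom(struct, vd$chain, r, vd$atom_name, required = TRUE), integer(1))
}

vd_value <- function(xyz, idx, frame_hint = NULL) {
  tryCatch(
    dihedral_angle(xyz[idx[1L], ], xyz[idx[2L], ], xyz[idx[3L], ],
                   xyz[idx[4L], ]),
    error = function(e) {
      stop("undefined virtual dihedral",
           if (!is.null(frame_hint)) paste0(" at frame ", frame_hint) else "",
           ": ", conditionMessage(e), call. = FALSE)
    })
}

#' Virtual-dihedral series
#'
#' Per-frame virtual dihedral in degrees on (-180, 180]. With
#' \code{unwrap = TRUE}, successive values are shifted by multiples of 360
#' to minimise frame-to-frame jumps (off by default; raw dihedrals are the
#' standard presentation).
#'
#' @param traj a \code{trn_trajectory}.
#' @param vd a \code{\link{virtual_dihedral}}.
#' @param unwrap remove 360-degree wrap jumps.
#' @return a \code{\link{metric_series}} in degrees.
#' @export
virtual_dihedral_series <- function(traj, vd, unwrap = FALSE) {
  stopifnot(inherits(traj, "trn_trajectory"), inherits(vd, "virtual_dihedral"))
  idx <- vd_indices(traj$topology, vd)
  f <- n_frames(traj)
  a <- nrow(traj$topology$atoms)
  vals <- vapply(seq_len(f), function(fr)
    vd_value(matrix(traj$coords[fr, , ], a, 3L), idx, frame_hint = fr),
    numeric(1))
  if (unwrap && f > 1L) {
    for (fr in 2:f)
      vals[fr] <- vals[fr] + 360 * round((vals[fr - 1L] - vals[fr]) / 360)
  }
  metric_series(paste0("virtual_dihedral_", vd$label), vals, unit = "degree",
                anchors = vapply(idx, function(i)
                  anchor_label(traj$topology, i), character(1)))
}

#' Rotation between two states along a virtual dihedral
#'
#' Minimal signed difference dihedral(b) - dihedral(a) wrapped to
#' (-180, 180] degrees.
#'
#' @param a,b \code{trn_structure}s containing the four anchors.
#' @param vd a \code{\link{virtual_dihedral}}.
#' @return signed rotation in degrees on (-180, 180].
#' @export
rotation_between_states <- function(a, b, vd) {
  stopifnot(inherits(a, "trn_structure"), inherits(b, "trn_structure"),
            inherits(vd, "virtual_dihedral"))
  da <- vd_value(a$xyz, vd_indices(a, vd))
  db <- vd_value(b$xyz, vd_indices(b, vd))
  wrap_angle(db - da)
}
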