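# Hydrophobic repacking metrics: minimum heavy-atom contact distances,
# contact persistence, and solvent exposure via Shrake-Rupley SASA with a
# deterministic golden-section sphere lattice.

#' Residue-pair contact definition
#'
#' @param chain_a,resno_a,chain_b,resno_b the two residues.
#' @param scope \code{"heavy"} (all non-hydrogen atoms) or
#'   \code{"side-chain-heavy"} (non-hydrogen atoms excluding the backbone
#'   N, CA, C, O, OXT).
#' @param cutoff contact cutoff on the minimum distance, Angstrom (> 0);
#'   4.5 is the usual heavy-atom hydrophobic-contact convention.
#' @param label text label for reports.
#' @return an object of class \code{contact_def}.
#' @export
contact_def <- function(chain_a, resno_a, chain_b, resno_b,
                        scope = c("heavy", "side-chain-heavy"),
                        cutoff = 4.5, label = NULL) {
  scope <- match.arg(scope)
  if (!is_scalar_number(cutoff) || cutoff <= 0)
    stop("contact_def: cutoff must be > 0", call. = FALSE)
  if (chain_a == chain_b && resno_a == resno_b)
    stop("contact_def: residues must be distinct", call. = FALSE)
  if (is.null(label))
    label <- sprintf("%s%d-%s%d", chain_a, resno_a, chain_b, resno_b)
  structure(list(chain_a = chain_a, resno_a = as.integer(resno_a),
                 chain_b = chain_b, resno_b = as.integer(resno_b),
                 scope = scope, cutoff = cutoff, label = label),
            class = "contact_def")
}

residue_scope_indices <- function(struct, chain, resno, scope) {
  a <- struct$atoms
  idx <- which(a$chain_id == chain & a$residue_number == resno &
                 a$element != "H")
  if (scope == "side-chain-heavy")
    idx <- idx[!a$atom_name[idx] %in% c("N", "CA", "C", "O", "OXT")]
  idx
}

#' Minimum inter-residue distance series
#'
#' Per-frame minimum pairwise distance between the in-scope atoms of the two
#' residues of a contact definition.
#'
#' @param traj a \code{trn_trajectory}.
#' @param pair a \code{\link{contact_def}}.
#' @return a \code{\link{metric_series}} in Angstrom.
#' @export
min_heavy_distance_series <- function(traj, pair) {
  stopifnot(inherits(traj, "trn_trajectory"), inherits(pair, "contact_def"))
  topo <- traj$topology
  ia <- residue_scope_indices(topo, pair$chain_a, pair$resno_a, pair$scope)
  ib <- residue_scope_indices(topo, pair$chain_b, pair$resno_b, pair$scope)
  if (length(ia) == 0L || length(ib) == 0L)
    stop(sprintf("contact %s: empty atom scope ('%s') for residue %s",
                 pair$label, pair$scope,
                 if (length(ia) == 0L)
                   paste0(pair$chain_a, pair$resno_a)
                 else paste0(pair$chain_b, pair$resno_b)),
         call. = FALSE)
  f <- n_frames(traj)
  vals <- vapply(seq_len(f), function(fr) {
    pa <- matrix(traj$coords[fr, ia, ], length(ia), 3L)
    pb <- matrix(traj$coords[fr, ib, ], length(ib), 3L)
    d2 <- outer(rowSums(pa^2), rowSums(pb^2), "+") - 2 * pa %*% t(pb)
    sqrt(max(0, min(d2)))
  }, numeric(1))
  metric_series(paste0("min_dist_", pair$label), vals,
                anchors = c(paste0(pair$chain_a, ":", pair$resno_a),
                            paste0(pair$chain_b, ":", pair$resno_b)))
}

#' Contact persistence
#'
#' Fraction of frames in which each pair's minimum in-scope distance is at
#' or below its cutoff.
#'
#' @param traj a \code{trn_trajectory}.
#' @param pairs list of \code{\link{contact_def}}s.
#' @return data.frame with columns \code{pair}, \code{scope}, \code{cutoff},
#'   \code{persistence}, \code{mean_min_dist}.
#' @export
contact_persistence <- function(traj, pairs) {
  if (inherits(pairs, "contact_def")) pairs <- list(pairs)
  rows <- lapply(pairs, function(p) {
    s <- min_heavy_distance_series(traj, p)
    data.frame(pair = p$label, scope = p$scope, cutoff = p$cutoff,
               persistence = mean(s$values <= p$cutoff),
               mean_min_dist = mean(s$values), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Default hydrophobic contact panel
#'
#' The residue pairs of the repacking narrative: the PHE25/74/77 scaffold,
#' PHE28 against its pocket partners, VAL44 insertion contacts, the MET
#' triad MET45/80/81, the MET27-MET47 seal and the ILE60-MET80 /
#' MET81-LEU48 packing pairs.
#'
#' @param chain chain id carrying TnC.
#' @param scope,cutoff forwarded to \code{\link{contact_def}}.
#' @return list of \code{\link{contact_def}}s.
#' @export
default_contact_panel <- function(chain, scope = "side-chain-heavy",
                                  cutoff = 4.5) {
  pairs <- list(
    c(25L, 74L), c(25L, 77L), c(74L, 77L),
    c(28L, 77L), c(28L, 41L), c(28L, 44L),
    c(44L, 77L), c(44L, 25L), c(44L, 24L),
    c(45L, 80L), c(45L, 81L), c(80L, 81L),
    c(27L, 47L),
    c(60L, 80L), c(81L, 48L))
  lapply(pairs, function(p)
    contact_def(chain, p[1L], chain, p[2L], scope = scope, cutoff = cutoff))
}

#' Default van der Waals radii (Angstrom)
#'
#' @return named numeric vector keyed by element symbol.
#' @export
default_vdw_radii <- function() {
  c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, Ca = 2.31, H = 1.20, P = 1.80)
}

# Deterministic quasi-uniform unit-sphere lattice (golden-section spiral);
# seedless and reproducible bit-for-bit.
sphere_lattice <- function(n) {
  i <- seq_len(n) - 0.5
  z <- 1 - 2 * i / n
  r <- sqrt(pmax(0, 1 - z^2))
  phi <- i * pi * (3 - sqrt(5))
  cbind(r * cos(phi), r * sin(phi), z)
}

sasa_for_coords <- function(xyz, radii_per_atom, probe, n_points,
                            subset = NULL) {
  n <- nrow(xyz)
  if (is.null(subset)) subset <- seq_len(n)
  pts <- sphere_lattice(n_points)
  big <- radii_per_atom + probe
  out <- numeric(length(subset))
  for (k in seq_along(subset)) {
    i <- subset[k]
    ri <- big[i]
    # neighbours close enough to occlude any of atom i's surface points
    d2 <- rowSums(sweep(xyz, 2L, xyz[i, ])^2)
    nb <- which(d2 < (ri + big)^2 & seq_len(n) != i)
    if (length(nb) == 0L) {
      out[k] <- 4 * pi * ri^2
      next
    }
    surf <- sweep(pts * ri, 2L, xyz[i, ], "+")
    accessible <- rep(TRUE, n_points)
    for (j in nb) {
      if (!any(accessible)) break
      dj2 <- rowSums(sweep(surf, 2L, xyz[j, ])^2)
      accessible <- accessible & dj2 > big[j]^2
    }
    out[k] <- 4 * pi * ri^2 * mean(accessible)
  }
  out
}

#' Solvent-accessible surface area (Shrake-Rupley)
#'
#' Quasi-uniform test points are placed on each atom's solvent-expanded
#' sphere (radius r + probe); the accessible area is the expanded-sphere
#' area times the fraction of points outside every neighbour's expanded
#' sphere. The point lattice is a deterministic golden-section spiral.
#'
#' @param struct a \code{trn_structure}.
#' @param probe probe radius, Angstrom (water: 1.4).
#' @param n_points test points per atom.
#' @param radii named per-element radii table, Angstrom.
#' @param atoms optional integer indices restricting which atoms' areas are
#'   computed (occlusion still considers all atoms).
#' @return numeric per-atom areas in square Angstrom (for \code{atoms} when
#'   given, otherwise all atoms).
#' @export
sasa_shrake_rupley <- function(struct, probe = 1.4, n_points = 960L,
                               radii = default_vdw_radii(), atoms = NULL) {
  stopifnot(inherits(struct, "trn_structure"))
  ele <- struct$atoms$element
  unknown <- setdiff(unique(ele), names(radii))
  if (length(unknown))
    stop("sasa_shrake_rupley: no vdW radius configured for element(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  sasa_for_coords(struct$xyz, unname(radii[ele]), probe, as.integer(n_points),
                  subset = atoms)
}

#' Relative side-chain solvent exposure series
#'
#' Per-frame side-chain SASA of one residue divided by the same side chain's
#' SASA computed in isolation (every atom outside the residue deleted, same
#' conformation). Buried side chains score near 0, fully exposed near 1.
#'
#' @param traj a \code{trn_trajectory}.
#' @param chain,resno the residue.
#' @param probe probe radius, Angstrom.
#' @param n_points test points per atom.
#' @param radii per-element radii table.
#' @return a \code{\link{metric_series}} (dimensionless relative exposure).
#' @export
residue_exposure_series <- function(traj, chain, resno, probe = 1.4,
                                    n_points = 960L,
                                    radii = default_vdw_radii()) {
  stopifnot(inherits(traj, "trn_trajectory"))
  topo <- traj$topology
  sc <- residue_scope_indices(topo, chain, resno, "side-chain-heavy")
  if (length(sc) == 0L)
    stop(sprintf(
      "residue %s:%d has no side-chain heavy atoms (glycine?); exposure undefined",
      chain, resno), call. = FALSE)
  res_idx <- which(topo$atoms$chain_id == chain &
                     topo$atoms$residue_number == resno)
  ele <- topo$atoms$element
  unknown <- setdiff(unique(ele), names(radii))
  if (length(unknown))
    stop("residue_exposure_series: no vdW radius for element(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  rad <- unname(radii[ele])
  f <- n_frames(traj)
  a <- nrow(topo$atoms)
  sc_in_res <- match(sc, res_idx)
  vals <- vapply(seq_len(f), function(fr) {
    xyz <- matrix(traj$coords[fr, , ], a, 3L)
    full <- sum(sasa_for_coords(xyz, rad, probe, n_points, subset = sc))
    iso <- sum(sasa_for_coords(xyz[res_idx, , drop = FALSE], rad[res_idx],
                               probe, n_points, subset = sc_in_res))
    full / iso
  }, numeric(1))
  metric_series(sprintf("exposure_%s%d", chain, resno), vals,
                unit = "relative",
                anchors = sprintf("%s:%d", chain, resno))
}
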