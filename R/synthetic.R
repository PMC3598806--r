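# Synthetic structures and trajectories with prescribed geometric and
# statistical ground truth, so that every analysis stage is testable without
# MD trajectories or downloads.
#
# The toy lobe is an idealised two-conformer N-lobe: five helices
# (N, A, B, C, D) built as ideal alpha-helices (rise 1.5 A, 100 deg/residue),
# two 12-residue binding loops (29-40 and 65-76) built as circular arcs with
# 3.8 A Calpha spacing, backbone N/C/O placed around the Calpha trace, and
# pseudo side chains (CB/CG, plus the position-12 glutamate CD/OE1/OE2) only
# where the packing and prong metrics need them. The open conformer places
# the Calpha16-Calpha48 pocket distance at d_open and holds the prong
# contacts formed (< 3 A); the closed conformer places it at d_closed with
# the prongs released and both binding loops expanded. A Calpha-only stub
# (residues 86-135) continues the D helix into the central linker and
# C-lobe so the default virtual dihedrals (anchors 131/104/73/15 and /54)
# resolve.

TOY_CHAIN <- "A"

TOY_RESIDUE_NAMES <- c(
  "15" = "GLU", "16" = "GLU", "17" = "MET", "21" = "PHE", "24" = "ALA",
  "25" = "PHE", "27" = "MET", "28" = "PHE", "29" = "ASP", "30" = "ALA",
  "31" = "ASP", "32" = "GLY", "33" = "GLY", "34" = "GLY", "35" = "ASP",
  "36" = "ILE", "37" = "SER", "38" = "THR", "39" = "LYS", "40" = "GLU",
  "41" = "LEU", "43" = "THR", "44" = "VAL", "45" = "MET", "47" = "MET",
  "48" = "LEU", "50" = "GLN", "54" = "GLU", "60" = "ILE", "61" = "ILE",
  "64" = "VAL", "65" = "ASP", "66" = "GLU", "69" = "SER", "70" = "GLY",
  "72" = "ILE", "73" = "ASP", "74" = "PHE", "76" = "GLU", "77" = "PHE",
  "80" = "MET", "81" = "MET", "104" = "PHE", "131" = "GLU")

# residues that carry CB/CG pseudo side chains (the hydrophobic panel)
TOY_SIDECHAIN_RESIDUES <- c(17L, 21L, 24L, 25L, 27L, 28L, 41L, 43L, 44L,
                            45L, 47L, 48L, 60L, 61L, 74L, 77L, 80L, 81L)

toy_residue_name <- function(resno) {
  nm <- unname(TOY_RESIDUE_NAMES[as.character(resno)])
  ifelse(is.na(nm), "ALA", nm)
}

perp_frame <- function(axis) {
  a <- unit(axis)
  ref <- if (abs(a[3L]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  u <- unit(ref - sum(ref * a) * a)
  v <- cross3(a, u)
  list(a = a, u = u, v = v)
}

# Calpha positions of an ideal alpha-helix: rise 1.5 A and 100 degrees of
# twist per residue on a 2.3 A radius around the axis.
helix_ca <- function(start, axis, n, rise = 1.5, twist = 100, radius = 2.3) {
  fr <- perp_frame(axis)
  k <- seq_len(n) - 1L
  ang <- deg2rad(twist * k)
  t(vapply(seq_len(n), function(i)
    start + rise * k[i] * fr$a +
      radius * (cos(ang[i]) * fr$u + sin(ang[i]) * fr$v),
    numeric(3)))
}

# n_interior points on a circular arc from p to q with a prescribed contour
# length (spacing * (n_interior + 1)); the arc bulges toward `bulge`.
arc_interior <- function(p, q, n_interior, bulge, spacing = 3.8) {
  contour <- spacing * (n_interior + 1L)
  chord <- vnorm(q - p)
  if (chord > contour)
    stop("arc_interior: endpoints too far apart for the contour length",
         call. = FALSE)
  ts <- seq_len(n_interior) / (n_interior + 1L)
  if (chord > 0.999 * contour)  # essentially straight
    return(t(vapply(ts, function(s) p + s * (q - p), numeric(3))))
  c_dir <- unit(q - p)
  m <- unit(bulge - sum(bulge * c_dir) * c_dir)
  f <- function(th) sin(th / 2) / (th / 2) - chord / contour
  theta <- stats::uniroot(f, c(1e-6, 2 * pi - 1e-4), tol = 1e-12)$root
  radius <- contour / theta
  h <- sqrt(max(0, radius^2 - (chord / 2)^2))
  # the centre sits opposite the bulge for minor arcs, on the bulge side for
  # major arcs (> pi), so the swept arc always passes through the bulge side
  center <- (p + q) / 2 + (if (theta > pi) h else -h) * m
  w <- unit(cross3(c_dir, m))
  plus <- rotate_about_axis(p, center, w, rad2deg(theta))
  sgn <- if (vnorm(plus - q) < vnorm(q - rotate_about_axis(p, center, w,
                                                           -rad2deg(theta))))
    1 else -1
  t(vapply(ts, function(s)
    rotate_about_axis(p, center, w, sgn * rad2deg(theta * s)), numeric(3)))
}

# Flesh out a Calpha trace with approximate backbone N, C, O positions:
# C_i and N_{i+1} sit on the i -> i+1 virtual bond with a 0.83 A
# perpendicular lift, reproducing realistic bond lengths (CA-C 1.52,
# C-N 1.33, N-CA 1.46); O hangs off C perpendicular to the segment plane.
backbone_from_ca <- function(ca, lift = 0.83) {
  n_res <- nrow(ca)
  a_len <- sqrt(1.52^2 - lift^2)
  b_len <- sqrt(1.46^2 - lift^2)
  N <- C <- O <- matrix(NA_real_, n_res, 3L)
  seg_p <- vector("list", n_res)
  for (i in seq_len(n_res - 1L)) {
    d <- unit(ca[i + 1L, ] - ca[i, ])
    ref <- if (abs(d[3L]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
    p <- unit(ref - sum(ref * d) * d)
    seg_p[[i]] <- list(d = d, p = p)
    C[i, ] <- ca[i, ] + a_len * d + lift * p
    N[i + 1L, ] <- ca[i + 1L, ] - b_len * d + lift * p
    O[i, ] <- C[i, ] + 1.23 * unit(cross3(d, p))
  }
  # chain termini: first N and last C/O reuse the nearest segment frame
  s1 <- seg_p[[1L]]
  N[1L, ] <- ca[1L, ] - b_len * s1$d + lift * s1$p
  sl <- seg_p[[n_res - 1L]]
  C[n_res, ] <- ca[n_res, ] + a_len * sl$d + lift * sl$p
  O[n_res, ] <- C[n_res, ] + 1.23 * unit(cross3(sl$d, sl$p))
  list(N = N, C = C, O = O)
}

# Heavy-atom clash check excluding atoms of the same or sequence-adjacent
# residues; a toy geometry that self-intersects is a construction error.
assert_no_clash <- function(atoms, xyz, min_dist = 1.5) {
  d <- as.matrix(stats::dist(xyz))
  same_chain <- outer(atoms$chain_id, atoms$chain_id, "==")
  near_seq <- abs(outer(atoms$residue_number, atoms$residue_number, "-")) <= 1L
  excl <- same_chain & near_seq
  diag(d) <- Inf
  d[excl] <- Inf
  if (min(d) < min_dist) {
    worst <- which(d == min(d), arr.ind = TRUE)[1L, ]
    stop(sprintf(
      "toy geometry self-intersects: atoms %s:%d:%s and %s:%d:%s at %.2f A",
      atoms$chain_id[worst[1L]], atoms$residue_number[worst[1L]],
      atoms$atom_name[worst[1L]], atoms$chain_id[worst[2L]],
      atoms$residue_number[worst[2L]], atoms$atom_name[worst[2L]],
      min(d)), call. = FALSE)
  }
  invisible(TRUE)
}

element_for_name <- function(name) {
  switch(name, N = "N", O = "O", OE1 = "O", OE2 = "O", "C")
}

#' Build the idealised two-state N-lobe
#'
#' A deterministic toy troponin-C N-lobe (chain "A") with helices N, A, B,
#' C, D, the two 12-residue binding loops, backbone N/CA/C/O for residues
#' 3-85, pseudo side chains on the hydrophobic-panel residues, glutamate
#' CD/OE1/OE2 at loop position 12 of both sites, and a Calpha-only central
#' helix / C-lobe stub (residues 86-135) carrying the virtual-dihedral
#' anchors 104 and 131. Both conformers share an identical topology.
#'
#' In the open conformer the pocket distance Calpha16-Calpha48 equals
#' \code{d_open} and both prong contacts are formed (N-OE < 3 A); in the
#' closed conformer the pocket distance equals \code{d_closed}, the prongs
#' are released (> 3.5 A) and both binding loops are expanded.
#'
#' @param conformer \code{"open"} or \code{"closed"}.
#' @param d_open,d_closed prescribed pocket distances, Angstrom.
#' @return a \code{trn_structure}; attribute \code{pocket_target} records
#'   the prescribed pocket distance.
#' @export
build_toy_two_state_lobe <- function(conformer = c("open", "closed"),
                                     d_open = 23.9, d_closed = 13.4) {
  conformer <- match.arg(conformer)
  d_target <- if (conformer == "open") d_open else d_closed

  ca <- matrix(NA_real_, 133L, 3L)  # residues 3..135
  rn <- 3:135
  put <- function(resno, xyz) ca[match(resno, rn), ] <<- xyz
  get_ca <- function(resno) ca[match(resno, rn), ]

  # fixed elements: N helix, A helix, D helix + extension + C-lobe stub
  a_axis <- c(1, 0, 0)
  put(16:28, helix_ca(c(0, 0, 0), a_axis, 13L))
  put(5:12, helix_ca(c(-16, -8, 4), c(1, 0, 0), 8L))
  ca5 <- get_ca(5L)
  put(4L, ca5 - 3.8 * c(1, 0, 0))
  put(3L, ca5 - 7.6 * c(1, 0, 0))
  put(13:15, arc_interior(get_ca(12L), get_ca(16L), 3L, bulge = c(0, 0, 1)))
  dext <- helix_ca(c(20, 11, 0), c(-1, 0, 0), 38L)   # residues 77..114
  put(77:114, dext)
  stub_dir <- unit(c(0, 0.6, 0.8))
  put(115:135, t(vapply(1:21, function(k)
    get_ca(114L) + 3.8 * k * stub_dir, numeric(3))))

  # B helix placed so that Calpha48 sits exactly at the prescribed pocket
  # distance from Calpha16, along a fixed direction; the C helix rides with
  # the B helix (they move together in the open <-> closed transition).
  w <- c(0.28, -0.96, 0)   # unit by construction
  ca16 <- get_ca(16L)
  ca48_target <- ca16 + d_target * w
  fr_b <- perp_frame(c(-1, 0, 0))
  ang7 <- deg2rad(100 * 7)
  b_off <- 1.5 * 7 * fr_b$a + 2.3 * (cos(ang7) * fr_b$u + sin(ang7) * fr_b$v)
  s_b <- ca48_target - b_off
  put(41:48, helix_ca(s_b, c(-1, 0, 0), 8L))

  s_c <- ca48_target + c(-3, 3, -16.3)   # C helix start (residue 54 at +2.3 z)
  put(54:64, helix_ca(s_c, c(1, 0, 0), 11L))
  put(49:53, arc_interior(get_ca(48L), get_ca(54L), 5L,
                          bulge = c(0, -0.4, -0.9)))

  # binding loops: positions 1 and 12 leave the flanking helices at
  # conformer-dependent angles off the chord, so that the loop expands on
  # calcium release (position 1 swings out toward the bulge, position 12
  # leans backward)
  alpha1 <- if (conformer == "open") 25 else 95
  alpha12 <- if (conformer == "open") 25 else 140
  place_loop <- function(res_prev, res_next, loop_res, bulge) {
    p_prev <- get_ca(res_prev); p_next <- get_ca(res_next)
    c_dir <- unit(p_next - p_prev)
    m <- unit(bulge - sum(bulge * c_dir) * c_dir)
    f1 <- cos(deg2rad(alpha1)) * c_dir + sin(deg2rad(alpha1)) * m
    f12 <- -cos(deg2rad(alpha12)) * c_dir + sin(deg2rad(alpha12)) * m
    pos1 <- p_prev + 3.8 * f1
    pos12 <- p_next + 3.8 * f12
    put(loop_res[1L], pos1)
    put(loop_res[12L], pos12)
    put(loop_res[2:11], arc_interior(pos1, pos12, 10L, bulge = m))
  }
  place_loop(28L, 41L, 29:40, bulge = c(1, 0.15, 0.1))
  place_loop(64L, 77L, 65:76, bulge = c(0.1, 0, -1))

  # backbone for residues 3..85 (the stub stays Calpha-only); residue 85
  # borrows the 85->86 segment for its carbonyl
  bb_ca <- ca[match(3:86, rn), , drop = FALSE]
  bb <- backbone_from_ca(bb_ca)

  rows <- list(); coords <- list(); serial <- 0L
  emit <- function(resno, name, pos) {
    serial <<- serial + 1L
    rows[[length(rows) + 1L]] <<- data.frame(
      serial = serial, atom_name = name, residue_name = toy_residue_name(resno),
      chain_id = TOY_CHAIN, residue_number = resno,
      element = element_for_name(name), alt_loc = NA_character_,
      hetatm = FALSE, stringsAsFactors = FALSE)
    coords[[length(coords) + 1L]] <<- pos
  }

  side_dir <- function(resno) {
    i <- match(resno, rn)
    unit(ca[i, ] - (ca[i - 1L, ] + ca[i + 1L, ]) / 2)
  }

  for (resno in 3:85) {
    i <- resno - 2L
    emit(resno, "N", bb$N[i, ])
    emit(resno, "CA", bb_ca[i, ])
    emit(resno, "C", bb$C[i, ])
    emit(resno, "O", bb$O[i, ])
    if (resno %in% TOY_SIDECHAIN_RESIDUES) {
      s <- side_dir(resno)
      emit(resno, "CB", bb_ca[i, ] + 1.53 * s)
      if (toy_residue_name(resno) != "ALA")
        emit(resno, "CG", bb_ca[i, ] + 2.6 * s)
    }
  }

  # position-12 glutamate pseudo side chains: held in toward the loop centre
  # (contacts formed) when open, swung outward (released) when closed
  n_index <- function(resno) {
    which(vapply(rows, function(r)
      r$residue_number == resno && r$atom_name == "N", logical(1)))
  }
  place_prong <- function(site_res, pos2, pos9, pos12) {
    centre <- colMeans(ca[match(site_res, rn), , drop = FALSE])
    n2 <- coords[[n_index(pos2)]]
    n9 <- coords[[n_index(pos9)]]
    if (conformer == "open") {
      oe1 <- n2 + 2.8 * unit(centre - n2)
      oe2 <- n9 + 2.9 * unit(centre - n9)
    } else {
      oe1 <- n2 + 6.0 * unit(n2 - centre)
      oe2 <- n9 + 6.0 * unit(n9 - centre)
    }
    cd <- (oe1 + oe2) / 2 + 0.6 * unit(get_ca(pos12) - (oe1 + oe2) / 2)
    emit(pos12, "CD", cd)
    emit(pos12, "OE1", oe1)
    emit(pos12, "OE2", oe2)
  }
  place_prong(29:40, 30L, 37L, 40L)
  place_prong(65:76, 66L, 73L, 76L)

  for (resno in 86:135)
    emit(resno, "CA", get_ca(resno))

  atoms <- do.call(rbind, rows)
  xyz <- do.call(rbind, coords)
  assert_no_clash(atoms, xyz)
  out <- new_structure(atoms, xyz,
                       source = paste0("toy_lobe_", conformer))
  attr(out, "pocket_target") <- d_target
  out
}

#' Chain map for the toy lobe
#' @return a \code{\link{chain_map}} with TnC on chain "A".
#' @export
toy_chain_map <- function() chain_map(tnc = TOY_CHAIN)

same_topology <- function(a, b) {
  identical(atom_key_string(a$atoms), atom_key_string(b$atoms))
}

#' Linear interpolation between two structures
#'
#' @param a,b \code{trn_structure}s with identical topology.
#' @param t interpolation fraction in [0, 1] (0 = a, 1 = b).
#' @return a \code{trn_structure}.
#' @export
lerp_structure <- function(a, b, t) {
  stopifnot(inherits(a, "trn_structure"), inherits(b, "trn_structure"))
  if (!same_topology(a, b))
    stop("lerp_structure: topologies differ", call. = FALSE)
  out <- a
  out$xyz <- (1 - t) * a$xyz + t * b$xyz
  out$source <- sprintf("lerp(%s,%s,%.3f)", a$source, b$source, t)
  out
}

#' Two-state morph trajectory
#'
#' Frame t is the linear interpolation of the two conformers at fraction
#' (t-1)/(F-1), plus i.i.d. isotropic Gaussian coordinate noise.
#'
#' @param open,closed \code{trn_structure}s with identical topology.
#' @param n_frames number of frames F (>= 1).
#' @param noise_sd per-coordinate Gaussian noise SD, Angstrom.
#' @param seed RNG seed; mandatory when \code{noise_sd > 0}.
#' @return a \code{trn_trajectory}.
#' @export
morph_trajectory <- function(open, closed, n_frames, noise_sd = 0,
                             seed = NULL) {
  stopifnot(inherits(open, "trn_structure"), inherits(closed, "trn_structure"))
  if (!same_topology(open, closed))
    stop("morph_trajectory: topologies differ", call. = FALSE)
  f <- as.integer(n_frames)
  stopifnot(f >= 1L)
  a <- nrow(open$atoms)
  alphas <- if (f == 1L) 0 else (seq_len(f) - 1L) / (f - 1L)
  coords <- array(NA_real_, c(f, a, 3L))
  for (fr in seq_len(f))
    coords[fr, , ] <- (1 - alphas[fr]) * open$xyz + alphas[fr] * closed$xyz
  if (noise_sd > 0) {
    if (is.null(seed))
      stop("morph_trajectory: noise_sd > 0 needs a seed", call. = FALSE)
    coords <- coords + with_seed(seed,
      array(stats::rnorm(f * a * 3L, 0, noise_sd), c(f, a, 3L)))
  }
  new_trajectory(open, coords)
}

#' Static structure plus per-atom isotropic Gaussian noise
#'
#' Emulates prescribed per-atom fluctuation amplitudes: atom i in every
#' frame is the reference position plus isotropic noise with SD
#' \code{per_atom_sd[i]} per coordinate, so its expected RMSF is
#' \code{sd * sqrt(3)}.
#'
#' @param struct reference \code{trn_structure}.
#' @param per_atom_sd per-coordinate SD, Angstrom; scalar or one per atom.
#' @param n_frames number of frames.
#' @param seed RNG seed (mandatory).
#' @return a \code{trn_trajectory}.
#' @export
noisy_static_trajectory <- function(struct, per_atom_sd, n_frames, seed) {
  stopifnot(inherits(struct, "trn_structure"))
  a <- nrow(struct$atoms)
  if (length(per_atom_sd) == 1L) per_atom_sd <- rep(per_atom_sd, a)
  if (length(per_atom_sd) != a)
    stop("noisy_static_trajectory: per_atom_sd must be scalar or one per atom",
         call. = FALSE)
  if (any(per_atom_sd < 0))
    stop("noisy_static_trajectory: negative SD", call. = FALSE)
  f <- as.integer(n_frames)
  coords <- with_seed(seed, {
    noise <- array(stats::rnorm(f * a * 3L), c(f, a, 3L)) *
      aperm(array(per_atom_sd, c(a, 3L, f)), c(3L, 1L, 2L))
    aperm(array(t(struct$xyz), c(3L, a, f)), c(3L, 2L, 1L)) + noise
  })
  new_trajectory(struct, coords)
}

#' Rigid-rotation trajectory
#'
#' Selected atoms are rotated frame-by-frame by a scheduled angle about the
#' axis through two anchor Calpha atoms; all other atoms stay fixed.
#'
#' @param struct reference \code{trn_structure}.
#' @param rotate_sel an \code{\link{selection}} of atoms to rotate.
#' @param axis_residues two residue numbers whose Calpha atoms define the
#'   rotation axis.
#' @param chain chain id of the axis anchors.
#' @param angle_schedule per-frame rotation angles, degrees.
#' @param noise_sd optional isotropic coordinate noise SD, Angstrom.
#' @param seed RNG seed; mandatory when \code{noise_sd > 0}.
#' @return a \code{trn_trajectory}.
#' @export
rigid_rotation_trajectory <- function(struct, rotate_sel, axis_residues,
                                      chain, angle_schedule, noise_sd = 0,
                                      seed = NULL) {
  stopifnot(inherits(struct, "trn_structure"), length(axis_residues) == 2L)
  if (axis_residues[1L] == axis_residues[2L])
    stop("rigid_rotation_trajectory: axis anchors must be distinct",
         call. = FALSE)
  i1 <- find_atom(struct, chain, axis_residues[1L], "CA", required = TRUE)
  i2 <- find_atom(struct, chain, axis_residues[2L], "CA", required = TRUE)
  p1 <- struct$xyz[i1, ]; p2 <- struct$xyz[i2, ]
  axis <- p2 - p1
  if (vnorm(axis) < 1e-6)
    stop("rigid_rotation_trajectory: axis anchors coincide", call. = FALSE)
  idx <- resolve_selection(struct, rotate_sel, require_atoms = 1L)
  for (i in c(i1, i2)) {
    if (i %in% idx) {
      r <- struct$xyz[i, ] - p1
      off_axis <- vnorm(r - sum(r * unit(axis)) * unit(axis))
      if (off_axis > 1e-6)
        warning("rigid_rotation_trajectory: an axis anchor is inside the ",
                "rotating selection and off-axis", call. = FALSE)
    }
  }
  f <- length(angle_schedule)
  a <- nrow(struct$atoms)
  coords <- array(NA_real_, c(f, a, 3L))
  for (fr in seq_len(f)) {
    xyz <- struct$xyz
    xyz[idx, ] <- rotate_about_axis(xyz[idx, , drop = FALSE], p1, axis,
                                    angle_schedule[fr])
    coords[fr, , ] <- xyz
  }
  if (noise_sd > 0) {
    if (is.null(seed))
      stop("rigid_rotation_trajectory: noise_sd > 0 needs a seed",
           call. = FALSE)
    coords <- coords + with_seed(seed,
      array(stats::rnorm(f * a * 3L, 0, noise_sd), c(f, a, 3L)))
  }
  new_trajectory(struct, coords)
}

#' Step-displacement event trajectory
#'
#' Selected atoms are displaced by a fixed vector from \code{event_frame}
#' (inclusive) to \code{return_frame} (exclusive; defaults to the end), so
#' distance-based metrics see a scheduled breakage at \code{event_frame} and
#' an optional reformation at \code{return_frame}.
#'
#' @param struct reference \code{trn_structure}.
#' @param move_sel an \code{\link{selection}} of atoms to displace.
#' @param displacement 3-vector displacement, Angstrom.
#' @param n_frames number of frames.
#' @param event_frame first displaced frame (1-based).
#' @param return_frame optional first frame back at the reference position.
#' @param noise_sd optional isotropic coordinate noise SD, Angstrom.
#' @param seed RNG seed; mandatory when \code{noise_sd > 0}.
#' @return a \code{trn_trajectory}.
#' @export
step_displacement_trajectory <- function(struct, move_sel, displacement,
                                         n_frames, event_frame,
                                         return_frame = NULL, noise_sd = 0,
                                         seed = NULL) {
  stopifnot(inherits(struct, "trn_structure"), length(displacement) == 3L)
  f <- as.integer(n_frames)
  event_frame <- as.integer(event_frame)
  if (event_frame < 1L || event_frame > f)
    stop("step_displacement_trajectory: event_frame outside 1..n_frames",
         call. = FALSE)
  idx <- resolve_selection(struct, move_sel, require_atoms = 1L)
  displaced <- seq_len(f) >= event_frame
  if (!is.null(return_frame)) displaced <- displaced &
      seq_len(f) < as.integer(return_frame)
  a <- nrow(struct$atoms)
  coords <- array(NA_real_, c(f, a, 3L))
  for (fr in seq_len(f)) {
    xyz <- struct$xyz
    if (displaced[fr])
      xyz[idx, ] <- sweep(xyz[idx, , drop = FALSE], 2L, displacement, "+")
    coords[fr, , ] <- xyz
  }
  if (noise_sd > 0) {
    if (is.null(seed))
      stop("step_displacement_trajectory: noise_sd > 0 needs a seed",
           call. = FALSE)
    coords <- coords + with_seed(seed,
      array(stats::rnorm(f * a * 3L, 0, noise_sd), c(f, a, 3L)))
  }
  new_trajectory(struct, coords)
}

#' Ornstein-Uhlenbeck two-probe trajectory
#'
#' An Euler-Maruyama Ornstein-Uhlenbeck series
#' x_{t+1} = x_t + theta (mu - x_t) dt + sigma sqrt(dt) Z realised as the
#' separation of two probe atoms at (0,0,0) and (0,0,x_t); its stationary
#' SD is sigma / sqrt(2 theta).
#'
#' @param theta mean-reversion rate (> 0), 1/ns.
#' @param mu stationary mean separation, Angstrom.
#' @param sigma diffusion amplitude, Angstrom/sqrt(ns).
#' @param dt time step, ns (> 0; theta * dt must stay below 2 for a stable
#'   discretisation).
#' @param n_frames number of frames.
#' @param seed RNG seed (mandatory).
#' @param x0 initial separation (default \code{mu}).
#' @return list with \code{trajectory} (a \code{trn_trajectory}),
#'   \code{series} (the x values), \code{stationary_mean} and
#'   \code{stationary_sd}.
#' @export
ou_two_probe_trajectory <- function(theta, mu, sigma, dt, n_frames, seed,
                                    x0 = mu) {
  if (!is_scalar_number(theta) || theta <= 0)
    stop("ou_two_probe_trajectory: theta must be > 0", call. = FALSE)
  if (!is_scalar_number(dt) || dt <= 0)
    stop("ou_two_probe_trajectory: dt must be > 0", call. = FALSE)
  if (theta * dt >= 2)
    stop("ou_two_probe_trajectory: unstable discretisation (theta*dt >= 2)",
         call. = FALSE)
  f <- as.integer(n_frames)
  x <- with_seed(seed, {
    z <- stats::rnorm(f - 1L)
    out <- numeric(f)
    out[1L] <- x0
    for (t in seq_len(f - 1L))
      out[t + 1L] <- out[t] + theta * (mu - out[t]) * dt +
        sigma * sqrt(dt) * z[t]
    out
  })
  atoms <- data.frame(
    serial = 1:2, atom_name = "CA", residue_name = "GLY",
    chain_id = "A", residue_number = 1:2, element = "C",
    alt_loc = NA_character_, hetatm = FALSE, stringsAsFactors = FALSE)
  topo <- new_structure(atoms, rbind(c(0, 0, 0), c(0, 0, x[1L])),
                        source = "ou_two_probe")
  coords <- array(0, c(f, 2L, 3L))
  coords[, 2L, 3L] <- x
  list(trajectory = new_trajectory(topo, coords,
                                   times = dt * (seq_len(f) - 1L) + 1e-9),
       series = x, stationary_mean = mu,
       stationary_sd = sigma / sqrt(2 * theta))
}

#' Build an idealised two-strand beta bridge
#'
#' A small antiparallel two-strand sheet carrying the beta-scaffold residue
#' numbering (strand 1: residues 33-39, strand 2: 69-75, chain "A"),
#' constructed so that all four scaffold hydrogen bonds (36/72 central
#' pairs, 34-74 and 38-70 flanking pairs) are formed at an HN-O distance of
#' 2.0 Angstrom. A positive \code{splay} displaces the flanking residues of
#' strand 2 (69, 70, 74, 75) away from strand 1, breaking the flanking
#' bonds while the central pairs stay formed.
#'
#' @param splay displacement of the flanking strand-2 residues, Angstrom.
#' @return a \code{trn_structure}.
#' @export
build_beta_bridge <- function(splay = 0) {
  s <- 3.3
  n_res <- 7L
  template <- lapply(seq_len(n_res) - 1L, function(i) {
    list(N = c(s * i, 0, 0),
         CA = c(s * i + 1.1, -0.5, 0.4),
         C = c(s * i + 2.2, 0, 0),
         O = c(s * i + 2.2, 1.23, 0))
  })
  # amide-H offset implied by the placement rule on this template
  h_off <- place_amide_h(template[[2L]]$N, template[[2L]]$CA,
                         template[[1L]]$C) - template[[2L]]$N
  xoff <- (s * 3 + 2.2) + (s * 3 + h_off[1L])
  d_strand <- 1.23 + h_off[2L] + sqrt(4 - h_off[3L]^2)  # HN-O = 2.0 exactly
  flip <- function(p) c(-p[1L] + xoff, -p[2L] + d_strand, p[3L])

  names1 <- c("ALA", "GLY", "ALA", "ILE", "SER", "THR", "ALA")
  names2 <- c("SER", "GLY", "ALA", "ILE", "ASP", "PHE", "ALA")
  rows <- list(); coords <- list(); serial <- 0L
  emit <- function(resno, resname, name, pos) {
    serial <<- serial + 1L
    rows[[length(rows) + 1L]] <<- data.frame(
      serial = serial, atom_name = name, residue_name = resname,
      chain_id = "A", residue_number = resno, element = element_for_name(name),
      alt_loc = NA_character_, hetatm = FALSE, stringsAsFactors = FALSE)
    coords[[length(coords) + 1L]] <<- pos
  }
  for (i in seq_len(n_res)) {
    for (nm in c("N", "CA", "C", "O"))
      emit(32L + i, names1[i], nm, template[[i]][[nm]])
  }
  for (j in seq_len(n_res)) {
    resno <- 68L + j
    shift <- if (resno %in% c(69L, 70L, 74L, 75L)) c(0, splay, 0) else c(0, 0, 0)
    for (nm in c("N", "CA", "C", "O"))
      emit(resno, names2[j], nm, flip(template[[j]][[nm]]) + shift)
  }
  new_structure(do.call(rbind, rows), do.call(rbind, coords),
                source = "toy_beta_bridge")
}
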