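# Fixture builders shared across the test files. Everything is generated in
# code; no stored data files.

# one fixed-width PDB ATOM/HETATM line; element = "" leaves cols 77-78 blank
pdb_line <- function(record, serial, name4, resname, chain, resno, x, y, z,
                     alt = " ", occ = 1, element = "") {
  sprintf("%-6s%5d %-4s%1s%-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          record, serial, name4, alt, resname, chain, resno, x, y, z, occ, 0,
          element)
}

write_fixture_pdb <- function(lines, path = tempfile(fileext = ".pdb")) {
  writeLines(c(lines, "END"), path)
  path
}

# minimal structure from a compact atom spec list:
# list(c(name, resname, chain, resno), xyz)
make_structure <- function(specs, xyz, hetatm = FALSE) {
  atoms <- do.call(rbind, lapply(seq_along(specs), function(i) {
    s <- specs[[i]]
    data.frame(serial = i, atom_name = s[[1]], residue_name = s[[2]],
               chain_id = s[[3]], residue_number = as.integer(s[[4]]),
               element = if (length(s) >= 5) s[[5]] else
                 substr(s[[1]], 1, 1),
               alt_loc = NA_character_,
               hetatm = if (length(hetatm) == 1) hetatm else hetatm[i],
               stringsAsFactors = FALSE)
  }))
  new_structure(atoms, xyz, source = "fixture")
}

# static F-frame trajectory repeating one structure
static_trajectory <- function(struct, n_frames) {
  a <- nrow(struct$atoms)
  coords <- array(NA_real_, c(n_frames, a, 3))
  for (fr in seq_len(n_frames)) coords[fr, , ] <- struct$xyz
  new_trajectory(struct, coords)
}

# apply one rigid transform (rotation about an axis plus translation) to
# every frame of a trajectory
rigidly_move_trajectory <- function(traj, axis_point = c(1, 2, 3),
                                    axis_dir = c(1, 1, 0), angle = 37,
                                    translation = c(5, -3, 2)) {
  coords <- traj$coords
  for (fr in seq_len(n_frames(traj))) {
    xyz <- matrix(coords[fr, , ], dim(coords)[2], 3)
    xyz <- rotate_about_axis(xyz, axis_point, axis_dir, angle)
    coords[fr, , ] <- sweep(xyz, 2, translation, "+")
  }
  new_trajectory(traj$topology, coords, times = traj$times)
}

# rotation matrix from a unit quaternion (independent construction used as
# the oracle for kabsch_superpose)
quat_rotation <- function(q) {
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}

toy_open <- function() build_toy_two_state_lobe("open")
toy_closed <- function() build_toy_two_state_lobe("closed")
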