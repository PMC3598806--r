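# Hydrophobic contact metrics and Shrake-Rupley solvent accessibility.

two_residue_pair <- function(xyz_list, names) {
  make_structure(lapply(seq_along(names), function(i) {
    n <- names[[i]]
    list(n$atom, "XXX", "A", n$resno,
         if (startsWith(n$atom, "O")) "O" else "C")
  }), do.call(rbind, xyz_list))
}

test_that("minimum-distance series respects the atom scope", {
  s <- two_residue_pair(
    list(c(0, 0, 0), c(0, 0, 3), c(0, 0, 4), c(0, 0, 6)),
    list(list(atom = "CA", resno = 1), list(atom = "CB", resno = 1),
         list(atom = "CA", resno = 2), list(atom = "CB", resno = 2)))
  traj <- new_trajectory(s, s$xyz)
  heavy <- min_heavy_distance_series(
    traj, contact_def("A", 1, "A", 2, scope = "heavy"))
  expect_equal(heavy$values, 1)  # CB1 to CA2
  sc <- min_heavy_distance_series(
    traj, contact_def("A", 1, "A", 2, scope = "side-chain-heavy"))
  expect_equal(sc$values, 3)     # CB1 to CB2: backbone excluded
  expect_gt(sc$values, heavy$values)
  # two single-atom residues 4 A apart
  s2 <- two_residue_pair(list(c(0, 0, 0), c(0, 4, 0)),
                         list(list(atom = "CB", resno = 1),
                              list(atom = "CB", resno = 2)))
  expect_equal(min_heavy_distance_series(
    new_trajectory(s2, s2$xyz), contact_def("A", 1, "A", 2))$values, 4)
  # symmetry in the pair
  expect_equal(min_heavy_distance_series(
    new_trajectory(s2, s2$xyz), contact_def("A", 2, "A", 1))$values, 4)
  # empty scope errors: residue with backbone only
  s3 <- two_residue_pair(list(c(0, 0, 0), c(0, 4, 0)),
                         list(list(atom = "CA", resno = 1),
                              list(atom = "CB", resno = 2)))
  expect_error(min_heavy_distance_series(
    new_trajectory(s3, s3$xyz),
    contact_def("A", 1, "A", 2, scope = "side-chain-heavy")),
    "empty atom scope")
})

test_that("contact persistence counts the in-contact frame fraction", {
  s <- two_residue_pair(list(c(0, 0, 0), c(0, 0, 4)),
                        list(list(atom = "CB", resno = 1),
                             list(atom = "CB", resno = 2)))
  stay <- contact_persistence(static_trajectory(s, 10),
                              contact_def("A", 1, "A", 2, cutoff = 4.5))
  expect_equal(stay$persistence, 1)
  # displacing one residue beyond the cutoff for half the frames gives 0.5
  half <- step_displacement_trajectory(
    s, selection(residue_set = 2L), displacement = c(0, 0, 3),
    n_frames = 10, event_frame = 6)
  expect_equal(contact_persistence(
    half, contact_def("A", 1, "A", 2, cutoff = 4.5))$persistence, 0.5)
  far <- step_displacement_trajectory(
    s, selection(residue_set = 2L), displacement = c(0, 0, 50),
    n_frames = 10, event_frame = 1)
  expect_equal(contact_persistence(
    far, contact_def("A", 1, "A", 2, cutoff = 4.5))$persistence, 0)
})

test_that("a scheduled insertion event drops the VAL44-PHE77 distance", {
  lobe <- toy_open()
  i44 <- find_atom(lobe, "A", 44, "CG"); i77 <- find_atom(lobe, "A", 77, "CG")
  toward <- lobe$xyz[i77, ] - lobe$xyz[i44, ]
  disp <- 3 * toward / sqrt(sum(toward^2))
  traj <- step_displacement_trajectory(
    lobe, selection(chain = "A", residue_set = 44L,
                    atom_names = c("CB", "CG")),
    displacement = disp, n_frames = 20, event_frame = 11)
  ser <- min_heavy_distance_series(
    traj, contact_def("A", 44, "A", 77, scope = "side-chain-heavy"))
  expect_true(all(ser$values[1:10] == ser$values[1]))
  expect_lt(ser$values[11], ser$values[10] - 2)
  expect_true(all(ser$values[11:20] < ser$values[1] - 2))
})

test_that("the default panel covers the scaffold, expulsion, insertion and MET sets", {
  panel <- default_contact_panel("A")
  labels <- vapply(panel, `[[`, character(1), "label")
  expect_true(all(c("A25-A74", "A25-A77", "A74-A77",         # PHE scaffold
                    "A28-A77", "A28-A41", "A28-A44",         # PHE28 pocket
                    "A44-A77", "A44-A25", "A44-A24",         # VAL44 insertion
                    "A45-A80", "A45-A81", "A80-A81",         # MET triad
                    "A27-A47", "A60-A80", "A81-A48") %in% labels))
  pers <- contact_persistence(static_trajectory(toy_open(), 2), panel)
  expect_equal(nrow(pers), 15L)
  expect_true(all(pers$persistence %in% c(0, 1)))  # static: all-or-nothing
})

test_that("SASA matches the analytic sphere and the two-sphere closed form", {
  one <- make_structure(list(list("C1", "LIG", "X", 1, "C")),
                        matrix(0, 1, 3), hetatm = TRUE)
  expect_equal(sasa_shrake_rupley(one), 4 * pi * 3.1^2, tolerance = 0.01)
  two_far <- make_structure(list(list("C1", "LIG", "X", 1, "C"),
                                 list("C2", "LIG", "X", 2, "C")),
                            rbind(c(0, 0, 0), c(0, 0, 50)), hetatm = TRUE)
  expect_equal(sum(sasa_shrake_rupley(two_far)), 2 * 4 * pi * 3.1^2,
               tolerance = 1e-6)
  # overlapping equal spheres: exposed area 4 pi R^2 - 2 pi R h per atom,
  # with h = R - d/2 the buried cap height (R = r + probe)
  d <- 2.5; R <- 1.7 + 1.4
  two <- make_structure(list(list("C1", "LIG", "X", 1, "C"),
                             list("C2", "LIG", "X", 2, "C")),
                        rbind(c(0, 0, 0), c(0, 0, d)), hetatm = TRUE)
  analytic <- 2 * (4 * pi * R^2 - 2 * pi * R * (R - d / 2))
  expect_equal(sum(sasa_shrake_rupley(two)), analytic, tolerance = 0.02)
  expect_error(sasa_shrake_rupley(
    make_structure(list(list("XX", "LIG", "X", 1, "Xx")), matrix(0, 1, 3))),
    "no vdW radius")
})

test_that("SASA is rigid-invariant and never grows when atoms are added", {
  lobe <- toy_open()
  subset <- which(lobe$atoms$residue_number %in% 24:30)
  base <- sum(sasa_shrake_rupley(lobe, atoms = subset))
  moved <- lobe
  moved$xyz <- rotate_about_axis(lobe$xyz, c(1, 2, 3), c(2, -1, 1), 53) + 7
  expect_equal(sum(sasa_shrake_rupley(moved, atoms = subset)), base,
               tolerance = base * 0.005)
  # adding an atom can only occlude
  set.seed(14)
  for (rep in 1:3) {
    extra_pos <- lobe$xyz[sample(subset, 1), ] + rnorm(3, sd = 2)
    grown <- new_structure(
      rbind(lobe$atoms,
            data.frame(serial = max(lobe$atoms$serial) + 1L,
                       atom_name = "CX", residue_name = "LIG",
                       chain_id = "X", residue_number = 1L, element = "C",
                       alt_loc = NA_character_, hetatm = TRUE)),
      rbind(lobe$xyz, extra_pos))
    expect_lte(sum(sasa_shrake_rupley(grown, atoms = subset)), base + 1e-9)
  }
})

test_that("relative exposure is 1 in isolation, near 0 in an occluding shell", {
  res <- make_structure(list(
    list("N", "ALA", "A", 1, "N"), list("CA", "ALA", "A", 1, "C"),
    list("C", "ALA", "A", 1, "C"), list("O", "ALA", "A", 1, "O"),
    list("CB", "ALA", "A", 1, "C")),
    rbind(c(-1.2, 0.8, 0), c(0, 0, 0), c(1.3, 0.7, 0), c(1.4, 1.9, 0.2),
          c(-0.3, -1, 1)))
  alone <- residue_exposure_series(new_trajectory(res, res$xyz), "A", 1,
                                   n_points = 240)
  expect_equal(alone$values, 1)
  # surround the residue with a dense carbon shell
  shell_pts <- efswitch:::sphere_lattice(500) * 5.5
  shell_atoms <- do.call(rbind, lapply(seq_len(nrow(shell_pts)), function(i)
    data.frame(serial = 10L + i, atom_name = paste0("C", i),
               residue_name = "SHL", chain_id = "S", residue_number = 999L,
               element = "C", alt_loc = NA_character_, hetatm = TRUE)))
  caged <- new_structure(rbind(res$atoms, shell_atoms),
                         rbind(res$xyz, shell_pts))
  buried <- residue_exposure_series(new_trajectory(caged, caged$xyz), "A", 1,
                                    n_points = 240)
  expect_lt(buried$values, 0.05)
  # glycine has no side chain: explicit error
  gly <- res; gly$atoms$residue_name <- "GLY"
  gly <- new_structure(gly$atoms[gly$atoms$atom_name != "CB", ],
                       gly$xyz[gly$atoms$atom_name != "CB", ])
  expect_error(residue_exposure_series(new_trajectory(gly, gly$xyz), "A", 1),
               "no side-chain heavy atoms")
})

test_that("an expulsion event raises the PHE28 side-chain exposure", {
  lobe <- toy_open()
  centroid <- colMeans(lobe$xyz[lobe$atoms$residue_number <= 85, ])
  i28 <- find_atom(lobe, "A", 28, "CG")
  outward <- lobe$xyz[i28, ] - centroid
  disp <- 8 * outward / sqrt(sum(outward^2))
  traj <- step_displacement_trajectory(
    lobe, selection(chain = "A", residue_set = 28L,
                    atom_names = c("CB", "CG")),
    displacement = disp, n_frames = 2, event_frame = 2)
  ser <- residue_exposure_series(traj, "A", 28, n_points = 240)
  expect_gt(ser$values[2], ser$values[1])
  expect_gt(ser$values[2], 0.8)
})
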