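# PDB / xyz-table reading and writing, element inference, alternate
# locations, model handling and selection resolution.

test_that("alpha-carbon and calcium-ion 'CA' atom names resolve to C and Ca", {
  path <- write_fixture_pdb(c(
    pdb_line("ATOM", 1, " CA ", "ALA", "A", 1, 1, 2, 3),
    pdb_line("HETATM", 2, "CA  ", "CA", "A", 101, 4, 5, 6)))
  s <- read_structure(path)
  expect_equal(n_atoms(s), 2L)
  expect_equal(s$atoms$element, c("C", "Ca"))
  expect_equal(count_calcium_ions(s), 1L)
  # explicit element field wins over inference
  path2 <- write_fixture_pdb(
    pdb_line("HETATM", 1, "CA  ", "CA", "A", 1, 0, 0, 0, element = "CA"))
  expect_equal(read_structure(path2)$atoms$element, "Ca")
})

test_that("requested MODEL is returned and absent models raise a listing error", {
  path <- write_fixture_pdb(c(
    "MODEL        1",
    pdb_line("ATOM", 1, " CA ", "ALA", "A", 1, 1, 0, 0),
    "ENDMDL",
    "MODEL        2",
    pdb_line("ATOM", 1, " CA ", "ALA", "A", 1, 9, 0, 0),
    "ENDMDL"))
  expect_equal(read_structure(path, model = 1)$xyz[1, 1], 1)
  expect_equal(read_structure(path, model = 2)$xyz[1, 1], 9)
  expect_error(read_structure(path, model = 3), "available models: 1, 2")
})

test_that("alternate locations keep the highest occupancy, ties toward A", {
  path <- write_fixture_pdb(c(
    pdb_line("ATOM", 1, " CA ", "ALA", "A", 1, 1, 0, 0, alt = "A", occ = 0.4),
    pdb_line("ATOM", 2, " CA ", "ALA", "A", 1, 2, 0, 0, alt = "B", occ = 0.6),
    pdb_line("ATOM", 3, " CB ", "ALA", "A", 1, 3, 0, 0, alt = "A", occ = 0.5),
    pdb_line("ATOM", 4, " CB ", "ALA", "A", 1, 4, 0, 0, alt = "B", occ = 0.5)))
  s <- read_structure(path)
  expect_equal(n_atoms(s), 2L)
  expect_equal(s$xyz[s$atoms$atom_name == "CA", 1], 2)  # occupancy 0.6 wins
  expect_equal(s$xyz[s$atoms$atom_name == "CB", 1], 3)  # tie -> altLoc A
})

test_that("malformed fixed-width records raise an error naming the line", {
  good <- pdb_line("ATOM", 1, " CA ", "ALA", "A", 1, 1, 0, 0)
  bad <- sub("   1.000", "  1.0.00", good, fixed = TRUE)
  path <- write_fixture_pdb(c(good, bad))
  expect_error(read_structure(path), "line 2")
  short <- write_fixture_pdb(c(good, "ATOM      2  CB"))
  expect_error(read_structure(short), "line 2")
})

test_that("multi-model trajectories read with F frames and strict atom checks", {
  lines <- unlist(lapply(1:3, function(m) c(
    sprintf("MODEL     %4d", m),
    pdb_line("ATOM", 1, " CA ", "ALA", "A", 1, m, 0, 0),
    pdb_line("ATOM", 2, " CA ", "ALA", "A", 2, m + 1, 0, 0),
    "ENDMDL")))
  path <- write_fixture_pdb(lines)
  traj <- read_trajectory(path)
  expect_equal(n_frames(traj), 3L)
  expect_equal(traj$coords[, 1, 1], c(1, 2, 3))
  # single-model PDB reads as a 1-frame trajectory equal to read_structure
  p1 <- write_fixture_pdb(pdb_line("ATOM", 1, " CA ", "ALA", "A", 1, 1, 2, 3))
  t1 <- read_trajectory(p1)
  expect_equal(n_frames(t1), 1L)
  expect_equal(t1$coords[1, , ], read_structure(p1)$xyz[1, ])
  # mismatched atom count across models names the offending model
  bad <- write_fixture_pdb(c(
    "MODEL        1",
    pdb_line("ATOM", 1, " CA ", "ALA", "A", 1, 1, 0, 0),
    "ENDMDL",
    "MODEL        2",
    pdb_line("ATOM", 1, " CA ", "ALA", "A", 1, 1, 0, 0),
    pdb_line("ATOM", 2, " CB ", "ALA", "A", 1, 2, 0, 0),
    "ENDMDL"))
  expect_error(read_trajectory(bad), "model 2 has 2 atoms")
})

test_that("PDB round-trip preserves keys, order and coordinates to 3 decimals", {
  traj <- morph_trajectory(toy_open(), toy_closed(), 5)
  path <- tempfile(fileext = ".pdb")
  write_trajectory(traj, path)
  back <- read_trajectory(path)
  expect_equal(n_frames(back), 5L)
  expect_identical(back$atoms, traj$atoms)
  expect_identical(
    paste(back$topology$atoms$chain_id, back$topology$atoms$residue_number,
          back$topology$atoms$atom_name),
    paste(traj$topology$atoms$chain_id, traj$topology$atoms$residue_number,
          traj$topology$atoms$atom_name))
  expect_lt(max(abs(back$coords - traj$coords)), 5.01e-4)
  expect_identical(back$topology$atoms$element, traj$topology$atoms$element)
})

test_that("parsed fixtures agree with the bio3d reader", {
  traj <- morph_trajectory(toy_open(), toy_closed(), 3)
  path <- tempfile(fileext = ".pdb")
  write_trajectory(traj, path)
  ref <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  mine <- read_trajectory(path)
  expect_equal(nrow(ref$atom), n_atoms(mine$topology))
  expect_identical(ref$atom$elety, mine$topology$atoms$atom_name)
  expect_identical(ref$atom$resno, mine$topology$atoms$residue_number)
  expect_lt(max(abs(matrix(ref$xyz[2, ], ncol = 3, byrow = TRUE) -
                      mine$coords[2, , ])), 1e-9)
})

test_that("xyz-table round-trips bitwise at printed precision", {
  traj <- morph_trajectory(toy_open(), toy_closed(), 3)
  path <- tempfile(fileext = ".xyz")
  write_trajectory(traj, path, format = "xyz")
  back <- read_trajectory(path, format = "xyz", topology = traj$topology)
  expect_equal(n_frames(back), 3L)
  expect_lt(max(abs(back$coords - traj$coords)), 5.01e-7)
  path2 <- tempfile(fileext = ".xyz")
  write_trajectory(back, path2, format = "xyz")
  expect_identical(readLines(path2), readLines(path))
})

test_that("coordinates exceeding the PDB field width refuse to write", {
  s <- make_structure(list(list("CA", "ALA", "A", 1, "C")),
                      matrix(c(100000, 0, 0), 1, 3))
  expect_error(write_trajectory(new_trajectory(s, s$xyz), tempfile(),
                                format = "pdb"),
               "field width")
})

test_that("selection resolution is order-stable, idempotent and warns on gaps", {
  lobe <- toy_open()
  sel <- selection(chain = "A", residue_range = c(5, 80), atom_names = "CA")
  idx <- suppressWarnings(resolve_selection(lobe, sel))
  expect_length(idx, 76L)
  expect_false(is.unsorted(idx))
  expect_identical(as.integer(idx),
                   as.integer(suppressWarnings(resolve_selection(lobe, sel))))
  # request order never matters: set {10, 7} comes back in topology order
  idx2 <- resolve_selection(lobe, selection(chain = "A",
                                            residue_set = c(10L, 7L),
                                            atom_names = "CA"))
  expect_identical(lobe$atoms$residue_number[idx2], c(7L, 10L))
  # absent residues are skipped with a warning carrying the count
  expect_warning(
    idx3 <- resolve_selection(lobe, selection(chain = "A",
                                              residue_set = c(10L, 500L))),
    "1 requested residue")
  expect_equal(attr(idx3, "n_missing_residues"), 1L)
  # empty resolution is representable, and an explicit error when required
  empty <- resolve_selection(lobe, selection(chain = "Z"))
  expect_length(empty, 0L)
  expect_error(resolve_selection(lobe, selection(chain = "Z"),
                                 require_atoms = 1L),
               "at least 1 required")
})

test_that("chain maps validate against the structure they describe", {
  lobe <- toy_open()
  expect_silent(validate_chain_map(chain_map(tnc = "A"), lobe))
  expect_error(validate_chain_map(chain_map(tnc = "Q"), lobe), "chain 'Q'")
  expect_error(chain_map(tnc = "A", tni = "A"), "distinct")
})
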