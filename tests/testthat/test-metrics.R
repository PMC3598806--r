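# Pocket openness, windowed statistics, state classification, site
# expansion and prong distances.

test_that("pocket openness is the per-frame Calpha-Calpha distance", {
  s <- make_structure(list(list("CA", "GLU", "T", 16, "C"),
                           list("CA", "LEU", "T", 48, "C")),
                      rbind(c(0, 0, 0), c(0, 23.9, 0)))
  ser <- pocket_openness_series(new_trajectory(s, s$xyz), chain = "T")
  expect_equal(ser$values, 23.9)
  expect_equal(ser$unit, "angstrom")
  expect_setequal(ser$anchors, c("T:16:CA", "T:48:CA"))
  expect_error(pocket_openness_series(new_trajectory(s, s$xyz),
                                      res_b = 49, chain = "T"),
               "residue 49")
})

test_that("a noise-free open->closed morph yields a strictly decreasing d", {
  traj <- morph_trajectory(toy_open(), toy_closed(), 50)
  d <- pocket_openness_series(traj, chain = "A")$values
  expect_true(all(diff(d) < 0))
  expect_equal(d[1], 23.9, tolerance = 1e-9)
  expect_equal(d[50], 13.4, tolerance = 1e-9)
  # linear interpolation of collinear anchors gives a linear series
  expect_lt(max(abs(diff(d, differences = 2))), 1e-9)
})

test_that("window statistics use the sample SD and clip frame ranges", {
  expect_equal(unname(window_stats(c(1, 2, 3))[c("mean", "sd")]), c(2, 1))
  expect_equal(unname(window_stats(rep(4.2, 10))["sd"]), 0)
  v <- rnorm(20)
  expect_equal(window_stats(v, list(last_n_frames = 20)),
               window_stats(v, "all"))
  expect_equal(unname(window_stats(v, list(frame_range = c(18, 99)))["n"]), 3)
  expect_error(window_stats(v, list(frame_range = c(25, 30))), "empty window")
  # mean of a linear ramp equals the midpoint of the window endpoints
  ramp <- seq(2, 12, length.out = 101)
  expect_equal(unname(window_stats(ramp, list(frame_range = c(11, 31)))["mean"]),
               (ramp[11] + ramp[31]) / 2, tolerance = 1e-9)
})

test_that("state classification separates the reported condition means", {
  # trajectory-mean pocket distances reported for the crystal-derived
  # conditions: closed apo TnC, semi-closed saturated TnC, open Tn with TnI
  expect_equal(classify_pocket_state(13.65), "closed")
  expect_equal(classify_pocket_state(13.23), "closed")
  expect_equal(classify_pocket_state(15.74), "semi-closed")
  expect_equal(classify_pocket_state(16.48), "semi-closed")
  expect_equal(classify_pocket_state(15.18), "semi-closed")
  expect_equal(classify_pocket_state(23.87), "open")
  expect_equal(classify_pocket_state(23.75), "open")
  expect_error(classify_pocket_state(-1), "non-negative")
  expect_error(pocket_state_thresholds(18, 14.5), "closed_max")
})

test_that("state classification is monotone in mean d", {
  lvl <- c(closed = 1, `semi-closed` = 2, open = 3)
  labels <- vapply(seq(0, 30, by = 0.25), classify_pocket_state, character(1))
  expect_true(all(diff(lvl[labels]) >= 0))
})

test_that("site expansion measures loop position 1 to position 12 and scales", {
  s <- make_structure(list(list("CA", "ASP", "T", 29, "C"),
                           list("CA", "GLU", "T", 40, "C")),
                      rbind(c(0, 0, 0), c(10, 0, 0)))
  site <- ef_site("I", chain = "T")
  expect_equal(site_expansion_series(new_trajectory(s, s$xyz), site)$values, 10)
  dilated <- s; dilated$xyz <- s$xyz * 1.1
  expect_equal(site_expansion_series(new_trajectory(dilated, dilated$xyz),
                                     site)$values, 11)
})

test_that("both toy binding sites expand on the open -> closed transition", {
  o <- toy_open(); cl <- toy_closed()
  for (site in list(ef_site("I", chain = "A"), ef_site("II", chain = "A"))) {
    eo <- site_expansion_series(new_trajectory(o, o$xyz), site)$values
    ec <- site_expansion_series(new_trajectory(cl, cl$xyz), site)$values
    expect_gt(ec, eo)
  }
})

test_that("ef_site defaults follow the 12-residue loop layout", {
  s1 <- ef_site("I", chain = "A")
  expect_equal(s1$loop_residues, 29:40)
  expect_equal(s1$position2_residue, 30L)
  expect_equal(s1$position9_residue, 37L)
  expect_equal(s1$position12_residue, 40L)
  expect_equal(s1$ligand_positions, c(1L, 3L, 7L, 12L))
  s2 <- ef_site("II", chain = "A")
  expect_equal(s2$loop_residues, 65:76)
  expect_equal(s2$ligand_positions, c(1L, 3L, 5L, 7L, 12L))  # +position 5
  expect_error(ef_site("III", chain = "A"), "no default")
})

test_that("prong series take the minimum over the two carboxylate oxygens", {
  s <- make_structure(list(
    list("N", "ALA", "T", 30, "N"), list("N", "SER", "T", 37, "N"),
    list("CD", "GLU", "T", 40, "C"), list("OE1", "GLU", "T", 40, "O"),
    list("OE2", "GLU", "T", 40, "O")),
    rbind(c(0, 0, 0), c(8, 0, 0), c(0, 1, 2), c(0, 0, 2.8), c(0, 0, 3.4)))
  ser <- prong_distance_series(new_trajectory(s, s$xyz),
                               ef_site("I", chain = "T"))
  expect_named(ser, c("N2_OE", "N2_CD", "N9_OE", "N9_CD"))
  expect_equal(ser$N2_OE$values, 2.8)
  expect_equal(ser$N2_CD$values, sqrt(5))
  # non-glutamate at position 12 fails loudly
  s2 <- make_structure(list(list("N", "ALA", "T", 30, "N"),
                            list("CA", "ALA", "T", 40, "C")),
                       rbind(c(0, 0, 0), c(5, 0, 0)))
  expect_error(prong_distance_series(new_trajectory(s2, s2$xyz),
                                     ef_site("I", chain = "T")),
               "position-12 residue 40")
})

test_that("toy prongs are formed when open and released when closed", {
  o <- toy_open(); cl <- toy_closed()
  for (site in list(ef_site("I", chain = "A"), ef_site("II", chain = "A"))) {
    po <- prong_distance_series(new_trajectory(o, o$xyz), site)
    pc <- prong_distance_series(new_trajectory(cl, cl$xyz), site)
    expect_lt(po$N2_OE$values, 3)
    expect_lt(po$N9_OE$values, 3)
    expect_gt(pc$N2_OE$values, 3.5)
    expect_gt(pc$N9_OE$values, 3.5)
  }
})

test_that("a scheduled prong release crosses 3.5 A exactly at the event frame", {
  o <- toy_open()
  traj <- step_displacement_trajectory(
    o, selection(chain = "A", residue_set = 40L,
                 atom_names = c("CD", "OE1", "OE2")),
    displacement = c(0, 0, 6), n_frames = 40, event_frame = 21)
  ser <- prong_distance_series(traj, ef_site("I", chain = "A"))$N2_OE
  expect_true(all(ser$values[1:20] < 3.5))
  expect_true(all(ser$values[21:40] > 3.5))
})

test_that("distance series are invariant under global rigid motion", {
  traj <- morph_trajectory(toy_open(), toy_closed(), 8)
  moved <- rigidly_move_trajectory(traj)
  expect_equal(pocket_openness_series(moved, chain = "A")$values,
               pocket_openness_series(traj, chain = "A")$values,
               tolerance = 1e-9)
  site <- ef_site("II", chain = "A")
  expect_equal(site_expansion_series(moved, site)$values,
               site_expansion_series(traj, site)$values, tolerance = 1e-9)
  expect_equal(prong_distance_series(moved, site)$N9_OE$values,
               prong_distance_series(traj, site)$N9_OE$values,
               tolerance = 1e-9)
})
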