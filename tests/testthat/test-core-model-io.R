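test_that("box validation accepts orthorhombic and rejects degenerate boxes", {
  expect_equal(as.numeric(hb_box(c(3, 3, 3))), c(3, 3, 3))
  expect_error(hb_box(c(0, 3, 3)), "positive")
  expect_error(hb_box(c(3, 3)), "three")
  # 9-component GRO box with off-diagonal terms is triclinic
  expect_error(hb_box(c(3, 3, 3, 0, 0, 0.5, 0, 0, 0)), "triclinic")
  expect_equal(as.numeric(hb_box(c(3, 4, 5, 0, 0, 0, 0, 0, 0))), c(3, 4, 5))
})

test_that("topology invariants are enforced per molecule", {
  atoms <- data.frame(atom_id = 0:3, molecule_id = c(0, 0, 0, 0),
                      name = c("OA", "HO", "OE", "CT"),
                      element = c("O", "H", "O", "C"),
                      role = c("OH_oxygen", "OH_hydrogen", "OE_oxygen",
                               "terminal_carbon"))
  expect_s3_class(hb_topology(atoms, n_separation = 3), "hb_topology")
  # two hydroxyl oxygens in one molecule
  bad <- atoms; bad$role[3] <- "OH_oxygen"
  expect_error(hb_topology(bad, n_separation = 0), "molecule 0.*OH_oxygen")
  # n_separation inconsistent with ether-oxygen presence
  expect_error(hb_topology(atoms, n_separation = 0), "OE_oxygen is present")
  no_oe <- atoms; no_oe$role[3] <- "other"
  expect_error(hb_topology(no_oe, n_separation = 3), "no OE_oxygen")
  # non-dense atom ids
  shifted <- atoms; shifted$atom_id <- c(0, 1, 2, 4)
  expect_error(hb_topology(shifted, n_separation = 3), "dense")
})

test_that("trajectory requires uniform dt and a shared box", {
  mk <- function(t) hb_frame(t, matrix(0, 1, 3), hb_box(c(3, 3, 3)))
  expect_error(hb_trajectory(list(mk(0), mk(10), mk(25))), "not uniform")
  expect_error(hb_trajectory(list(mk(0), mk(0))), "strictly increasing")
  traj <- hb_trajectory(list(mk(0), mk(10), mk(20)))
  expect_equal(traj$dt, 10)
  f2 <- hb_frame(10, matrix(0, 1, 3), hb_box(c(4, 3, 3)))
  expect_error(hb_trajectory(list(mk(0), f2)), "share one box")
})

test_that("GRO parsing reads the documented two-atom body", {
  lines <- c("demo", "    2",
             "    1OCT     OA    1   0.000   0.000   0.000",
             "    1OCT     HO    2   0.100   0.000   0.000",
             "   3.0 3.0 3.0")
  f <- tempfile(fileext = ".gro")
  writeLines(lines, f)
  gro <- read_gro(f)
  expect_equal(nrow(gro$frame$coordinates), 2)
  expect_equal(as.numeric(gro$frame$box), c(3, 3, 3))
  expect_equal(gro$frame$coordinates[2, 1], 0.1)
  expect_equal(gro$topology$atoms$name, c("OA", "HO"))
  expect_equal(gro$topology$atoms$molecule_id, c(0L, 0L))

  writeLines(c(lines[1:4], "   0.0 0.0 0.0"), f)
  expect_error(read_gro(f), "box")
  writeLines(c("demo", "    2", lines[3], "garbage line here", lines[5]), f)
  expect_error(read_gro(f), "line 4")
})

test_that("GRO write -> read round-trips within format precision and is byte-stable", {
  scene <- make_planted_scene(planted_scene_spec(seed = 4, chain = c(4),
                                                 double_dimer = 1))
  f1 <- tempfile(fileext = ".gro")
  f2 <- tempfile(fileext = ".gro")
  write_gro(scene$frame, scene$topology, f1)
  rt <- read_gro(f1)
  expect_lt(max(abs(rt$frame$coordinates - scene$frame$coordinates)), 1e-3)
  write_gro(rt$frame, rt$topology, f2)
  rt2 <- read_gro(f2)
  write_gro(rt2$frame, rt2$topology, f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("XYZ multi-frame round trip preserves coordinates and times", {
  ig <- make_ideal_gas(5, hb_box(c(2, 2, 2)), n_frames = 3, dt = 5, seed = 2)
  f <- tempfile(fileext = ".xyz")
  write_xyz(ig$trajectory, ig$topology, f)
  back <- read_xyz(f, box = hb_box(c(2, 2, 2)))
  expect_equal(length(back$frames), 3)
  expect_equal(back$dt, 5)
  expect_lt(max(abs(back$frames[[2]]$coordinates -
                      ig$trajectory$frames[[2]]$coordinates)), 1e-6)
  expect_error(read_xyz(f, box = NULL), "box")
})

test_that("series reader tolerates xvg-style comments", {
  f <- tempfile(fileext = ".xvg")
  writeLines(c("# comment", "@ xaxis label", "0 1.5 2.5", "10 1.6 2.6"), f)
  s <- read_series(f, col_names = c("a", "b"))
  expect_equal(s$time, c(0, 10))
  expect_equal(s$b, c(2.5, 2.6))
  expect_equal(hbondnet:::series_dt(s), 10)
})

test_that("role map assignment validates and flags bad molecules", {
  lines <- c("demo", "    4",
             "    1MOL     OA    1   0.000   0.000   0.000",
             "    1MOL     HO    2   0.100   0.000   0.000",
             "    1MOL     OE    3   0.600   0.000   0.000",
             "    1MOL     CT    4   0.900   0.000   0.000",
             "   3.0 3.0 3.0")
  f <- tempfile(fileext = ".gro")
  writeLines(lines, f)
  skel <- read_gro(f)$topology
  rm_ok <- c(OA = "OH_oxygen", HO = "OH_hydrogen", OE = "OE_oxygen",
             CT = "terminal_carbon")
  topo <- apply_role_map(skel, rm_ok, n_separation = 3)
  expect_equal(topo$atoms$role,
               c("OH_oxygen", "OH_hydrogen", "OE_oxygen", "terminal_carbon"))
  # two atoms mapped to OH_oxygen in the same molecule
  rm_bad <- c(OA = "OH_oxygen", HO = "OH_hydrogen", OE = "OH_oxygen",
              CT = "terminal_carbon")
  expect_error(apply_role_map(skel, rm_bad, n_separation = 3), "molecule 0")
  # ether oxygen present but declared n_separation = 0
  expect_error(apply_role_map(skel, rm_ok, n_separation = 0), "OE_oxygen")
})

test_that("run config parser handles sections, role maps and numbers", {
  f <- tempfile(fileext = ".cfg")
  writeLines(c("# run", "role_map = OA:OH_oxygen, HO:OH_hydrogen",
               "[criteria]", "distance = 0.30", "angle = 30",
               "[simulate]", "chain = 3 3 5"), f)
  cfg <- read_run_config(f)
  expect_equal(unname(cfg$role_map["OA"]), "OH_oxygen")
  expect_equal(cfg$criteria.distance, 0.30)
  expect_equal(cfg$simulate.chain, c(3, 3, 5))
})

test_that("minimum imaging matches hand arithmetic", {
  box <- hb_box(c(3, 3, 3))
  # 0.05 -> 2.80 wraps backwards across the boundary: -0.25
  expect_equal(min_image_vector(c(0.05, 0, 0), c(2.80, 0, 0), box),
               c(-0.25, 0, 0))
  expect_equal(min_image_distance(c(0.05, 0, 0), c(2.80, 0, 0), box), 0.25)
  expect_equal(min_image_vector(c(1, 1, 1), c(1, 1, 1), box), c(0, 0, 0))
  expect_equal(min_image_vector(c(0, 0, 0), c(1.4, 0, 0), box),
               c(1.4, 0, 0))   # no wrap inside half box
})

test_that("minimum-image norm never exceeds (sqrt(3)/2) max box edge", {
  set.seed(1)
  box <- hb_box(c(2, 3, 5))
  for (i in 1:200) {
    a <- runif(3, -10, 10)
    b <- runif(3, -10, 10)
    expect_lte(min_image_distance(a, b, box), sqrt(3) / 2 * 5 + 1e-12)
  }
})

test_that("angles at a vertex cover collinear, right-angle and opposite cases", {
  box <- hb_box(c(10, 10, 10))
  v <- c(5, 5, 5)
  expect_equal(angle_at(v, v + c(1, 0, 0), v + c(2, 0, 0), box), 0)
  expect_equal(angle_at(v, v + c(1, 0, 0), v + c(0, 1, 0), box), 90)
  expect_equal(angle_at(v, v + c(1, 0, 0), v + c(-1, 0, 0), box), 180)
  expect_error(angle_at(v, v, v + c(1, 0, 0), box), "zero-length")
})

test_that("lattice translation leaves bond counts, networks and RDFs unchanged", {
  scene <- make_planted_scene(planted_scene_spec(
    seed = 3, double_dimer = 2, ring = 4, chain = 3, intra_bonded = 2))
  L <- as.numeric(scene$frame$box)
  shifted <- scene
  shifted$frame$coordinates <- sweep(scene$frame$coordinates, 2,
                                     c(2 * L[1], -L[2], 3 * L[3]), "+")
  b0 <- detect_hbonds(scene$frame, scene$topology)
  b1 <- detect_hbonds(shifted$frame, shifted$topology)
  expect_identical(b0, b1)
  s0 <- frame_network_stats(build_graph(b0, scene$topology))
  s1 <- frame_network_stats(build_graph(b1, shifted$topology))
  expect_identical(s0, s1)
  # RDF translation invariance checked on generic positions (planted
  # separations sit exactly on shared bin edges, where the last-ulp shift
  # of a lattice translation could flip a bin)
  ig <- make_ideal_gas(N = 150, box = hb_box(c(4, 4, 4)), n_frames = 4,
                       seed = 11)
  sh_frames <- lapply(ig$trajectory$frames, function(f) {
    hb_frame(f$time, sweep(f$coordinates, 2, c(8, -4, 12), "+"), f$box)
  })
  r0 <- rdf(ig$trajectory, ig$topology, "all", "all", bin_width = 0.01)
  r1 <- rdf(hb_trajectory(sh_frames), ig$topology, "all", "all",
            bin_width = 0.01)
  expect_equal(r0$g, r1$g)
})
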