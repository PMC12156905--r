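# Hand-built two-molecule system: molecule 0 donates from the origin along
# +x, molecule 1 offers a hydroxyl-oxygen acceptor at `acceptor_pos` (its
# own hydrogen points away along +y so no reverse bond forms).
two_mol_system <- function(acceptor_pos, h_pos = c(0.1, 0, 0), box_L = 3) {
  atoms <- data.frame(
    atom_id = 0:3, molecule_id = c(0L, 0L, 1L, 1L),
    name = c("OA", "HO", "OA", "HO"), element = c("O", "H", "O", "H"),
    role = c("OH_oxygen", "OH_hydrogen", "OH_oxygen", "OH_hydrogen"),
    stringsAsFactors = FALSE)
  coords <- rbind(c(0, 0, 0), h_pos, acceptor_pos,
                  acceptor_pos + c(0, 0.1, 0))
  list(topology = hb_topology(atoms, n_separation = 0L),
       frame = hb_frame(0, coords, hb_box(rep(box_L, 3))))
}

test_that("criteria validation rejects out-of-range cutoffs", {
  expect_error(hbond_criteria(max_da_distance = 0), "0, 1")
  expect_error(hbond_criteria(max_da_distance = 1.5), "0, 1")
  expect_error(hbond_criteria(max_angle_deviation = 120), "0, 90")
  expect_equal(hbond_criteria()$max_da_distance, 0.30)
  expect_equal(hbond_criteria()$max_angle_deviation, 30)
})

test_that("collinear donor-H-acceptor at 0.29 nm is one OH-OH bond", {
  sys <- two_mol_system(c(0.29, 0, 0))
  bonds <- detect_hbonds(sys$frame, sys$topology)
  expect_equal(nrow(bonds), 1)
  expect_equal(bonds$class, "inter_OH_OH")
  expect_equal(bonds$donor_O, 0L)
  expect_equal(bonds$acceptor_O, 2L)
})

test_that("distance and angle criteria reject near-miss geometries", {
  # 0.31 nm: just beyond the distance cutoff
  sys <- two_mol_system(c(0.31, 0, 0))
  expect_equal(nrow(detect_hbonds(sys$frame, sys$topology)), 0)
  # 0.25 nm but 45 degrees off the O-H direction
  sys <- two_mol_system(0.25 * c(cos(45 * pi / 180), sin(45 * pi / 180), 0))
  expect_equal(nrow(detect_hbonds(sys$frame, sys$topology)), 0)
  # same geometry passes at a 50-degree cutoff
  wide <- hbond_criteria(max_angle_deviation = 50)
  expect_equal(nrow(detect_hbonds(sys$frame, sys$topology, wide)), 1)
})

test_that("intramolecular OH->OE pairs are classified by molecule identity", {
  atoms <- data.frame(atom_id = 0:2, molecule_id = 0L,
                      name = c("OA", "HO", "OE"), element = c("O", "H", "O"),
                      role = c("OH_oxygen", "OH_hydrogen", "OE_oxygen"))
  topo <- hb_topology(atoms, n_separation = 3)
  # minimum-image distance 0.28 through the periodic boundary (the ether
  # oxygen sits at x = 2.72 in a 3 nm box, i.e. at -0.28), angle ~10 deg
  dir10 <- c(-cos(10 * pi / 180), sin(10 * pi / 180), 0)
  frame <- hb_frame(0, rbind(c(0, 0, 0), 0.1 * dir10, c(2.72, 0, 0)),
                    hb_box(c(3, 3, 3)))
  bonds <- detect_hbonds(frame, topo)
  expect_equal(bonds$class, "intra_OH_OE")
})

test_that("both angle conventions agree with the brute-force scan on dense frames", {
  set.seed(101)
  for (convention in c("ADH_at_donor", "DHA_deviation")) {
    crit <- hbond_criteria(angle_convention = convention)
    for (rep in 1:10) {
      sys <- random_dense_frame(sample(4:12, 1))
      got <- detect_hbonds(sys$frame, sys$topology, crit)
      want <- oracle_hbonds(sys$frame, sys$topology, crit)
      expect_equal(got, want, info = paste(convention, "rep", rep))
    }
  }
})

test_that("detection is deterministic and invariant under 90-degree rotations", {
  scene <- make_planted_scene(planted_scene_spec(
    seed = 6, double_dimer = 3, chain = c(3, 4), ring = 5, intra_bonded = 2))
  b1 <- detect_hbonds(scene$frame, scene$topology)
  b2 <- detect_hbonds(scene$frame, scene$topology)
  expect_identical(b1, b2)
  # rotate (x, y, z) -> (y, L - x, z) about the cubic box axis
  L <- as.numeric(scene$frame$box)[1]
  rot <- scene$frame$coordinates[, c(2, 1, 3)]
  rot[, 2] <- L - rot[, 2]
  fr <- hb_frame(0, rot, scene$frame$box)
  b3 <- detect_hbonds(fr, scene$topology)
  expect_equal(table(b3$class), table(b1$class))
  expect_equal(nrow(find_dimers(b3)), nrow(find_dimers(b1)))
})

test_that("per-class counts average over all frames including empty ones", {
  tab <- rbind(
    data.frame(frame = 0L, donor_O = 0L, donor_H = 1L, acceptor_O = 4L,
               donor_mol = 0L, acceptor_mol = 1L, class = "inter_OH_OH"),
    data.frame(frame = 0L, donor_O = 4L, donor_H = 5L, acceptor_O = 0L,
               donor_mol = 1L, acceptor_mol = 0L, class = "inter_OH_OH"),
    data.frame(frame = 0L, donor_O = 8L, donor_H = 9L, acceptor_O = 0L,
               donor_mol = 2L, acceptor_mol = 0L, class = "inter_OH_OH"),
    data.frame(frame = 1L, donor_O = 0L, donor_H = 1L, acceptor_O = 4L,
               donor_mol = 0L, acceptor_mol = 1L, class = "inter_OH_OH"),
    data.frame(frame = 1L, donor_O = 4L, donor_H = 5L, acceptor_O = 0L,
               donor_mol = 1L, acceptor_mol = 0L, class = "inter_OH_OH"),
    data.frame(frame = 1L, donor_O = 8L, donor_H = 9L, acceptor_O = 0L,
               donor_mol = 2L, acceptor_mol = 0L, class = "inter_OH_OH"),
    data.frame(frame = 1L, donor_O = 12L, donor_H = 13L, acceptor_O = 0L,
               donor_mol = 3L, acceptor_mol = 0L, class = "inter_OH_OH"),
    data.frame(frame = 1L, donor_O = 16L, donor_H = 17L, acceptor_O = 0L,
               donor_mol = 4L, acceptor_mol = 0L, class = "inter_OH_OH"))
  cc <- count_by_class(tab, n_frames = 2)
  expect_equal(cc$mean[cc$class == "inter_OH_OH"], 4)     # (3 + 5) / 2
  expect_equal(cc$mean[cc$class == "intra_OH_OE"], 0)
  # total mean equals the sum of class means
  expect_equal(cc$mean[cc$class == "total"],
               sum(cc$mean[cc$class != "total"]))
  empty <- count_by_class(hbondnet:::empty_bond_table(), n_frames = 3)
  expect_true(all(empty$mean == 0))
})

test_that("dimer census requires reciprocal OH->OE bonds in the same frame", {
  scene <- make_planted_scene(planted_scene_spec(seed = 8, double_dimer = 7,
                                                 chain = c(3, 3, 3)))
  bonds <- detect_hbonds(scene$frame, scene$topology)
  d <- find_dimers(bonds)
  expect_equal(nrow(d), 7)
  expect_true(all(d$mol_a < d$mol_b))
  # dropping one direction of a reciprocal pair kills that dimer
  oe_rows <- which(bonds$class == "inter_OH_OE")
  expect_equal(nrow(find_dimers(bonds[-oe_rows[1], ])), 6)
  # single-direction OH->OE only
  single <- make_planted_scene(planted_scene_spec(seed = 1, pair_OH_OE = 3))
  expect_equal(nrow(find_dimers(detect_hbonds(single$frame, single$topology))), 0)
})

test_that("dimer count never exceeds half the inter OH-OE bond count", {
  for (seed in 1:8) {
    scene <- make_planted_scene(random_scene_spec(seed + 300))
    bonds <- detect_hbonds(scene$frame, scene$topology)
    expect_lte(nrow(find_dimers(bonds)),
               sum(bonds$class == "inter_OH_OE") / 2)
  }
})

test_that("triplets chain through a shared middle oxygen", {
  # planted bent triplet carries the designed O1-O3 separation
  scene <- make_planted_scene(planted_scene_spec(seed = 5, triplet = 1))
  bonds <- detect_hbonds(scene$frame, scene$topology)
  tr <- find_triplets(bonds, scene$frame)
  expect_equal(nrow(tr), 1)
  expect_equal(tr$o1_o3_distance, 0.47, tolerance = 1e-6)
  # a single bond yields no triplet
  pair <- make_planted_scene(planted_scene_spec(seed = 5, pair_OH_OH = 1))
  pb <- detect_hbonds(pair$frame, pair$topology)
  expect_equal(nrow(find_triplets(pb, pair$frame)), 0)
  # a 3-ring yields one triplet per middle molecule
  ring <- make_planted_scene(planted_scene_spec(seed = 5, ring = 3))
  rb <- detect_hbonds(ring$frame, ring$topology)
  expect_equal(nrow(find_triplets(rb, ring$frame)), 3)
})

test_that("bond tables round-trip through CSV", {
  scene <- make_planted_scene(planted_scene_spec(seed = 2, chain = 3))
  bonds <- detect_hbonds(scene$frame, scene$topology)
  f <- tempfile(fileext = ".csv")
  write_bond_table(bonds, f)
  expect_equal(read_bond_table(f), bonds)
})
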