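# Two-particle topology helper: particles are separate molecules.
particle_pair_traj <- function(pos_a, pos_b, box_L = 4, n_frames = 1) {
  atoms <- data.frame(atom_id = 0:1, molecule_id = 0:1, name = "P",
                      element = "X", role = "other")
  topo <- hb_topology(atoms, strict = FALSE)
  frames <- lapply(seq_len(n_frames) - 1, function(i) {
    hb_frame(i, rbind(pos_a, pos_b), hb_box(rep(box_L, 3)))
  })
  list(trajectory = hb_trajectory(frames, dt = 1), topology = topo)
}

test_that("a rigid pair puts all density in the bin containing its separation", {
  sys <- particle_pair_traj(c(1, 1, 1), c(1.5, 1, 1), n_frames = 5)
  r <- rdf(sys$trajectory, sys$topology, "all", "all", bin_width = 0.02,
           r_max = 1.8)
  hot <- which(r$g > 0)
  expect_length(hot, 1)
  expect_true(r$r[hot] > 0.48 && r$r[hot] < 0.52)
})

test_that("single-pair normalisation matches the hand formula", {
  # one A-B pair at separation d in volume V: g(bin k) = 1 / (4 pi r_k^2 dr / V)
  sys <- particle_pair_traj(c(1, 1, 1), c(1.5, 1, 1))
  bw <- 0.02
  r <- rdf(sys$trajectory, sys$topology, 0L, 1L, bin_width = bw, r_max = 1.8)
  k <- which(r$counts > 0)
  V <- 4^3
  expect_equal(r$g[k], 1 / (4 * pi * r$r[k]^2 * bw / V))
})

test_that("ideal gas is flat at unity and obeys the shell sum rule", {
  ig <- make_ideal_gas(N = 400, box = hb_box(c(4, 4, 4)), n_frames = 30,
                       seed = 5)
  r <- rdf(ig$trajectory, ig$topology, "all", "all", bin_width = 0.05,
           r_max = 1.8)
  mid <- r$r > 0.3 & r$r < 1.8
  expect_lt(max(abs(r$g[mid] - 1)), 0.05)
  # sum rule: integrating rho * g * 4 pi r^2 dr recovers the neighbour count
  rho <- 400 / 4^3
  expected_neighbours <- 4 / 3 * pi * r$r_max^3 * rho * (399 / 400)
  got <- sum(rho * r$g * 4 * pi * r$r^2 * r$bin_width) * (399 / 400)
  expect_equal(got, expected_neighbours, tolerance = 0.02)
})

test_that("r_max beyond half the box edge is rejected", {
  ig <- make_ideal_gas(N = 10, box = hb_box(c(4, 4, 4)), n_frames = 1, seed = 1)
  expect_error(rdf(ig$trajectory, ig$topology, "all", "all", r_max = 2.5),
               "half the smallest box edge")
})

test_that("exclusion and its complement conserve the raw histogram", {
  scene <- make_planted_scene(planted_scene_spec(seed = 17, double_dimer = 3,
                                                 intra_bonded = 4, chain = 3))
  traj <- hb_trajectory(list(scene$frame), dt = 10)
  bw <- 0.01
  r_all <- rdf(traj, scene$topology, "OH_oxygen", "OE_oxygen",
               bin_width = bw, exclude = "none", denominator = "total")
  r_inter <- rdf(traj, scene$topology, "OH_oxygen", "OE_oxygen",
                 bin_width = bw, exclude = "same_molecule",
                 denominator = "total")
  r_intra <- rdf_intramolecular(traj, scene$topology, bin_width = bw)
  expect_equal(r_intra$counts + r_inter$counts, r_all$counts)
  expect_equal(r_intra$g + r_inter$g, r_all$g)
})

test_that("planted conformers put the subtraction RDF peak at the bonded separation", {
  scene <- make_planted_scene(planted_scene_spec(seed = 23, intra_bonded = 15))
  traj <- hb_trajectory(list(scene$frame), dt = 10)
  ri <- rdf_intramolecular(traj, scene$topology, bin_width = 0.002)
  peak_bin <- which.max(ri$g)
  expect_true(ri$r[peak_bin] > 0.28 - 0.002 && ri$r[peak_bin] < 0.28 + 0.002)
  # molecules are far apart: no intermolecular density below 0.35 nm
  expect_equal(max(ri$g_inter$g[ri$g_inter$r < 0.35]), 0)
  # identity: if no intramolecular pairs are counted the subtraction is zero
  mono <- make_planted_scene(planted_scene_spec(seed = 23, monomer = 6))
  tr2 <- hb_trajectory(list(mono$frame), dt = 10)
  r_all <- rdf(tr2, mono$topology, "OH_oxygen", "OE_oxygen",
               bin_width = 0.01, r_max = 0.55, denominator = "total")
  r_int <- rdf(tr2, mono$topology, "OH_oxygen", "OE_oxygen",
               bin_width = 0.01, r_max = 0.55, exclude = "same_molecule",
               denominator = "total")
  # monomer OH-OE sits at 0.6 nm so below r_max = 0.55 both variants agree
  expect_equal(r_all$g, r_int$g)
})

test_that("species without ether oxygens refuse the subtraction RDF", {
  atoms <- data.frame(atom_id = 0:2, molecule_id = 0L,
                      name = c("OA", "HO", "CT"), element = c("O", "H", "C"),
                      role = c("OH_oxygen", "OH_hydrogen", "terminal_carbon"))
  topo <- hb_topology(atoms, n_separation = 0)
  traj <- hb_trajectory(list(hb_frame(0, matrix(runif(9), 3, 3),
                                      hb_box(c(3, 3, 3)))), dt = 1)
  expect_error(rdf_intramolecular(traj, topo), "not applicable")
})

test_that("intramolecular distances reproduce rigid and closed-form cases", {
  mk_topology <- function() {
    hb_topology(data.frame(
      atom_id = 0:3, molecule_id = 0L, name = c("OA", "HO", "OE", "CT"),
      element = c("O", "H", "O", "C"),
      role = c("OH_oxygen", "OH_hydrogen", "OE_oxygen", "terminal_carbon")),
      n_separation = 3)
  }
  topo <- mk_topology()
  box <- hb_box(c(5, 5, 5))
  # rigid linear molecule with OH-CT at 0.9 nm
  fr <- hb_frame(0, rbind(c(1, 1, 1), c(1.1, 1, 1), c(1.5, 1, 1),
                          c(1.9, 1, 1)), box)
  ds <- intramolecular_distances(hb_trajectory(list(fr), dt = 1), topo)
  expect_equal(ds$mean[ds$observable == "OH_terminal_C_distance"], 0.9)
  expect_equal(ds$sd[ds$observable == "OH_terminal_C_distance"], 0)
  expect_equal(ds$mean[ds$observable == "OH_OE_distance"], 0.5)
  # two conformers 50/50 at 0.4 and 0.6 nm average to 0.5 nm
  fr2 <- hb_frame(1, rbind(c(1, 1, 1), c(1.1, 1, 1), c(1.5, 1, 1),
                           c(1.4, 1, 1)), box)
  fr3 <- hb_frame(2, rbind(c(1, 1, 1), c(1.1, 1, 1), c(1.5, 1, 1),
                           c(1.6, 1, 1)), box)
  ds2 <- intramolecular_distances(hb_trajectory(list(fr2, fr3)), topo)
  expect_equal(ds2$mean[ds2$observable == "OH_terminal_C_distance"], 0.5)
  # three collinear unit-spaced heavy atoms: Rg = sqrt(2/3)
  fr4 <- hb_frame(0, rbind(c(1, 1, 1), c(1.05, 1, 1), c(2, 1, 1),
                           c(3, 1, 1)), box)
  ds4 <- intramolecular_distances(hb_trajectory(list(fr4), dt = 1), topo)
  expect_equal(ds4$mean[ds4$observable == "radius_of_gyration"], sqrt(2 / 3))
  # missing terminal carbon role is an error
  bad <- topo
  bad$atoms$role[4] <- "other"
  expect_error(intramolecular_distances(hb_trajectory(list(fr), dt = 1), bad),
               "terminal_carbon")
})

test_that("observables are invariant under axis permutation", {
  scene <- make_planted_scene(planted_scene_spec(seed = 19, intra_bonded = 5,
                                                 pair_OH_OH = 3))
  traj <- hb_trajectory(list(scene$frame), dt = 10)
  perm <- scene$frame
  perm$coordinates <- perm$coordinates[, c(3, 1, 2)]
  traj_p <- hb_trajectory(list(perm), dt = 10)
  d0 <- intramolecular_distances(traj, scene$topology)
  d1 <- intramolecular_distances(traj_p, scene$topology)
  expect_equal(d0, d1)
  r0 <- rdf(traj, scene$topology, "OH_oxygen", "OE_oxygen", bin_width = 0.01)
  r1 <- rdf(traj_p, scene$topology, "OH_oxygen", "OE_oxygen", bin_width = 0.01)
  expect_equal(r0$g, r1$g)
})
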