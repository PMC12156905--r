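# Independent brute-force oracles.  These deliberately avoid the package's
# vectorised internals: plain scalar arithmetic and exhaustive loops only.

oracle_wrap <- function(d, L) d - L * floor(d / L + 0.5)

oracle_dist <- function(a, b, L) {
  d <- oracle_wrap(b - a, L)
  sqrt(sum(d^2))
}

oracle_angle <- function(vertex, p, q, L) {
  u <- oracle_wrap(p - vertex, L)
  v <- oracle_wrap(q - vertex, L)
  cosang <- sum(u * v) / (sqrt(sum(u^2)) * sqrt(sum(v^2)))
  acos(min(1, max(-1, cosang))) * 180 / pi
}

# O(n^3) all-triples hydrogen-bond scan.
oracle_hbonds <- function(frame, topology, criteria) {
  atoms <- topology$atoms
  X <- frame$coordinates
  L <- as.numeric(frame$box)
  don <- atoms[atoms$role == "OH_oxygen", ]
  hyd <- atoms[atoms$role == "OH_hydrogen", ]
  acc <- atoms[atoms$role %in% c("OH_oxygen", "OE_oxygen"), ]
  rows <- list()
  for (i in seq_len(nrow(don))) {
    d_atom <- don$atom_id[i]
    h_atom <- hyd$atom_id[hyd$molecule_id == don$molecule_id[i]]
    for (j in seq_len(nrow(acc))) {
      a_atom <- acc$atom_id[j]
      if (a_atom == d_atom) next
      dd <- oracle_dist(X[d_atom + 1, ], X[a_atom + 1, ], L)
      if (dd > criteria$max_da_distance) next
      dev <- if (criteria$angle_convention == "ADH_at_donor") {
        oracle_angle(X[d_atom + 1, ], X[h_atom + 1, ], X[a_atom + 1, ], L)
      } else {
        180 - oracle_angle(X[h_atom + 1, ], X[d_atom + 1, ], X[a_atom + 1, ], L)
      }
      if (dev > criteria$max_angle_deviation) next
      cls <- if (don$molecule_id[i] == acc$molecule_id[j]) "intra_OH_OE"
             else if (acc$role[j] == "OE_oxygen") "inter_OH_OE"
             else "inter_OH_OH"
      rows[[length(rows) + 1]] <- data.frame(
        frame = 0L, donor_O = d_atom, donor_H = h_atom, acceptor_O = a_atom,
        donor_mol = don$molecule_id[i], acceptor_mol = acc$molecule_id[j],
        class = cls, stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) return(hbondnet:::empty_bond_table())
  out <- do.call(rbind, rows)
  out <- out[order(out$donor_O, out$acceptor_O), ]
  rownames(out) <- NULL
  out
}

# Connected components by boolean adjacency-matrix powers; exhaustive
# simple-cycle search (length >= 3 over distinct vertices).
oracle_network_stats <- function(bonds, n_mol) {
  A <- matrix(FALSE, n_mol, n_mol)
  for (r in seq_len(nrow(bonds))) {
    a <- bonds$donor_mol[r] + 1
    b <- bonds$acceptor_mol[r] + 1
    if (a != b) { A[a, b] <- TRUE; A[b, a] <- TRUE }
  }
  reach <- A | diag(TRUE, n_mol)
  repeat {
    nxt <- (reach %*% reach) > 0
    if (identical(nxt, reach)) break
    reach <- nxt
  }
  comp_of <- integer(n_mol)
  cid <- 0
  for (v in seq_len(n_mol)) {
    if (comp_of[v] == 0) {
      cid <- cid + 1
      comp_of[reach[v, ]] <- cid
    }
  }
  bond_comp <- comp_of[bonds$donor_mol + 1]
  nets <- sort(unique(bond_comp))
  bonds_per <- vapply(nets, function(cc) sum(bond_comp == cc), integer(1))

  has_cycle_from <- function(start) {
    found <- FALSE
    path <- integer(0)
    dfs <- function(v) {
      if (found) return()
      path[length(path) + 1] <<- v
      for (w in which(A[v, ])) {
        if (w == start && length(path) >= 3) { found <<- TRUE; return() }
        if (!(w %in% path) && w > start) dfs(w)
      }
      path <<- path[-length(path)]
    }
    dfs(start)
    found
  }
  cyc_comp <- unique(comp_of[vapply(seq_len(n_mol), has_cycle_from, logical(1))])

  oe <- bonds[bonds$class == "inter_OH_OE", , drop = FALSE]
  dimer_comps <- integer(0)
  n_dimer_motifs <- 0
  if (nrow(oe)) {
    for (r in seq_len(nrow(oe))) {
      a <- oe$donor_mol[r]; b <- oe$acceptor_mol[r]
      if (a < b && any(oe$donor_mol == b & oe$acceptor_mol == a)) {
        n_dimer_motifs <- n_dimer_motifs + 1
        dimer_comps <- union(dimer_comps, comp_of[a + 1])
      }
    }
  }
  list(n_networks = length(nets),
       bonds_per_network = as.integer(sort(bonds_per)),
       n_dimer_networks = length(dimer_comps),
       n_dimer_motifs = n_dimer_motifs,
       n_cyclic = length(intersect(cyc_comp, nets)))
}

# Quartile by the explicit linear-interpolation rule h = (n-1) p + 1.
oracle_quantile <- function(x, p) {
  x <- sort(x)
  n <- length(x)
  h <- (n - 1) * p + 1
  lo <- floor(h)
  if (lo >= n) return(x[n])
  x[lo] + (h - lo) * (x[lo + 1] - x[lo])
}

# Random molecule-level bond set on n_mol molecules (atoms laid out 4/mol:
# OA = 4m, HO = 4m+1, OE = 4m+2).
random_bond_set <- function(n_mol, n_bonds) {
  if (n_bonds == 0) return(hbondnet:::empty_bond_table())
  rows <- lapply(seq_len(n_bonds), function(i) {
    cls <- sample(c("inter_OH_OH", "inter_OH_OE", "intra_OH_OE"), 1,
                  prob = c(0.45, 0.45, 0.1))
    dm <- sample(n_mol, 1) - 1
    am <- if (cls == "intra_OH_OE") dm else {
      repeat { am <- sample(n_mol, 1) - 1; if (am != dm) break }
      am
    }
    data.frame(frame = 0L, donor_O = 4 * dm, donor_H = 4 * dm + 1,
               acceptor_O = if (cls == "inter_OH_OH") 4 * am else 4 * am + 2,
               donor_mol = dm, acceptor_mol = am, class = cls,
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  tab[!duplicated(tab[c("donor_O", "acceptor_O")]), ]
}

# Minimal topology stand-in when only the molecule count matters.
fake_topology <- function(n_mol) {
  structure(list(n_molecules = n_mol), class = "hb_topology")
}

# Random dense frame of k pseudo ether-alcohol molecules for detector
# stress tests: positions uniform in a small box so criteria hits happen
# by chance.
random_dense_frame <- function(k, box_L = 1.4) {
  unit <- function() { v <- rnorm(3); v / sqrt(sum(v^2)) }
  atoms <- list(); coords <- list()
  for (m in seq_len(k) - 1L) {
    O <- runif(3, 0, box_L)
    coords[[length(coords) + 1]] <- rbind(O, O + 0.1 * unit(),
                                          O + 0.25 * unit(), O + 0.3 * unit())
    atoms[[length(atoms) + 1]] <- data.frame(
      molecule_id = m, name = c("OA", "HO", "OE", "CT"),
      element = c("O", "H", "O", "C"),
      role = c("OH_oxygen", "OH_hydrogen", "OE_oxygen", "terminal_carbon"),
      stringsAsFactors = FALSE)
  }
  df <- do.call(rbind, atoms)
  df$atom_id <- seq_len(nrow(df)) - 1L
  list(frame = hb_frame(0, do.call(rbind, coords), hb_box(rep(box_L, 3))),
       topology = hb_topology(df, species_label = "dense", n_separation = 3L))
}

# Random planted-scene specification with bounded molecule count.
random_scene_spec <- function(seed, max_molecules = 200) {
  set.seed(seed + 90000)
  spec <- planted_scene_spec(
    seed = seed,
    monomer = sample(0:4, 1),
    pair_OH_OH = sample(0:4, 1),
    pair_OH_OE = sample(0:3, 1),
    triplet = sample(0:3, 1),
    double_dimer = sample(0:5, 1),
    intra_bonded = sample(0:5, 1),
    chain = sample(2:6, sample(0:3, 1), replace = TRUE),
    ring = sample(3:6, sample(0:2, 1), replace = TRUE))
  n_mol <- spec$monomer + 2 * spec$pair_OH_OH + 2 * spec$pair_OH_OE +
    3 * spec$triplet + 2 * spec$double_dimer + spec$intra_bonded +
    sum(spec$chain) + sum(spec$ring)
  if (n_mol == 0) spec$monomer <- 1
  stopifnot(n_mol <= max_molecules)
  spec
}

# detect -> speciate -> dimers -> triplets -> networks on a planted scene,
# compared field by field against its ground truth.
expect_scene_roundtrip <- function(scene) {
  bonds <- detect_hbonds(scene$frame, scene$topology)
  counts <- table(factor(bonds$class, levels = names(scene$truth$n_bonds_by_class)))
  expect_equal(as.numeric(counts),
               as.numeric(scene$truth$n_bonds_by_class),
               info = paste("seed", scene$spec$seed))
  expect_equal(nrow(find_dimers(bonds)), scene$truth$n_dimers)
  expect_equal(nrow(find_triplets(bonds, scene$frame)), scene$truth$n_triplets)
  st <- frame_network_stats(build_graph(bonds, scene$topology))
  expect_equal(st$n_networks, scene$truth$n_networks)
  expect_equal(sort(st$bonds_per_network), scene$truth$bonds_per_network)
  expect_equal(st$n_cyclic, scene$truth$n_cyclic)
  expect_equal(st$n_dimer_networks, scene$truth$n_dimers)
  invisible(bonds)
}
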