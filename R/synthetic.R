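## Synthetic inputs with exact ground truth: planted hydrogen-bond scenes,
## Brownian tracers, ideal-gas frames, exponential bond lifetimes and
## Ornstein-Uhlenbeck stress series.
##
## Planted-scene geometry: intended bonds sit at a donor-acceptor distance
## of 0.28 nm with the donor hydrogen aimed at the acceptor (angle ~0), and
## every unintended oxygen-oxygen pair is kept at >= 0.35 nm or at an angle
## >= 60 degrees, so perturbing the criteria by +/- 0.01 nm or +/- 5 degrees
## cannot flip the ground truth.  Motifs are separated by >= 1 nm.

local_seed <- function(seed) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  function() {
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }
}

random_rotation <- function() {
  axis <- stats::rnorm(3)
  axis <- axis / sqrt(sum(axis^2))
  th <- stats::runif(1, 0, 2 * pi)
  K <- matrix(c(0, -axis[3], axis[2],
                axis[3], 0, -axis[1],
                -axis[2], axis[1], 0), 3, 3, byrow = TRUE)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

## One pseudo ether-alcohol molecule: rows OA, HO, OE, CT (local coords).
## `O` is the hydroxyl oxygen, `h_dir` the unit direction of the O-H bond
## (length 0.1 nm), `OE` an explicit ether-oxygen position or NULL for the
## default safe position 0.6 nm "above" the hydroxyl oxygen.
pseudo_molecule <- function(O, h_dir, OE = NULL, up = c(0, 0, 1)) {
  h_dir <- h_dir / sqrt(sum(h_dir^2))
  if (is.null(OE)) OE <- O + 0.6 * up
  CT <- O - 0.8 * up
  rbind(OA = O, HO = O + 0.1 * h_dir, OE = OE, CT = CT)
}

BOND_D <- 0.28   # planted donor-acceptor distance, nm

## Each motif builder returns list(mols = list of 4x3 matrices,
## truth = list(bonds_by_class, dimers, triplets, network_bonds, cyclic)).
motif_monomer <- function() {
  list(mols = list(pseudo_molecule(c(0, 0, 0), c(1, 0, 0))),
       truth = list(bonds = c(inter_OH_OH = 0, inter_OH_OE = 0, intra_OH_OE = 0),
                    dimers = 0L, triplets = 0L, network_bonds = integer(0),
                    cyclic = 0L))
}

motif_pair_OH_OH <- function() {
  m1 <- pseudo_molecule(c(0, 0, 0), c(1, 0, 0))
  m2 <- pseudo_molecule(c(BOND_D, 0, 0), c(1, 0, 0))
  list(mols = list(m1, m2),
       truth = list(bonds = c(inter_OH_OH = 1, inter_OH_OE = 0, intra_OH_OE = 0),
                    dimers = 0L, triplets = 0L, network_bonds = 1L,
                    cyclic = 0L))
}

motif_pair_OH_OE <- function() {
  m1 <- pseudo_molecule(c(0, 0, 0), c(1, 0, 0))
  m2 <- pseudo_molecule(c(BOND_D, 0.6, 0), c(0, 1, 0), OE = c(BOND_D, 0, 0))
  list(mols = list(m1, m2),
       truth = list(bonds = c(inter_OH_OH = 0, inter_OH_OE = 1, intra_OH_OE = 0),
                    dimers = 0L, triplets = 0L, network_bonds = 1L,
                    cyclic = 0L))
}

motif_intra_bonded <- function() {
  m <- pseudo_molecule(c(0, 0, 0), c(1, 0, 0), OE = c(BOND_D, 0, 0))
  list(mols = list(m),
       truth = list(bonds = c(inter_OH_OH = 0, inter_OH_OE = 0, intra_OH_OE = 1),
                    dimers = 0L, triplets = 0L, network_bonds = 1L,
                    cyclic = 0L))
}

motif_double_dimer <- function() {
  mA <- pseudo_molecule(c(0, 0, 0), c(1, 0, 0), OE = c(0, BOND_D, 0))
  mB <- pseudo_molecule(c(BOND_D, BOND_D, 0), c(-1, 0, 0),
                        OE = c(BOND_D, 0, 0))
  list(mols = list(mA, mB),
       truth = list(bonds = c(inter_OH_OH = 0, inter_OH_OE = 2, intra_OH_OE = 0),
                    dimers = 1L, triplets = 0L, network_bonds = 2L,
                    cyclic = 0L))
}

motif_chain <- function(k) {
  stopifnot(k >= 2)
  mols <- lapply(seq_len(k), function(i) {
    O <- c((i - 1) * BOND_D, 0, 0)
    h_dir <- if (i < k) c(1, 0, 0) else c(0, 1, 0)  # last donor aims away
    pseudo_molecule(O, h_dir)
  })
  list(mols = mols,
       truth = list(bonds = c(inter_OH_OH = k - 1, inter_OH_OE = 0,
                              intra_OH_OE = 0),
                    dimers = 0L, triplets = max(0L, k - 2L),
                    network_bonds = k - 1L, cyclic = 0L))
}

## Bent three-molecule chain giving the planted O1-O3 separation.
motif_triplet <- function(d13 = 0.47) {
  alpha <- 2 * asin(d13 / (2 * BOND_D))       # interior angle at O2
  O1 <- c(0, 0, 0)
  O2 <- c(BOND_D, 0, 0)
  dir23 <- c(-cos(alpha), sin(alpha), 0)
  O3 <- O2 + BOND_D * dir23
  m1 <- pseudo_molecule(O1, c(1, 0, 0))
  m2 <- pseudo_molecule(O2, dir23)
  m3 <- pseudo_molecule(O3, c(0, 0, 1), up = dir23)  # ether O points away
  list(mols = list(m1, m2, m3),
       truth = list(bonds = c(inter_OH_OH = 2, inter_OH_OE = 0, intra_OH_OE = 0),
                    dimers = 0L, triplets = 1L, network_bonds = 2L,
                    cyclic = 0L))
}

motif_ring <- function(k) {
  stopifnot(k >= 3)
  r <- BOND_D / (2 * sin(pi / k))
  th <- 2 * pi * (seq_len(k) - 1) / k
  O <- cbind(r * cos(th), r * sin(th), 0)
  mols <- lapply(seq_len(k), function(i) {
    nxt <- if (i == k) 1L else i + 1L
    h_dir <- O[nxt, ] - O[i, ]
    pseudo_molecule(O[i, ], h_dir)
  })
  list(mols = mols,
       truth = list(bonds = c(inter_OH_OH = k, inter_OH_OE = 0, intra_OH_OE = 0),
                    dimers = 0L, triplets = k, network_bonds = k,
                    cyclic = 1L))
}

#' Specification for a planted hydrogen-bond scene
#'
#' @param seed Integer seed controlling motif orientations and placement.
#' @param monomer,pair_OH_OH,pair_OH_OE,triplet,double_dimer,intra_bonded
#'   Motif counts.
#' @param chain,ring Integer vectors of motif sizes, one motif per element
#'   (e.g. `chain = c(3, 3, 5)` plants two 3-chains and one 5-chain; rings
#'   need `k >= 3`, chains `k >= 2`).
#' @param box Optional [hb_box()]; sized automatically when omitted.  A box
#'   too small for the required motif separation is a capacity error.
#' @return List of class `hb_scene_spec`.
#' @export
planted_scene_spec <- function(seed = 1L, monomer = 0L, pair_OH_OH = 0L,
                               pair_OH_OE = 0L, triplet = 0L,
                               double_dimer = 0L, intra_bonded = 0L,
                               chain = integer(0), ring = integer(0),
                               box = NULL) {
  structure(list(seed = as.integer(seed), monomer = monomer,
                 pair_OH_OH = pair_OH_OH, pair_OH_OE = pair_OH_OE,
                 triplet = triplet, double_dimer = double_dimer,
                 intra_bonded = intra_bonded, chain = as.integer(chain),
                 ring = as.integer(ring), box = box),
            class = "hb_scene_spec")
}

#' Generate a planted hydrogen-bond scene with exact ground truth
#'
#' Builds pseudo ether-alcohol molecules (hydroxyl O and H, ether O,
#' terminal C) arranged into the requested motifs, each given a random rigid
#' rotation and placed on a grid with at least 1 nm between motifs, so the
#' default detection criteria recover exactly the planted bonds.
#'
#' @param spec A [planted_scene_spec()].
#' @return List of class `hb_scene`: `frame`, `topology`, `spec`, and
#'   `truth` with `n_bonds_by_class`, `n_dimers`, `n_triplets`,
#'   `n_networks`, `bonds_per_network` (sorted), `n_cyclic`, `n_molecules`.
#' @export
make_planted_scene <- function(spec) {
  stopifnot(inherits(spec, "hb_scene_spec"))
  restore <- local_seed(spec$seed)
  on.exit(restore())

  motifs <- c(
    replicate(spec$monomer, motif_monomer(), simplify = FALSE),
    replicate(spec$pair_OH_OH, motif_pair_OH_OH(), simplify = FALSE),
    replicate(spec$pair_OH_OE, motif_pair_OH_OE(), simplify = FALSE),
    replicate(spec$triplet, motif_triplet(), simplify = FALSE),
    replicate(spec$double_dimer, motif_double_dimer(), simplify = FALSE),
    replicate(spec$intra_bonded, motif_intra_bonded(), simplify = FALSE),
    lapply(spec$chain, motif_chain),
    lapply(spec$ring, motif_ring))
  if (!length(motifs)) stop("scene spec requests no motifs", call. = FALSE)

  ## motif bounding radius about its local origin (atoms included)
  radius <- vapply(motifs, function(m) {
    max(sqrt(rowSums(do.call(rbind, m$mols)^2)))
  }, numeric(1))
  cell <- 2 * max(radius) + 1.0          # >= 1 nm clearance between motifs
  n_motifs <- length(motifs)
  if (is.null(spec$box)) {
    n_side <- max(2L, ceiling(n_motifs^(1 / 3)))
    box <- hb_box(rep(n_side * cell, 3))
  } else {
    box <- if (inherits(spec$box, "hb_box")) spec$box else hb_box(spec$box)
    n_side <- floor(min(as.numeric(box)) / cell)
    if (n_side^3 < n_motifs) {
      stop("box cannot hold ", n_motifs, " motifs at ", cell,
           " nm spacing (capacity ", n_side^3, ")", call. = FALSE)
    }
  }
  cells <- as.matrix(expand.grid(x = seq_len(n_side), y = seq_len(n_side),
                                 z = seq_len(n_side)))[, 1:3, drop = FALSE]
  cells <- (cells - 0.5) * cell
  slots <- sample(nrow(cells), n_motifs)

  coords <- list()
  atoms <- list()
  mol_id <- 0L
  truth_bonds <- c(inter_OH_OH = 0, inter_OH_OE = 0, intra_OH_OE = 0)
  n_dimers <- 0L
  n_triplets <- 0L
  bonds_per_network <- integer(0)
  n_cyclic <- 0L
  for (i in seq_len(n_motifs)) {
    m <- motifs[[i]]
    Rot <- random_rotation()
    centre <- cells[slots[i], ]
    for (mm in m$mols) {
      placed <- t(Rot %*% t(mm)) +
        matrix(centre, nrow(mm), 3, byrow = TRUE)
      coords[[length(coords) + 1L]] <- placed
      atoms[[length(atoms) + 1L]] <- data.frame(
        molecule_id = mol_id,
        name = c("OA", "HO", "OE", "CT"),
        element = c("O", "H", "O", "C"),
        role = c("OH_oxygen", "OH_hydrogen", "OE_oxygen", "terminal_carbon"),
        stringsAsFactors = FALSE)
      mol_id <- mol_id + 1L
    }
    truth_bonds <- truth_bonds + m$truth$bonds
    n_dimers <- n_dimers + m$truth$dimers
    n_triplets <- n_triplets + m$truth$triplets
    bonds_per_network <- c(bonds_per_network, m$truth$network_bonds)
    n_cyclic <- n_cyclic + m$truth$cyclic
  }
  X <- do.call(rbind, coords)
  atoms_df <- do.call(rbind, atoms)
  atoms_df$atom_id <- seq_len(nrow(atoms_df)) - 1L
  topology <- hb_topology(atoms_df, species_label = "pseudo ether alcohol",
                          n_separation = 3L, strict = TRUE)
  frame <- hb_frame(0, X, box)
  truth <- list(n_bonds_by_class = truth_bonds,
                n_dimers = n_dimers,
                n_triplets = n_triplets,
                n_networks = length(bonds_per_network),
                bonds_per_network = sort(bonds_per_network),
                n_cyclic = n_cyclic,
                n_molecules = mol_id)
  structure(list(frame = frame, topology = topology, truth = truth,
                 spec = spec), class = "hb_scene")
}

#' Brownian tracer trajectory with known diffusion coefficient
#'
#' Independent Gaussian displacements with per-axis variance `2 D dt`.
#'
#' @param N Number of particles.
#' @param D_true Diffusion coefficient, m^2/s.
#' @param dt Frame spacing, ps.
#' @param n_frames Number of frames.
#' @param box An [hb_box()] (nm) for the wrapped trajectory.
#' @param seed Integer seed.
#' @return List: `trajectory` (wrapped, one `other`-role atom per particle),
#'   `topology`, `com_series` (unwrapped positions: columns `x1, y1, z1,
#'   x2, ...`), `D_true`.
#' @export
make_brownian_trajectory <- function(N, D_true, dt, n_frames, box,
                                     seed = 1L) {
  stopifnot(D_true >= 0, dt > 0, n_frames >= 1)
  if (!inherits(box, "hb_box")) box <- hb_box(box)
  restore <- local_seed(seed)
  on.exit(restore())
  D_nm <- D_true / hb_constants$nm2_ps_to_m2_s     # nm^2/ps
  sd_step <- sqrt(2 * D_nm * dt)
  L <- as.numeric(box)
  start <- cbind(stats::runif(N, 0, L[1]), stats::runif(N, 0, L[2]),
                 stats::runif(N, 0, L[3]))
  pos <- array(0, dim = c(n_frames, N, 3))
  pos[1, , ] <- start
  if (n_frames > 1) {
    steps <- array(stats::rnorm((n_frames - 1) * N * 3, sd = sd_step),
                   dim = c(n_frames - 1, N, 3))
    for (k in 1:3) {
      pos[, , k] <- apply(rbind(start[, k], steps[, , k]), 2, cumsum)
    }
  }
  frames <- lapply(seq_len(n_frames), function(f) {
    hb_frame((f - 1) * dt,
             wrap_positions(matrix(pos[f, , ], ncol = 3), box), box)
  })
  atoms <- data.frame(atom_id = seq_len(N) - 1L, molecule_id = seq_len(N) - 1L,
                      name = "P", element = "X", role = "other",
                      stringsAsFactors = FALSE)
  cols <- matrix(aperm(pos, c(1, 3, 2)), nrow = n_frames)  # x1 y1 z1 x2 ...
  colnames(cols) <- paste0(rep(c("x", "y", "z"), N),
                           rep(seq_len(N), each = 3))
  list(trajectory = hb_trajectory(frames, dt = dt),
       topology = hb_topology(atoms, species_label = "brownian tracer",
                              strict = FALSE),
       com_series = hb_series((seq_len(n_frames) - 1) * dt,
                              as.data.frame(cols)),
       D_true = D_true)
}

#' Ideal-gas trajectory (uniform independent positions each frame)
#'
#' @param N Number of particles (> 1).
#' @param box An [hb_box()].
#' @param n_frames Number of frames.
#' @param dt Frame spacing, ps.
#' @param seed Integer seed.
#' @return List: `trajectory`, `topology` (all `other` roles).
#' @export
make_ideal_gas <- function(N, box, n_frames, dt = 1, seed = 1L) {
  stopifnot(N > 1, n_frames >= 1)
  if (!inherits(box, "hb_box")) box <- hb_box(box)
  restore <- local_seed(seed)
  on.exit(restore())
  L <- as.numeric(box)
  frames <- lapply(seq_len(n_frames), function(f) {
    hb_frame((f - 1) * dt,
             cbind(stats::runif(N, 0, L[1]), stats::runif(N, 0, L[2]),
                   stats::runif(N, 0, L[3])), box)
  })
  atoms <- data.frame(atom_id = seq_len(N) - 1L, molecule_id = seq_len(N) - 1L,
                      name = "P", element = "X", role = "other",
                      stringsAsFactors = FALSE)
  list(trajectory = hb_trajectory(frames, dt = dt),
       topology = hb_topology(atoms, species_label = "ideal gas",
                              strict = FALSE))
}

#' Exponential bonded-time sample with known decay constant
#'
#' Draws bond lifetimes from an exponential law with rate `gamma_true`,
#' discretises them to whole frames of `dt` (rounding up, minimum one
#' frame) and truncates at the window length, mirroring the windowed
#' bonded-time table of real trajectories.
#'
#' @param gamma_true Decay constant, 1/ps.
#' @param n_pairs Number of unique bond pairs to draw.
#' @param window_ps Window length, ps (default 5000).
#' @param dt Frame spacing, ps (default 10).
#' @param seed Integer seed.
#' @return data.frame in the layout of [bonded_times()].
#' @export
make_lifetime_sample <- function(gamma_true, n_pairs, window_ps = 5000,
                                 dt = 10, seed = 1L) {
  stopifnot(gamma_true > 0, n_pairs >= 1, window_ps >= dt)
  restore <- local_seed(seed)
  on.exit(restore())
  raw <- stats::rexp(n_pairs, rate = gamma_true)
  k <- pmin(pmax(ceiling(raw / dt), 1L), as.integer(window_ps / dt))
  data.frame(window = 0L, donor_O = 2L * seq_len(n_pairs) - 2L,
             acceptor_O = 2L * seq_len(n_pairs) - 1L,
             class = "inter_OH_OH", frames_bonded = as.integer(k),
             time_bonded = k * dt, stringsAsFactors = FALSE)
}

#' Stationary Ornstein-Uhlenbeck stress series
#'
#' Three independent Gauss-Markov series with exact autocovariance
#' `C0 exp(-t/tau)`, generated with the exact discrete-time update
#' `x_{t+1} = phi x_t + sqrt(C0 (1 - phi^2)) eps`, `phi = exp(-dt/tau)`, so
#' the Green-Kubo integral has the closed form `C0 tau` (in bar^2 ps).
#'
#' @param C0 Stationary variance, bar^2.
#' @param tau Correlation time, ps.
#' @param dt Sample spacing, ps.
#' @param n_samples Series length.
#' @param seed Integer seed.
#' @return An [hb_series()] with columns `time`, `Pxy`, `Pxz`, `Pyz`.
#' @export
make_ou_stress <- function(C0, tau, dt, n_samples, seed = 1L) {
  stopifnot(C0 > 0, tau > 0, dt > 0, n_samples >= 2)
  restore <- local_seed(seed)
  on.exit(restore())
  phi <- exp(-dt / tau)
  sd_innov <- sqrt(C0 * (1 - phi^2))
  cols <- vapply(1:3, function(j) {
    innov <- stats::rnorm(n_samples, sd = sd_innov)
    innov[1] <- stats::rnorm(1, sd = sqrt(C0))   # stationary start
    as.numeric(stats::filter(innov, phi, method = "recursive"))
  }, numeric(n_samples))
  colnames(cols) <- c("Pxy", "Pxz", "Pyz")
  hb_series((seq_len(n_samples) - 1) * dt, as.data.frame(cols))
}
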