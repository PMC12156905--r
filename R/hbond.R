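## Geometric hydrogen-bond detection and speciation.
##
## A bond is a (donor O, donor H, acceptor O) triple satisfying both a
## heavy-atom distance criterion and an angular criterion under minimum
## imaging.  Hydroxyl oxygens donate (via their molecule's hydroxyl
## hydrogen) and accept; ether oxygens only accept.  Bonds are speciated as
## intermolecular OH-OH, intermolecular OH-OE, or intramolecular OH-OE.

HB_CLASSES <- c("inter_OH_OH", "inter_OH_OE", "intra_OH_OE")

#' Hydrogen-bond geometric criteria
#'
#' Defaults follow the common geometric criteria for trajectory analysis:
#' acceptor-donor (O...O) distance within 0.30 nm and an angular deviation of
#' at most 30 degrees.  Two angle conventions are supported:
#'
#' * `ADH_at_donor` (default): the acceptor-donor-hydrogen angle measured at
#'   the donor oxygen must be `<= max_angle_deviation`.
#' * `DHA_deviation`: the deviation of the donor-hydrogen-acceptor angle from
#'   linearity (180 degrees minus the D-H...A angle at the hydrogen) must be
#'   `<= max_angle_deviation`, i.e. the default asks D-H...A >= 150 degrees.
#'
#' For a rigid ~0.1 nm O-H bond the two conventions nearly coincide.
#'
#' @param max_da_distance Donor-acceptor O...O cutoff, nm (0, 1].
#' @param max_angle_deviation Angular cutoff, degrees (0, 90].
#' @param angle_convention `"ADH_at_donor"` or `"DHA_deviation"`.
#' @return Object of class `hb_criteria`.
#' @export
hbond_criteria <- function(max_da_distance = 0.30, max_angle_deviation = 30,
                           angle_convention = c("ADH_at_donor", "DHA_deviation")) {
  angle_convention <- match.arg(angle_convention)
  if (!(max_da_distance > 0 && max_da_distance <= 1.0)) {
    stop("max_da_distance must be in (0, 1] nm", call. = FALSE)
  }
  if (!(max_angle_deviation > 0 && max_angle_deviation <= 90)) {
    stop("max_angle_deviation must be in (0, 90] degrees", call. = FALSE)
  }
  structure(list(max_da_distance = max_da_distance,
                 max_angle_deviation = max_angle_deviation,
                 angle_convention = angle_convention),
            class = "hb_criteria")
}

empty_bond_table <- function() {
  data.frame(frame = integer(0), donor_O = integer(0), donor_H = integer(0),
             acceptor_O = integer(0), donor_mol = integer(0),
             acceptor_mol = integer(0), class = character(0),
             stringsAsFactors = FALSE)
}

#' Detect hydrogen bonds in one frame
#'
#' Scans all (donor O, donor H, acceptor O) triples: donors are hydroxyl
#' oxygens paired with their molecule's hydroxyl hydrogen; acceptors are all
#' hydroxyl and ether oxygens except the donor oxygen itself.  A donor may
#' bond several acceptors simultaneously (bifurcated bonds are all kept), and
#' intramolecular hydroxyl-to-ether pairs are geometry-tested like any other
#' pair.  Output rows are sorted by `(donor_O, acceptor_O)`.
#'
#' @param frame An [hb_frame()].
#' @param topology A strict [hb_topology()].
#' @param criteria An [hbond_criteria()].
#' @param frame_index Frame index recorded in the output (0-based).
#' @return data.frame with columns `frame`, `donor_O`, `donor_H`,
#'   `acceptor_O`, `donor_mol`, `acceptor_mol`, `class`.
#' @export
detect_hbonds <- function(frame, topology, criteria = hbond_criteria(),
                          frame_index = 0L) {
  validate_topology(topology)
  stopifnot(inherits(frame, "hb_frame"), inherits(criteria, "hb_criteria"))
  atoms <- topology$atoms
  if (nrow(frame$coordinates) != nrow(atoms)) {
    stop("frame atom count does not match topology", call. = FALSE)
  }
  box <- frame$box
  X <- frame$coordinates

  don <- atoms[atoms$role == "OH_oxygen", ]
  don <- don[order(don$molecule_id), ]
  hyd <- atoms[atoms$role == "OH_hydrogen", ]
  hyd <- hyd[order(hyd$molecule_id), ]      # aligned with don by molecule
  acc <- atoms[atoms$role %in% c("OH_oxygen", "OE_oxygen"), ]
  if (!nrow(don) || !nrow(acc)) return(empty_bond_table())

  dmat <- cross_min_image_dist(X[don$atom_id + 1L, , drop = FALSE],
                               X[acc$atom_id + 1L, , drop = FALSE], box)
  hit <- which(dmat <= criteria$max_da_distance &
                 outer(don$atom_id, acc$atom_id, "!="), arr.ind = TRUE)
  if (!nrow(hit)) return(empty_bond_table())

  di <- hit[, 1]
  ai <- hit[, 2]
  D <- X[don$atom_id[di] + 1L, , drop = FALSE]
  H <- X[hyd$atom_id[di] + 1L, , drop = FALSE]
  A <- X[acc$atom_id[ai] + 1L, , drop = FALSE]
  dev <- if (criteria$angle_convention == "ADH_at_donor") {
    angles_at_rows(D, H, A, box)            # angle A-D-H at the donor oxygen
  } else {
    180 - angles_at_rows(H, D, A, box)      # deviation of D-H...A from linear
  }
  keep <- dev <= criteria$max_angle_deviation
  if (!any(keep)) return(empty_bond_table())
  di <- di[keep]
  ai <- ai[keep]

  acc_role <- acc$role[ai]
  same_mol <- don$molecule_id[di] == acc$molecule_id[ai]
  out <- data.frame(frame = frame_index,
                    donor_O = don$atom_id[di],
                    donor_H = hyd$atom_id[di],
                    acceptor_O = acc$atom_id[ai],
                    donor_mol = don$molecule_id[di],
                    acceptor_mol = acc$molecule_id[ai],
                    class = ifelse(same_mol, "intra_OH_OE",
                                   ifelse(acc_role == "OE_oxygen",
                                          "inter_OH_OE", "inter_OH_OH")),
                    stringsAsFactors = FALSE)
  out <- out[order(out$donor_O, out$acceptor_O), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Detect hydrogen bonds across a trajectory
#'
#' @param trajectory An [hb_trajectory()].
#' @inheritParams detect_hbonds
#' @return One bond table (see [detect_hbonds()]) with `frame` running over
#'   0-based frame indices.
#' @export
detect_hbonds_trajectory <- function(trajectory, topology,
                                     criteria = hbond_criteria()) {
  stopifnot(inherits(trajectory, "hb_trajectory"))
  tabs <- lapply(seq_along(trajectory$frames), function(i) {
    detect_hbonds(trajectory$frames[[i]], topology, criteria,
                  frame_index = i - 1L)
  })
  do.call(rbind, c(tabs, list(make.row.names = FALSE)))
}

#' Per-class bond counts: mean and SD per frame
#'
#' Frames with no bonds of a class contribute zero counts, so the total
#' number of analysed frames must be supplied.
#'
#' @param bond_table Bond table over a trajectory.
#' @param n_frames Number of frames analysed (>= 1).
#' @return data.frame with one row per bond class plus a `total` row:
#'   columns `class`, `mean`, `sd`.
#' @export
count_by_class <- function(bond_table, n_frames) {
  stopifnot(n_frames >= 1)
  per_frame <- function(cls) {
    sub <- bond_table[bond_table$class %in% cls, , drop = FALSE]
    counts <- integer(n_frames)
    if (nrow(sub)) {
      tab <- table(sub$frame)
      counts[as.integer(names(tab)) + 1L] <- as.integer(tab)
    }
    counts
  }
  rows <- lapply(HB_CLASSES, function(cls) {
    cnt <- per_frame(cls)
    data.frame(class = cls, mean = mean(cnt),
               sd = stats::sd(cnt), stringsAsFactors = FALSE)
  })
  tot <- per_frame(HB_CLASSES)
  out <- rbind(do.call(rbind, rows),
               data.frame(class = "total", mean = mean(tot),
                          sd = stats::sd(tot), stringsAsFactors = FALSE))
  out$sd[is.na(out$sd)] <- 0
  out
}

#' Find double-hydrogen-bonded dimers in one frame
#'
#' A dimer is an unordered pair of distinct molecules joined by two
#' reciprocal intermolecular OH->OE bonds (A's hydroxyl donates to B's ether
#' oxygen and vice versa), forming a closed ring motif of two molecules.
#'
#' @param frame_bonds Bond table rows from a single frame.
#' @return data.frame with columns `frame`, `mol_a`, `mol_b` (`mol_a <
#'   mol_b`), one row per dimer.
#' @export
find_dimers <- function(frame_bonds) {
  empty <- data.frame(frame = integer(0), mol_a = integer(0),
                      mol_b = integer(0))
  oe <- frame_bonds[frame_bonds$class == "inter_OH_OE", , drop = FALSE]
  if (!nrow(oe)) return(empty)
  fwd <- paste(oe$donor_mol, oe$acceptor_mol)
  rev <- paste(oe$acceptor_mol, oe$donor_mol)
  recip <- fwd %in% rev
  if (!any(recip)) return(empty)
  sub <- oe[recip & oe$donor_mol < oe$acceptor_mol, , drop = FALSE]
  sub <- sub[!duplicated(paste(sub$donor_mol, sub$acceptor_mol)), , drop = FALSE]
  data.frame(frame = sub$frame, mol_a = sub$donor_mol, mol_b = sub$acceptor_mol,
             row.names = NULL)
}

#' Find hydrogen-bond triplets O1 -> O2 -> O3 in one frame
#'
#' The middle oxygen O2 accepts a bond from O1 and donates one to O3 within
#' the same frame; O1 and O3 must differ.  The O1-O3 separation is measured
#' with minimum imaging.
#'
#' @param frame_bonds Bond table rows from a single frame.
#' @param frame The corresponding [hb_frame()] (for the O1-O3 distance).
#' @return data.frame with columns `frame`, `o1`, `o2`, `o3`,
#'   `o1_o3_distance` (nm).
#' @export
find_triplets <- function(frame_bonds, frame) {
  empty <- data.frame(frame = integer(0), o1 = integer(0), o2 = integer(0),
                      o3 = integer(0), o1_o3_distance = numeric(0))
  if (!nrow(frame_bonds)) return(empty)
  m <- merge(frame_bonds, frame_bonds,
             by.x = "acceptor_O", by.y = "donor_O",
             suffixes = c("_in", "_out"))
  if (!nrow(m)) return(empty)
  m <- m[m$donor_O != m$acceptor_O_out, , drop = FALSE]
  if (!nrow(m)) return(empty)
  d <- min_image_distance(frame$coordinates[m$donor_O + 1L, , drop = FALSE],
                          frame$coordinates[m$acceptor_O_out + 1L, , drop = FALSE],
                          frame$box)
  out <- data.frame(frame = m$frame_in, o1 = m$donor_O, o2 = m$acceptor_O,
                    o3 = m$acceptor_O_out, o1_o3_distance = d)
  out <- out[order(out$o1, out$o2, out$o3), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write / read a bond table as CSV
#'
#' @param bond_table Bond table (see [detect_hbonds()]).
#' @param path CSV path.
#' @return `path` invisibly (write); the bond table (read).
#' @export
write_bond_table <- function(bond_table, path) {
  utils::write.csv(bond_table, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_bond_table
#' @export
read_bond_table <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  needed <- names(empty_bond_table())
  if (!all(needed %in% names(tab))) {
    stop("bond table CSV lacks required columns", call. = FALSE)
  }
  tab[needed]
}
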