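## Structural observables: radial distribution functions under periodic
## boundaries and intramolecular distance summaries.

resolve_selection <- function(topology, sel) {
  atoms <- topology$atoms
  if (is.character(sel) && length(sel) == 1 && sel == "all") {
    return(atoms$atom_id)
  }
  if (is.character(sel)) {
    if (!all(sel %in% HB_ROLES)) {
      stop("unknown selection role(s): ",
           paste(setdiff(sel, HB_ROLES), collapse = ", "), call. = FALSE)
    }
    return(atoms$atom_id[atoms$role %in% sel])
  }
  ids <- as.integer(sel)
  if (any(ids < 0 | ids >= nrow(atoms))) {
    stop("selection atom ids out of range", call. = FALSE)
  }
  ids
}

#' Radial distribution function
#'
#' Computes `g(r)` between two selections as the frame-averaged histogram of
#' minimum-image pair distances, normalised by the ideal-gas shell count
#' `n_pairs * 4 pi r^2 dr / V`.  Ordered pairs are counted (both `a->b` and
#' `b->a` when the selections overlap), with pairs of identical atoms always
#' excluded.
#'
#' @param trajectory An [hb_trajectory()].
#' @param topology An [hb_topology()].
#' @param sel_a,sel_b Selections: `"all"`, a role name (e.g. `"OH_oxygen"`),
#'   a vector of roles, or 0-based atom ids.
#' @param bin_width Histogram bin width, nm (default 0.002).
#' @param r_max Histogram range, nm; defaults to 0.45 * min box edge and may
#'   not exceed half the smallest box edge.
#' @param exclude `"none"` or `"same_molecule"` (drop intramolecular pairs
#'   before counting).
#' @param denominator `"counted"` normalises by the pairs eligible after the
#'   exclusion rule; `"total"` normalises by all ordered pairs regardless of
#'   exclusion, which makes histogram-level subtraction of RDF variants
#'   exact (see [rdf_intramolecular()]).
#' @return Object of class `hb_rdf`: list with `r` (bin centres, nm), `g`,
#'   `counts`, `bin_width`, `r_max`, `n_pairs`, `n_frames`, `pair_spec`.
#' @export
rdf <- function(trajectory, topology, sel_a, sel_b, bin_width = 0.002,
                r_max = NULL, exclude = c("none", "same_molecule"),
                denominator = c("counted", "total")) {
  exclude <- match.arg(exclude)
  denominator <- match.arg(denominator)
  stopifnot(inherits(trajectory, "hb_trajectory"), bin_width > 0)
  box <- trajectory$box
  half_min <- min(as.numeric(box)) / 2
  if (is.null(r_max)) r_max <- 0.9 * half_min
  if (r_max > half_min + 1e-12) {
    stop("r_max (", r_max, " nm) exceeds half the smallest box edge (",
         half_min, " nm)", call. = FALSE)
  }
  ids_a <- resolve_selection(topology, sel_a)
  ids_b <- resolve_selection(topology, sel_b)
  if (!length(ids_a) || !length(ids_b)) {
    stop("empty RDF selection", call. = FALSE)
  }
  mol <- topology$atoms$molecule_id
  same_atom <- outer(ids_a, ids_b, "==")
  same_mol <- outer(mol[ids_a + 1L], mol[ids_b + 1L], "==")
  n_total <- length(ids_a) * length(ids_b) - sum(same_atom)
  keep_mask <- !same_atom
  if (exclude == "same_molecule") keep_mask <- keep_mask & !same_mol
  n_counted <- sum(keep_mask)
  n_pairs <- if (denominator == "total") n_total else n_counted
  if (n_pairs == 0) stop("RDF selections leave no eligible pairs", call. = FALSE)

  n_bins <- as.integer(ceiling(r_max / bin_width - 1e-9))
  counts <- numeric(n_bins)
  for (f in trajectory$frames) {
    d <- cross_min_image_dist(f$coordinates[ids_a + 1L, , drop = FALSE],
                              f$coordinates[ids_b + 1L, , drop = FALSE], box)
    d <- d[keep_mask]
    d <- d[d <= r_max & d > 0]
    if (length(d)) {
      k <- pmin(as.integer(ceiling(d / bin_width)), n_bins)
      counts <- counts + tabulate(k, nbins = n_bins)
    }
  }
  n_frames <- length(trajectory$frames)
  V <- prod(as.numeric(box))
  r_centers <- (seq_len(n_bins) - 0.5) * bin_width
  shell <- 4 * pi * r_centers^2 * bin_width / V
  g <- counts / (n_frames * n_pairs * shell)
  structure(list(r = r_centers, g = g, counts = counts,
                 bin_width = bin_width, r_max = n_bins * bin_width,
                 n_pairs = n_pairs, n_frames = n_frames,
                 pair_spec = list(sel_a = sel_a, sel_b = sel_b,
                                  exclude = exclude,
                                  denominator = denominator)),
            class = "hb_rdf")
}

#' @export
print.hb_rdf <- function(x, ...) {
  pk <- which.max(x$g)
  cat(sprintf("rdf: %d bins of %g nm to %g nm over %d frame(s); peak g = %.3f at r = %.3f nm\n",
              length(x$g), x$bin_width, x$r_max, x$n_frames, x$g[pk], x$r[pk]))
  invisible(x)
}

#' Intramolecular hydroxyl-ether RDF by subtraction
#'
#' The all-pair hydroxyl-to-ether-oxygen RDF is computed once with and once
#' without intramolecular pairs, both on the same grid and with the same
#' total-pair normalisation, and subtracted: `g_intra = g_all - g_inter`.
#' The subtraction is then exact at histogram level.
#'
#' @inheritParams rdf
#' @return An `hb_rdf` whose `g` is the intramolecular component; carries
#'   the two inputs as `g_all` and `g_inter` attributes-like list entries.
#' @export
rdf_intramolecular <- function(trajectory, topology, bin_width = 0.002,
                               r_max = NULL) {
  if (topology$n_separation == 0L ||
      !any(topology$atoms$role == "OE_oxygen")) {
    stop("species has no ether oxygen (n_separation = 0); ",
         "intramolecular OH-OE RDF is not applicable", call. = FALSE)
  }
  g_all <- rdf(trajectory, topology, "OH_oxygen", "OE_oxygen",
               bin_width = bin_width, r_max = r_max, exclude = "none",
               denominator = "total")
  g_inter <- rdf(trajectory, topology, "OH_oxygen", "OE_oxygen",
                 bin_width = bin_width, r_max = r_max,
                 exclude = "same_molecule", denominator = "total")
  out <- g_all
  out$g <- g_all$g - g_inter$g
  out$counts <- g_all$counts - g_inter$counts
  out$pair_spec$exclude <- "intramolecular_by_subtraction"
  out$g_all <- g_all
  out$g_inter <- g_inter
  out
}

#' Intramolecular distance summary
#'
#' Per-frame minimum-image distances from the hydroxyl oxygen to the ether
#' oxygen (when present) and to the terminal carbon, averaged over molecules
#' and then over frames, plus the mass-unweighted radius of gyration over
#' heavy atoms (molecules are made whole before the centroid is taken).
#'
#' @param trajectory An [hb_trajectory()].
#' @param topology A strict [hb_topology()]; `terminal_carbon` is required,
#'   the ether oxygen optional.
#' @return data.frame with columns `observable`, `mean` (nm), `sd` (over
#'   frame means, nm).  Observables: `OH_OE_distance` (only when an ether
#'   oxygen exists), `OH_terminal_C_distance`, `radius_of_gyration`.
#' @export
intramolecular_distances <- function(trajectory, topology) {
  validate_topology(topology)
  atoms <- topology$atoms
  if (!any(atoms$role == "terminal_carbon")) {
    stop("topology has no terminal_carbon atoms", call. = FALSE)
  }
  mols <- sort(unique(atoms$molecule_id))
  id_of <- function(role) {
    sub <- atoms[atoms$role == role, ]
    sub <- sub[!duplicated(sub$molecule_id), ]   # one per molecule
    out <- rep(NA_integer_, length(mols))
    out[match(sub$molecule_id, mols)] <- sub$atom_id
    out
  }
  oh <- id_of("OH_oxygen")
  ct <- id_of("terminal_carbon")
  oe <- id_of("OE_oxygen")
  if (anyNA(ct)) stop("a molecule lacks a terminal_carbon atom", call. = FALSE)
  has_oe <- !anyNA(oe) && any(!is.na(oe))
  heavy <- atoms$element != "H"
  box <- trajectory$box

  per_frame <- lapply(trajectory$frames, function(f) {
    X <- f$coordinates
    d_ct <- mean(min_image_distance(X[oh + 1L, , drop = FALSE],
                                    X[ct + 1L, , drop = FALSE], box))
    d_oe <- if (has_oe) {
      mean(min_image_distance(X[oh + 1L, , drop = FALSE],
                              X[oe + 1L, , drop = FALSE], box))
    } else NA_real_
    Xw <- unwrap_molecules(X, atoms$molecule_id, box)
    rg <- vapply(mols, function(m) {
      idx <- which(atoms$molecule_id == m & heavy)
      P <- Xw[idx, , drop = FALSE]
      cen <- colMeans(P)
      sqrt(mean(rowSums(sweep(P, 2, cen)^2)))
    }, numeric(1))
    c(d_oe = d_oe, d_ct = d_ct, rg = mean(rg))
  })
  M <- do.call(rbind, per_frame)
  sd0 <- function(x) if (length(x) > 1) stats::sd(x) else 0
  rows <- list(
    data.frame(observable = "OH_terminal_C_distance",
               mean = mean(M[, "d_ct"]), sd = sd0(M[, "d_ct"])),
    data.frame(observable = "radius_of_gyration",
               mean = mean(M[, "rg"]), sd = sd0(M[, "rg"])))
  if (has_oe) {
    rows <- c(list(data.frame(observable = "OH_OE_distance",
                              mean = mean(M[, "d_oe"]), sd = sd0(M[, "d_oe"]))),
              rows)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
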