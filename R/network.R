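## Molecule-level hydrogen-bond graphs and network statistics.
##
## Every hydrogen bond, regardless of type, is one edge of a multigraph over
## molecules; intramolecular bonds are self-loops.  A "network" is a
## connected component containing at least one bond.  A network is cyclic
## only if it contains a cycle over >= 3 distinct molecules: the parallel
## double edge of a reciprocal dimer and self-loops do not count as rings.

#' Build the per-frame molecule bond graph
#'
#' @param frame_bonds Bond table rows from a single frame.
#' @param topology An [hb_topology()]; supplies the node set (isolated
#'   molecules are kept as isolated nodes).
#' @return An igraph multigraph whose vertices are molecule ids (0-based,
#'   stored as vertex name) and whose edges carry the bond attributes
#'   `donor_mol`, `acceptor_mol`, `class`.
#' @export
build_graph <- function(frame_bonds, topology) {
  n_mol <- topology$n_molecules
  if (nrow(frame_bonds)) {
    bad <- which(frame_bonds$donor_mol >= n_mol | frame_bonds$acceptor_mol >= n_mol |
                   frame_bonds$donor_mol < 0 | frame_bonds$acceptor_mol < 0)
    if (length(bad)) {
      stop("bond references unknown molecule id ",
           frame_bonds$donor_mol[bad[1]], "/", frame_bonds$acceptor_mol[bad[1]],
           call. = FALSE)
    }
  }
  g <- igraph::make_empty_graph(n = n_mol, directed = FALSE)
  igraph::V(g)$name <- as.character(seq_len(n_mol) - 1L)
  if (nrow(frame_bonds)) {
    edges <- rbind(frame_bonds$donor_mol + 1L, frame_bonds$acceptor_mol + 1L)
    g <- igraph::add_edges(g, as.vector(edges),
                           donor_mol = frame_bonds$donor_mol,
                           acceptor_mol = frame_bonds$acceptor_mol,
                           class = frame_bonds$class)
  }
  g
}

#' Per-frame network statistics
#'
#' Components with at least one edge are networks.  `bonds_per_network` is
#' the edge count of each network (self-loops count as one bond).  A network
#' is cyclic when its simplified skeleton (parallel edges collapsed,
#' self-loops dropped) still contains a cycle, which for a connected graph
#' means at least as many distinct-molecule edges as molecules — this is a
#' ring over >= 3 molecules.  `n_dimer_networks` counts networks containing
#' at least one reciprocal OH->OE dimer pair; `n_dimer_motifs` counts the
#' dimer pairs themselves.
#'
#' @param graph Multigraph from [build_graph()].
#' @return List with `n_networks`, `bonds_per_network` (integer vector),
#'   `n_dimer_networks`, `n_dimer_motifs`, `n_cyclic`.
#' @export
frame_network_stats <- function(graph) {
  comp <- igraph::components(graph)
  el <- igraph::as_edgelist(graph, names = FALSE)
  if (!nrow(el)) {
    return(list(n_networks = 0L, bonds_per_network = integer(0),
                n_dimer_networks = 0L, n_dimer_motifs = 0L, n_cyclic = 0L))
  }
  edge_comp <- comp$membership[el[, 1]]
  bonds_per <- table(edge_comp)
  net_ids <- as.integer(names(bonds_per))

  ## cyclic: per network, count distinct unordered molecule pairs (loops out)
  non_loop <- el[, 1] != el[, 2]
  cyclic <- logical(length(net_ids))
  if (any(non_loop)) {
    key <- paste(pmin(el[non_loop, 1], el[non_loop, 2]),
                 pmax(el[non_loop, 1], el[non_loop, 2]))
    uniq <- !duplicated(key)
    simple_edges <- table(factor(edge_comp[non_loop][uniq], levels = net_ids))
    cyclic <- as.integer(simple_edges) >= comp$csize[net_ids]
  }

  ## dimers: reciprocal inter OH->OE pairs
  n_dimer_motifs <- 0L
  dimer_net <- integer(0)
  cls <- igraph::E(graph)$class
  is_oe <- cls == "inter_OH_OE"
  if (any(is_oe)) {
    dm <- igraph::E(graph)$donor_mol[is_oe]
    am <- igraph::E(graph)$acceptor_mol[is_oe]
    fwd <- paste(dm, am)
    rev <- paste(am, dm)
    recip <- fwd %in% rev & dm < am
    recip_keys <- unique(fwd[recip])
    n_dimer_motifs <- length(recip_keys)
    if (n_dimer_motifs) {
      mols <- as.integer(vapply(strsplit(recip_keys, " "), `[`, character(1), 1))
      dimer_net <- unique(comp$membership[mols + 1L])
    }
  }

  list(n_networks = length(net_ids),
       bonds_per_network = as.integer(bonds_per),
       n_dimer_networks = length(dimer_net),
       n_dimer_motifs = n_dimer_motifs,
       n_cyclic = sum(cyclic))
}

#' Summarise network statistics over frames
#'
#' Bonds-per-network values are pooled over all frames before computing
#' mean, SD and quartiles; quartiles use linear interpolation (R type 7).
#'
#' @param per_frame List of per-frame statistics from
#'   [frame_network_stats()].
#' @return Object of class `hb_network_summary`: a list with
#'   `n_networks_mean/sd`, `bonds_mean/sd`, `q1`, `median`, `q3`, `max`,
#'   `dimer_networks_mean`, `dimer_motifs_mean`, `cyclic_mean`, `n_frames`.
#' @export
summarize_networks <- function(per_frame) {
  stopifnot(length(per_frame) >= 1)
  nn <- vapply(per_frame, `[[`, integer(1), "n_networks")
  pooled <- unlist(lapply(per_frame, `[[`, "bonds_per_network"))
  if (is.null(pooled)) pooled <- integer(0)
  dn <- vapply(per_frame, `[[`, integer(1), "n_dimer_networks")
  dmot <- vapply(per_frame, `[[`, integer(1), "n_dimer_motifs")
  cy <- vapply(per_frame, `[[`, integer(1), "n_cyclic")
  qs <- if (length(pooled)) stats::quantile(pooled, c(0.25, 0.5, 0.75),
                                            type = 7, names = FALSE)
        else rep(NA_real_, 3)
  sd0 <- function(x) if (length(x) > 1) stats::sd(x) else 0
  structure(list(
    n_networks_mean = mean(nn), n_networks_sd = sd0(nn),
    bonds_mean = if (length(pooled)) mean(pooled) else NA_real_,
    bonds_sd = if (length(pooled)) sd0(pooled) else NA_real_,
    q1 = qs[1], median = qs[2], q3 = qs[3],
    max = if (length(pooled)) max(pooled) else NA_integer_,
    dimer_networks_mean = mean(dn),
    dimer_motifs_mean = mean(dmot),
    cyclic_mean = mean(cy),
    n_frames = length(per_frame)), class = "hb_network_summary")
}

#' @export
print.hb_network_summary <- function(x, ...) {
  cat(sprintf(paste0(
    "hydrogen-bond networks over %d frame(s)\n",
    "  networks/frame: %.2f +/- %.2f\n",
    "  bonds/network (pooled): %.2f +/- %.2f  [Q1 %.4g, median %.4g, Q3 %.4g, max %s]\n",
    "  dimer-containing networks/frame: %.3f (motifs %.3f)\n",
    "  cyclic networks/frame: %.3f\n"),
    x$n_frames, x$n_networks_mean, x$n_networks_sd, x$bonds_mean, x$bonds_sd,
    x$q1, x$median, x$q3, format(x$max),
    x$dimer_networks_mean, x$dimer_motifs_mean, x$cyclic_mean))
  invisible(x)
}

#' Network statistics for a whole trajectory
#'
#' Convenience wrapper: detect bonds per frame (or take a precomputed bond
#' table), build the molecule graph, and summarise.
#'
#' @param bond_table Bond table over a trajectory.
#' @param topology An [hb_topology()].
#' @param n_frames Number of frames analysed.
#' @return An `hb_network_summary`.
#' @export
network_summary_from_bonds <- function(bond_table, topology, n_frames) {
  per_frame <- lapply(seq_len(n_frames) - 1L, function(fi) {
    frame_network_stats(build_graph(
      bond_table[bond_table$frame == fi, , drop = FALSE], topology))
  })
  summarize_networks(per_frame)
}
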