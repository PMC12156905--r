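## Core data model: simulation box, role-tagged topology, frames,
## trajectories and columnar time series.

HB_ROLES <- c("OH_oxygen", "OH_hydrogen", "OE_oxygen", "terminal_carbon", "other")

#' Orthorhombic simulation box
#'
#' @param lengths Numeric vector of the three edge lengths in nm.  Triclinic
#'   boxes (nine-component box specifications with non-zero off-diagonal
#'   elements) are not supported and are rejected.
#' @return An object of class `hb_box`: a numeric length-3 vector.
#' @examples
#' hb_box(c(3, 3, 3))
#' @export
hb_box <- function(lengths) {
  lengths <- as.numeric(lengths)
  if (length(lengths) == 9) {
    if (any(abs(lengths[4:9]) > 0)) {
      stop("triclinic boxes are not supported; only orthorhombic boxes ",
           "(three edge lengths) are accepted", call. = FALSE)
    }
    lengths <- lengths[1:3]
  }
  if (length(lengths) != 3 || anyNA(lengths)) {
    stop("box must have exactly three edge lengths", call. = FALSE)
  }
  if (any(lengths <= 0)) {
    stop("box edge lengths must all be positive", call. = FALSE)
  }
  structure(lengths, class = "hb_box")
}

#' @export
print.hb_box <- function(x, ...) {
  cat(sprintf("orthorhombic box: %.4f x %.4f x %.4f nm\n", x[1], x[2], x[3]))
  invisible(x)
}

#' Role-tagged molecular topology
#'
#' A topology assigns each atom a 0-based `atom_id`, a 0-based `molecule_id`
#' and a role from `OH_oxygen`, `OH_hydrogen`, `OE_oxygen`,
#' `terminal_carbon`, `other`.  Roles drive all hydrogen-bond selections:
#' hydroxyl oxygens donate (through their molecule's hydroxyl hydrogen) and
#' accept; ether oxygens only accept.
#'
#' @param atoms data.frame with columns `atom_id`, `molecule_id`, `name`,
#'   `element`, `role`.  `atom_id` must be the dense sequence 0..n-1.
#' @param species_label Free-text label for the species.
#' @param n_separation Number of carbons separating the hydroxyl and ether
#'   oxygens (0 means the species has no ether oxygen at all).
#' @param strict If `TRUE`, enforce the hydrogen-bonding invariants: exactly
#'   one `OH_oxygen` and one `OH_hydrogen` per molecule, at most one
#'   `OE_oxygen`, and `n_separation == 0` exactly when no ether oxygen is
#'   present.  Generators of role-free particle systems (Brownian tracers,
#'   ideal gas) use `strict = FALSE`.
#' @return An object of class `hb_topology`.
#' @export
hb_topology <- function(atoms, species_label = "unknown", n_separation = 0L,
                        strict = TRUE) {
  required <- c("atom_id", "molecule_id", "name", "element", "role")
  missing <- setdiff(required, names(atoms))
  if (length(missing)) {
    stop("topology atoms table lacks columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  atoms <- atoms[required]
  atoms$atom_id <- as.integer(atoms$atom_id)
  atoms$molecule_id <- as.integer(atoms$molecule_id)
  atoms$role <- as.character(atoms$role)
  if (!all(atoms$role %in% HB_ROLES)) {
    stop("unknown atom role(s): ",
         paste(unique(setdiff(atoms$role, HB_ROLES)), collapse = ", "),
         call. = FALSE)
  }
  atoms <- atoms[order(atoms$atom_id), , drop = FALSE]
  rownames(atoms) <- NULL
  if (!identical(atoms$atom_id, seq_len(nrow(atoms)) - 1L)) {
    stop("atom_ids must be dense, unique and 0-based", call. = FALSE)
  }
  n_separation <- as.integer(n_separation)
  if (is.na(n_separation) || n_separation < 0L) {
    stop("n_separation must be a non-negative integer", call. = FALSE)
  }
  topo <- structure(
    list(atoms = atoms,
         n_molecules = length(unique(atoms$molecule_id)),
         species_label = as.character(species_label),
         n_separation = n_separation),
    class = "hb_topology")
  if (strict) validate_topology(topo)
  topo
}

#' Validate the hydrogen-bonding invariants of a topology
#'
#' @param topology An `hb_topology`.
#' @return The topology, invisibly; errors name the offending molecule.
#' @export
validate_topology <- function(topology) {
  stopifnot(inherits(topology, "hb_topology"))
  atoms <- topology$atoms
  for (role in c("OH_oxygen", "OH_hydrogen")) {
    tab <- table(factor(atoms$molecule_id[atoms$role == role],
                        levels = sort(unique(atoms$molecule_id))))
    bad <- names(tab)[tab != 1L]
    if (length(bad)) {
      stop(sprintf("molecule %s has %s %s atoms (exactly one required)",
                   bad[1], tab[bad[1]], role), call. = FALSE)
    }
  }
  oe <- table(atoms$molecule_id[atoms$role == "OE_oxygen"])
  if (any(oe > 1L)) {
    stop(sprintf("molecule %s has more than one OE_oxygen",
                 names(oe)[oe > 1L][1]), call. = FALSE)
  }
  has_oe <- any(atoms$role == "OE_oxygen")
  if (has_oe && topology$n_separation == 0L) {
    stop("n_separation = 0 but an OE_oxygen is present", call. = FALSE)
  }
  if (!has_oe && topology$n_separation > 0L) {
    stop("n_separation > 0 but no OE_oxygen is present", call. = FALSE)
  }
  invisible(topology)
}

#' @export
print.hb_topology <- function(x, ...) {
  cat(sprintf("hb_topology: %d atoms, %d molecules, species '%s' (n = %d)\n",
              nrow(x$atoms), x$n_molecules, x$species_label, x$n_separation))
  print(table(x$atoms$role))
  invisible(x)
}

#' Single trajectory frame
#'
#' @param time Frame time in ps.
#' @param coordinates N x 3 numeric matrix of positions in nm.
#' @param box An [hb_box()].
#' @return An object of class `hb_frame`.
#' @export
hb_frame <- function(time, coordinates, box) {
  coordinates <- as.matrix(coordinates)
  if (ncol(coordinates) != 3 || !is.numeric(coordinates)) {
    stop("coordinates must be an N x 3 numeric matrix", call. = FALSE)
  }
  dimnames(coordinates) <- NULL
  if (!inherits(box, "hb_box")) box <- hb_box(box)
  structure(list(time = as.numeric(time), coordinates = coordinates, box = box),
            class = "hb_frame")
}

#' Time-ordered trajectory with uniform frame spacing
#'
#' Frames must share one box (constant-volume assumption) and be spaced by a
#' constant interval `dt`: the persistence analysis converts frame counts to
#' time, so non-uniform spacing is an error rather than something to resample.
#'
#' @param frames List of [hb_frame()] objects with strictly increasing times.
#' @param dt Frame spacing in ps; inferred from the times if omitted.
#' @param tol Tolerance on spacing uniformity (ps).
#' @return Object of class `hb_trajectory` with elements `frames`, `dt`,
#'   `times`, `box`, `n_atoms`.
#' @export
hb_trajectory <- function(frames, dt = NULL, tol = 1e-6) {
  if (!length(frames)) stop("trajectory needs at least one frame", call. = FALSE)
  stopifnot(all(vapply(frames, inherits, logical(1), "hb_frame")))
  times <- vapply(frames, function(f) f$time, numeric(1))
  if (length(times) > 1) {
    steps <- diff(times)
    if (any(steps <= 0)) stop("frame times must be strictly increasing", call. = FALSE)
    if (is.null(dt)) dt <- steps[1]
    if (any(abs(steps - dt) > tol)) {
      stop("frame spacing is not uniform (tolerance ", tol, " ps); ",
           "resampling is not performed", call. = FALSE)
    }
  } else if (is.null(dt)) {
    dt <- 1
  }
  box <- frames[[1]]$box
  same_box <- vapply(frames, function(f) isTRUE(all.equal(as.numeric(f$box),
                                                          as.numeric(box))),
                     logical(1))
  if (!all(same_box)) stop("all frames must share one box", call. = FALSE)
  n_atoms <- nrow(frames[[1]]$coordinates)
  if (!all(vapply(frames, function(f) nrow(f$coordinates), integer(1)) == n_atoms)) {
    stop("all frames must have the same atom count", call. = FALSE)
  }
  structure(list(frames = frames, dt = as.numeric(dt), times = times,
                 box = box, n_atoms = n_atoms),
            class = "hb_trajectory")
}

#' @export
print.hb_trajectory <- function(x, ...) {
  cat(sprintf("hb_trajectory: %d frames x %d atoms, dt = %g ps, box %s nm\n",
              length(x$frames), x$n_atoms, x$dt,
              paste(signif(as.numeric(x$box), 5), collapse = " x ")))
  invisible(x)
}

#' Columnar time series
#'
#' Thin wrapper for time-stamped numeric columns (centre-of-mass positions,
#' pressure-tensor components, mean squared displacements, ...).
#'
#' @param times Numeric vector, ps.
#' @param columns data.frame (or named list) of numeric columns, all the same
#'   length as `times`.
#' @return data.frame of class `hb_series` whose first column is `time`.
#' @export
hb_series <- function(times, columns) {
  columns <- as.data.frame(columns)
  if (nrow(columns) != length(times)) {
    stop("all series columns must have the same length as times", call. = FALSE)
  }
  out <- cbind(data.frame(time = as.numeric(times)), columns)
  class(out) <- c("hb_series", "data.frame")
  out
}

series_dt <- function(series, tol = 1e-6) {
  steps <- diff(series$time)
  if (!length(steps)) stop("series has fewer than two samples", call. = FALSE)
  if (any(abs(steps - steps[1]) > tol)) {
    stop("series time spacing is not uniform", call. = FALSE)
  }
  steps[1]
}
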