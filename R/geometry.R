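## Periodic-boundary geometry primitives (minimum image convention).

#' Minimum-image separation vector
#'
#' Returns `b - a` with each component wrapped into `[-L/2, L/2)`, i.e. the
#' displacement to the nearest periodic copy of `b`.
#'
#' @param a,b Positions in nm: length-3 vectors or N x 3 matrices (recycled
#'   row-wise against each other).
#' @param box An [hb_box()].
#' @return Length-3 vector or N x 3 matrix of wrapped displacements, nm.
#' @examples
#' min_image_vector(c(0.05, 0, 0), c(2.80, 0, 0), hb_box(c(3, 3, 3)))
#' @export
min_image_vector <- function(a, b, box) {
  if (!inherits(box, "hb_box")) box <- hb_box(box)
  d <- if (is.matrix(a) || is.matrix(b)) {
    a <- matrix(a, ncol = 3)
    b <- matrix(b, ncol = 3)
    sweep_d <- b - a[rep_len(seq_len(nrow(a)), nrow(b)), , drop = FALSE]
    sweep_d
  } else {
    b - a
  }
  wrap_displacement(d, box)
}

## Wrap displacement components into [-L/2, L/2).
wrap_displacement <- function(d, box) {
  L <- as.numeric(box)
  if (is.matrix(d)) {
    for (k in 1:3) d[, k] <- d[, k] - L[k] * floor(d[, k] / L[k] + 0.5)
  } else {
    d <- d - L * floor(d / L + 0.5)
  }
  d
}

## Wrap absolute coordinates into [0, L).
wrap_positions <- function(x, box) {
  L <- as.numeric(box)
  for (k in 1:3) x[, k] <- x[, k] - L[k] * floor(x[, k] / L[k])
  x
}

#' Minimum-image distance between two positions
#'
#' @inheritParams min_image_vector
#' @return Distance in nm.
#' @export
min_image_distance <- function(a, b, box) {
  d <- min_image_vector(a, b, box)
  if (is.matrix(d)) sqrt(rowSums(d^2)) else sqrt(sum(d^2))
}

## All minimum-image distances between the rows of X (n x 3) and Y (m x 3):
## an n x m matrix.  Vectorised with per-axis outer differences.
cross_min_image_dist <- function(X, Y, box) {
  L <- as.numeric(box)
  d2 <- 0
  for (k in 1:3) {
    dk <- outer(X[, k], Y[, k], "-")
    dk <- dk - L[k] * floor(dk / L[k] + 0.5)
    d2 <- d2 + dk * dk
  }
  sqrt(d2)
}

#' Angle at a vertex under minimum imaging
#'
#' The angle between the minimum-image vectors `vertex -> p` and
#' `vertex -> q`, in degrees in `[0, 180]`.
#'
#' @param vertex,p,q Positions (length-3, nm).
#' @param box An [hb_box()].
#' @return Angle in degrees.
#' @export
angle_at <- function(vertex, p, q, box) {
  u <- min_image_vector(vertex, p, box)
  v <- min_image_vector(vertex, q, box)
  nu <- sqrt(sum(u^2))
  nv <- sqrt(sum(v^2))
  if (nu == 0 || nv == 0) {
    stop("zero-length vector at angle vertex", call. = FALSE)
  }
  cosang <- sum(u * v) / (nu * nv)
  cosang <- min(1, max(-1, cosang))
  acos(cosang) * 180 / pi
}

## Angles (degrees) at vertices V (n x 3) between V->P and V->Q, rowwise.
angles_at_rows <- function(V, P, Q, box) {
  U <- wrap_displacement(P - V, box)
  W <- wrap_displacement(Q - V, box)
  nu <- sqrt(rowSums(U^2))
  nw <- sqrt(rowSums(W^2))
  if (any(nu == 0 | nw == 0)) {
    stop("zero-length vector at angle vertex", call. = FALSE)
  }
  cosang <- rowSums(U * W) / (nu * nw)
  cosang <- pmin(1, pmax(-1, cosang))
  acos(cosang) * 180 / pi
}

## Make each molecule whole with respect to its first atom, so intramolecular
## geometry is unambiguous even after wrapping into the primary cell.
unwrap_molecules <- function(coords, molecule_id, box) {
  for (m in unique(molecule_id)) {
    idx <- which(molecule_id == m)
    if (length(idx) < 2) next
    ref <- coords[idx[1], ]
    d <- wrap_displacement(coords[idx, , drop = FALSE] -
                             matrix(ref, length(idx), 3, byrow = TRUE), box)
    coords[idx, ] <- matrix(ref, length(idx), 3, byrow = TRUE) + d
  }
  coords
}
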