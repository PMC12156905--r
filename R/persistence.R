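## Hydrogen-bond persistence: windowed bonded times, the complementary
## cumulative distribution of bonded time, and its single-exponential fit.
##
## Within consecutive non-overlapping windows of `window_frames` frames,
## each unique directed (donor_O, acceptor_O) pair observed at least once
## accumulates time_bonded = (#frames bonded) * dt, regardless of whether
## the bond is continuously formed.  The CCDF over a window of length W is
## P(t) = 1 - sum_{i <= t} Count(i) / TotalCount on a dt-spaced grid, and is
## fitted with P_fit(t) = C * exp(-gamma * t).

#' Windowed bonded times per unique bond pair
#'
#' @param bond_table Bond table over a trajectory (see [detect_hbonds()]).
#' @param dt Frame spacing, ps.
#' @param window_frames Frames per window (default 500, i.e. 5000 ps at
#'   dt = 10 ps).
#' @param n_frames Total frames analysed; defaults to `max(frame) + 1`.
#'   Only complete windows are used.
#' @return data.frame with columns `window`, `donor_O`, `acceptor_O`,
#'   `class`, `frames_bonded`, `time_bonded` (ps).  Pair identity is
#'   directional: A->B and B->A are distinct pairs.
#' @export
bonded_times <- function(bond_table, dt = 10, window_frames = 500L,
                         n_frames = NULL) {
  if (is.null(n_frames)) {
    n_frames <- if (nrow(bond_table)) max(bond_table$frame) + 1L else 0L
  }
  n_windows <- n_frames %/% window_frames
  if (n_windows < 1L) {
    stop("bond table spans fewer frames (", n_frames,
         ") than one window (", window_frames, ")", call. = FALSE)
  }
  tab <- bond_table[bond_table$frame < n_windows * window_frames, , drop = FALSE]
  if (!nrow(tab)) {
    return(data.frame(window = integer(0), donor_O = integer(0),
                      acceptor_O = integer(0), class = character(0),
                      frames_bonded = integer(0), time_bonded = numeric(0)))
  }
  ## a pair may satisfy the criteria twice in one frame only through distinct
  ## hydrogens, which the single-OH topology excludes; dedupe defensively
  tab <- tab[!duplicated(tab[c("frame", "donor_O", "acceptor_O")]), , drop = FALSE]
  win <- tab$frame %/% window_frames
  key <- paste(win, tab$donor_O, tab$acceptor_O, sep = "|")
  agg <- stats::aggregate(list(frames_bonded = rep(1L, nrow(tab))),
                          by = list(window = win, donor_O = tab$donor_O,
                                    acceptor_O = tab$acceptor_O,
                                    class = tab$class), FUN = sum)
  agg$time_bonded <- agg$frames_bonded * dt
  agg <- agg[order(agg$window, agg$donor_O, agg$acceptor_O), , drop = FALSE]
  rownames(agg) <- NULL
  agg
}

#' Complementary cumulative distribution of bonded times
#'
#' Bin width equals the frame spacing `dt`; the grid runs from `dt` to the
#' largest observed bonded time.  `P(t)` is the probability that a unique
#' pair's bonded time exceeds `t`; it is non-increasing and reaches exactly
#' zero at the last bin.
#'
#' @param times_bonded Multiset of bonded times (ps), all positive multiples
#'   of `dt`.
#' @param dt Bin width, ps.
#' @return Object of class `hb_ccdf`: list with `times`, `P`, `counts`,
#'   `total_count`, `dt`.
#' @export
bond_ccdf <- function(times_bonded, dt) {
  if (!length(times_bonded)) stop("empty bonded-time multiset", call. = FALSE)
  k <- as.integer(round(times_bonded / dt))
  if (any(k < 1) || any(abs(times_bonded - k * dt) > 1e-6 * dt)) {
    stop("bonded times must be positive multiples of dt", call. = FALSE)
  }
  counts <- tabulate(k, nbins = max(k))
  total <- sum(counts)
  P <- 1 - cumsum(counts) / total
  structure(list(times = seq_along(counts) * dt, P = P, counts = counts,
                 total_count = total, dt = dt), class = "hb_ccdf")
}

#' @export
print.hb_ccdf <- function(x, ...) {
  cat(sprintf("bonded-time CCDF: %d pairs, %d bins of %g ps, P(first) = %.4f\n",
              x$total_count, length(x$P), x$dt, x$P[1]))
  invisible(x)
}

#' Fit a single-exponential decay to a CCDF
#'
#' Nonlinear least squares of `C * exp(-gamma * t)` against `P(t)` on the
#' linear scale, over bins with `P > 0` (and, when bin counts are available,
#' with at least one observation).  `C` is a free coefficient, not pinned to
#' one.  Starting values: `C0 = max(P)`, `gamma0 = 1 / mean(time bonded)`.
#'
#' @param ccdf An `hb_ccdf`, or a list with elements `times` and `P`.
#' @return Object of class `hb_persistence_fit`: list with `C`, `gamma`
#'   (1/ps), `fit_rms`, `n_points`.
#' @export
fit_persistence <- function(ccdf) {
  t_all <- ccdf$times
  P_all <- ccdf$P
  keep <- P_all > 0
  if (!is.null(ccdf$counts)) keep <- keep & ccdf$counts > 0
  t <- t_all[keep]
  P <- P_all[keep]
  if (length(t) < 3) {
    stop("need at least 3 CCDF points with P > 0 to fit", call. = FALSE)
  }
  mean_time <- if (!is.null(ccdf$counts)) {
    sum(ccdf$times * ccdf$counts) / sum(ccdf$counts)
  } else {
    ## trapezoidal integral of P approximates the mean above the first bin
    max(t_all[1] + sum(P_all) * (t_all[2] - t_all[1]), t_all[1])
  }
  start <- list(C = max(P), gamma = 1 / mean_time)
  fit <- tryCatch(
    minpack.lm::nlsLM(P ~ C * exp(-gamma * t),
                      start = start,
                      control = minpack.lm::nls.lm.control(
                        ftol = 1e-10, ptol = 1e-10, maxiter = 500)),
    error = function(e) {
      stop("exponential fit failed to converge (start C = ",
           signif(start$C, 6), ", gamma = ", signif(start$gamma, 6),
           "): ", conditionMessage(e), call. = FALSE)
    })
  co <- stats::coef(fit)
  if (!is.finite(co[["gamma"]]) || co[["gamma"]] <= 0 || co[["C"]] <= 0) {
    stop("exponential fit did not converge to a decaying solution ",
         "(gamma = ", signif(co[["gamma"]], 6), ", C = ",
         signif(co[["C"]], 6), "); input may be non-decaying", call. = FALSE)
  }
  structure(list(C = unname(co[["C"]]), gamma = unname(co[["gamma"]]),
                 fit_rms = sqrt(mean(stats::residuals(fit)^2)),
                 n_points = length(t)),
            class = "hb_persistence_fit")
}

#' @export
print.hb_persistence_fit <- function(x, ...) {
  cat(sprintf("P(t) ~ C exp(-gamma t): C = %.4f, gamma = %.6g 1/ps (rms %.3g, %d points)\n",
              x$C, x$gamma, x$fit_rms, x$n_points))
  invisible(x)
}

#' Per-class persistence analysis of a bond table
#'
#' Splits the trajectory into consecutive non-overlapping windows, pools the
#' per-window bonded times per bond class, and fits each class CCDF.
#'
#' @inheritParams bonded_times
#' @return Named list per class present in the table: each element has
#'   `ccdf` and `fit` (NULL with a warning if a class has too few points to
#'   fit).
#' @export
persistence_by_class <- function(bond_table, dt = 10, window_frames = 500L,
                                 n_frames = NULL) {
  bt <- bonded_times(bond_table, dt = dt, window_frames = window_frames,
                     n_frames = n_frames)
  out <- list()
  for (cls in intersect(HB_CLASSES, unique(bt$class))) {
    times <- bt$time_bonded[bt$class == cls]
    ccdf <- bond_ccdf(times, dt)
    fit <- tryCatch(fit_persistence(ccdf), error = function(e) {
      warning("class ", cls, ": ", conditionMessage(e), call. = FALSE)
      NULL
    })
    out[[cls]] <- list(ccdf = ccdf, fit = fit)
  }
  out
}
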