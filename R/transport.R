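## Transport properties: mean squared displacement and self-diffusion,
## finite-size correction, Green-Kubo shear viscosity, Stokes-Einstein
## products and two-point Arrhenius activation energies.
##
## Inputs arrive in simulation units (nm, ps, bar); outputs are SI.

## Exact all-origin MSD of one scalar signal via the FFT identity
## sum_t (x_{t+m} - x_t)^2 = S1(m) - 2 S2(m), with S2 the unnormalised
## autocorrelation computed in O(F log F).
msd_fft_1d <- function(x) {
  F <- length(x)
  n_pad <- 2^ceiling(log2(2 * F))
  fx <- stats::fft(c(x, numeric(n_pad - F)))
  s2 <- Re(stats::fft(Mod(fx)^2, inverse = TRUE))[1:F] / n_pad
  D <- x * x
  total <- sum(D)
  m <- 0:(F - 1)
  head_m <- c(0, cumsum(D))[m + 1L]          # sum of the first m terms
  tail_m <- c(0, cumsum(rev(D)))[m + 1L]     # sum of the last m terms
  s1 <- 2 * total - head_m - tail_m
  (s1 - 2 * s2) / (F - m)
}

#' Mean squared displacement from unwrapped positions
#'
#' Averages over all molecules and all time origins (overlapping windows) at
#' every lag, using an FFT-based algorithm so the cost is `O(N F log F)`
#' rather than `O(N F^2)`.  Positions must be unwrapped (continuous);
#' passing a box enables a jump check that rejects wrapped input.
#'
#' @param com_series An [hb_series()] of unwrapped centre-of-mass positions:
#'   after the `time` column, three columns (x, y, z in nm) per molecule.
#' @param box Optional [hb_box()]; if given, any single-step displacement
#'   larger than half a box edge raises an error advising unwrapping.
#' @param max_lags Lags above this count are decimated onto a logarithmic
#'   grid (cost control for very long series).
#' @return An [hb_series()] with columns `time` (lag, ps) and `msd` (nm^2),
#'   starting at lag `dt`.
#' @export
msd_from_positions <- function(com_series, box = NULL, max_lags = 1000L) {
  dt <- series_dt(com_series)
  cols <- as.matrix(com_series[, -1, drop = FALSE])
  if (ncol(cols) %% 3 != 0) {
    stop("position series must have three columns (x, y, z) per molecule",
         call. = FALSE)
  }
  if (!is.null(box)) {
    L <- as.numeric(hb_box(box))
    jumps <- abs(diff(cols))
    lim <- rep(L, each = 1)[((seq_len(ncol(cols)) - 1) %% 3) + 1] / 2
    if (any(sweep(jumps, 2, lim, ">"))) {
      stop("wrapped coordinates detected (single-step jump > L/2); ",
           "unwrap positions before computing the MSD", call. = FALSE)
    }
  }
  F <- nrow(cols)
  if (F < 2) stop("need at least two frames for an MSD", call. = FALSE)
  n_mol <- ncol(cols) / 3
  msd <- numeric(F)
  for (j in seq_len(ncol(cols))) msd <- msd + msd_fft_1d(cols[, j])
  msd <- msd / n_mol
  lags <- seq_len(F - 1L)
  if (length(lags) > max_lags) {
    keep <- lags <= max_lags
    logged <- unique(round(exp(seq(log(max_lags + 1), log(max(lags)),
                                   length.out = max_lags %/% 4))))
    lags <- sort(unique(c(lags[keep], logged)))
  }
  hb_series(lags * dt, data.frame(msd = msd[lags + 1L]))
}

#' Linear fit of the diffusive regime of an MSD
#'
#' Ordinary least squares of `MSD(t) = 6 D(L) t + c` over a window of the
#' available lags (default 10 to 50 percent), with the slope converted from
#' nm^2/ps to m^2/s.  A log-log slope over the same window is reported as a
#' diagnostic (it should be close to one in a truly diffusive regime).
#'
#' @param msd_series An [hb_series()] with columns `time` (ps) and `msd`
#'   (nm^2).
#' @param window_fractions Length-2 fractions of the maximum lag delimiting
#'   the fit window.
#' @return Object of class `hb_msd_fit`: list with `D_L` (m^2/s),
#'   `intercept` (nm^2), `window` (ps), `slope_rms` (residual rms, nm^2),
#'   `loglog_slope`, `n_points`.
#' @export
fit_msd <- function(msd_series, window_fractions = c(0.1, 0.5)) {
  stopifnot(length(window_fractions) == 2,
            window_fractions[1] < window_fractions[2])
  t <- msd_series$time
  y <- msd_series$msd
  t_max <- max(t)
  keep <- t >= window_fractions[1] * t_max & t <= window_fractions[2] * t_max
  if (sum(keep) < 2) stop("MSD fit window contains fewer than 2 points",
                          call. = FALSE)
  if (stats::sd(y[keep]) == 0) {
    stop("non-diffusive input: MSD is constant over the fit window",
         call. = FALSE)
  }
  fit <- stats::lm(y[keep] ~ t[keep])
  slope <- unname(stats::coef(fit)[2])
  if (!is.finite(slope) || slope <= 0) {
    stop("non-diffusive input: fitted MSD slope is not positive (",
         signif(slope, 6), " nm^2/ps)", call. = FALSE)
  }
  pos <- keep & y > 0 & t > 0
  loglog <- if (sum(pos) >= 2) {
    unname(stats::coef(stats::lm(log(y[pos]) ~ log(t[pos])))[2])
  } else NA_real_
  structure(list(D_L = slope / 6 * hb_constants$nm2_ps_to_m2_s,
                 intercept = unname(stats::coef(fit)[1]),
                 window = range(t[keep]),
                 slope_rms = sqrt(mean(stats::residuals(fit)^2)),
                 loglog_slope = loglog,
                 n_points = sum(keep)),
            class = "hb_msd_fit")
}

#' @export
print.hb_msd_fit <- function(x, ...) {
  cat(sprintf("D(L) = %.6g m^2/s (window %.4g-%.4g ps, log-log slope %.3f)\n",
              x$D_L, x$window[1], x$window[2], x$loglog_slope))
  invisible(x)
}

#' Finite-size correction of the self-diffusion coefficient
#'
#' Adds the analytic hydrodynamic correction for a cubic periodic box:
#' `D_inf = D_L + kB T xi / (6 pi eta L)` with `xi = 2.837298`.
#'
#' @param D_L Box-size-dependent diffusion coefficient, m^2/s.
#' @param T Temperature, K.
#' @param eta Shear viscosity, Pa s.
#' @param L Box edge, m.
#' @return Object of class `hb_corrected_diffusion`: list with `D_inf`,
#'   `correction_term` (both m^2/s), and the echoed inputs `T`, `eta`, `L`,
#'   `xi`.
#' @export
yeh_hummer <- function(D_L, T, eta, L) {
  stopifnot(D_L > 0, T > 0, eta > 0, L > 0)
  corr <- hb_constants$kB * T * hb_constants$xi_cubic / (6 * pi * eta * L)
  structure(list(D_inf = D_L + corr, correction_term = corr, D_L = D_L,
                 T = T, eta = eta, L = L, xi = hb_constants$xi_cubic),
            class = "hb_corrected_diffusion")
}

#' @export
print.hb_corrected_diffusion <- function(x, ...) {
  cat(sprintf("D_inf = %.6g m^2/s = D(L) %.6g + correction %.6g (%.1f%%)\n",
              x$D_inf, x$D_L, x$correction_term,
              100 * x$correction_term / x$D_L))
  invisible(x)
}

## Unnormalised-mean autocorrelation a(m) = (1/(n-m)) sum_t x_t x_{t+m},
## lags 0..max_lag, via FFT.
acf_fft <- function(x, max_lag) {
  n <- length(x)
  n_pad <- 2^ceiling(log2(2 * n))
  fx <- stats::fft(c(x, numeric(n_pad - n)))
  raw <- Re(stats::fft(Mod(fx)^2, inverse = TRUE))[1:(max_lag + 1L)] / n_pad
  raw / (n - 0:max_lag)
}

#' Green-Kubo shear viscosity from pressure-tensor fluctuations
#'
#' `eta = V/(kB T) * integral of <P_ab(0) P_ab(t)> dt`, with the
#' autocorrelation averaged over the off-diagonal pressure components and
#' the integral taken as the plateau of the running integral.  Statistics
#' are improved by splitting the series into consecutive time blocks,
#' estimating the plateau in each by fitting `A (1 - exp(-t/tau))` to the
#' running integral, and averaging the per-block `A`.
#'
#' @param stress_series An [hb_series()]: `time` (ps) plus at least three
#'   off-diagonal pressure components (bar), e.g. Pxy, Pxz, Pyz.
#' @param V Box volume, m^3.
#' @param T Temperature, K.
#' @param n_blocks Number of consecutive time blocks (default 5).
#' @param max_lag Autocorrelation length in samples; default 5 percent of a
#'   block.  The running integral must reach its plateau well inside this
#'   range.
#' @return Object of class `hb_viscosity`: list with `eta` (Pa s),
#'   `block_estimates`, `n_blocks`, `running_integral` (an [hb_series()]
#'   averaged over blocks, Pa s), `tau` (mean fitted correlation time, ps).
#' @export
green_kubo_viscosity <- function(stress_series, V, T, n_blocks = 5L,
                                 max_lag = NULL) {
  stopifnot(V > 0, T > 0, n_blocks >= 1)
  dt <- series_dt(stress_series)
  comp <- as.matrix(stress_series[, -1, drop = FALSE])
  if (ncol(comp) < 3) {
    stop("need at least three off-diagonal pressure components", call. = FALSE)
  }
  if (all(apply(comp, 2, stats::sd) == 0)) {
    stop("pressure components carry no fluctuations; viscosity must be ",
         "positive", call. = FALSE)
  }
  n <- nrow(comp)
  block_len <- n %/% n_blocks
  if (is.null(max_lag)) max_lag <- max(10L, block_len %/% 20L)
  if (max_lag >= block_len) {
    stop("max_lag must be smaller than a block", call. = FALSE)
  }
  to_SI <- hb_constants$bar_to_Pa^2 * hb_constants$ps_to_s
  pref <- V / (hb_constants$kB * T)
  t_lag <- (1:max_lag) * dt

  run_sum <- numeric(max_lag)
  block_eta <- numeric(n_blocks)
  block_tau <- numeric(n_blocks)
  for (b in seq_len(n_blocks)) {
    rows <- ((b - 1L) * block_len + 1L):(b * block_len)
    C <- rowMeans(vapply(seq_len(ncol(comp)), function(j) {
      x <- comp[rows, j]
      acf_fft(x - mean(x), max_lag)
    }, numeric(max_lag + 1L)))
    ## cumulative trapezoid of the ACF, then to SI
    integ <- dt * (cumsum(C)[-1] - (C[1] + C[2:(max_lag + 1L)]) / 2)
    run <- pref * integ * to_SI
    run_sum <- run_sum + run
    A0 <- mean(utils::tail(run, max(3L, length(run) %/% 5L)))
    cross <- which(run >= (1 - exp(-1)) * A0)
    tau0 <- if (length(cross)) max(t_lag[cross[1]], dt) else max(t_lag) / 10
    fit <- tryCatch(
      minpack.lm::nlsLM(run ~ A * (1 - exp(-t_lag / tau)),
                        start = list(A = A0, tau = tau0),
                        control = minpack.lm::nls.lm.control(maxiter = 500)),
      error = function(e) NULL)
    if (is.null(fit)) {
      stop("running Green-Kubo integral shows no plateau in block ", b,
           " (tail value ", signif(A0, 6), " Pa s); extend the series or ",
           "max_lag", call. = FALSE)
    }
    co <- stats::coef(fit)
    block_eta[b] <- co[["A"]]
    block_tau[b] <- co[["tau"]]
  }
  eta <- mean(block_eta)
  if (!is.finite(eta) || eta <= 0) {
    stop("Green-Kubo viscosity estimate is not positive (", signif(eta, 6),
         " Pa s)", call. = FALSE)
  }
  structure(list(eta = eta, block_estimates = block_eta,
                 n_blocks = n_blocks, tau = mean(block_tau),
                 running_integral = hb_series(
                   t_lag, data.frame(eta_running = run_sum / n_blocks))),
            class = "hb_viscosity")
}

#' @export
print.hb_viscosity <- function(x, ...) {
  cat(sprintf("eta = %.6g Pa s (%d blocks, spread %.3g, tau ~ %.4g ps)\n",
              x$eta, x$n_blocks, stats::sd(x$block_estimates), x$tau))
  invisible(x)
}

#' Stokes-Einstein product and hydrodynamic radius
#'
#' From `D = kB T / (xi pi eta r)`: the product `D eta / T` (SI) and the
#' implied hydrodynamic radius `r = kB T / (xi pi eta D)` for a boundary
#' constant `xi` between 4 (slip) and 6 (stick).
#'
#' @param D Self-diffusion coefficient, m^2/s.
#' @param eta Viscosity, Pa s.
#' @param T Temperature, K.
#' @param xi_SE Boundary-condition constant in `[4, 6]` (default 6).
#' @return List with `SE_product` (D eta / T) and `r` (m).
#' @export
stokes_einstein <- function(D, eta, T, xi_SE = 6) {
  stopifnot(D > 0, eta > 0, T > 0)
  if (xi_SE < 4 || xi_SE > 6) {
    stop("xi_SE must lie in [4, 6]", call. = FALSE)
  }
  list(SE_product = D * eta / T,
       r = hb_constants$kB * T / (xi_SE * pi * eta * D))
}

#' Two-point Arrhenius activation energy
#'
#' `Ea = R ln(x(T1)/x(T2)) / (1/T2 - 1/T1)` in kJ/mol.  With
#' `process = "diffusion"` a property that increases with temperature gives
#' a positive activation energy; `process = "viscosity"` flips the sign
#' (equivalently, applies the formula to the reciprocal property), so a
#' viscosity that drops with temperature is also a positive barrier.
#'
#' @param x_T1,x_T2 Property values at `T1` and `T2` (both positive).
#' @param T1,T2 Temperatures, K (distinct).
#' @param process `"diffusion"` (default) or `"viscosity"`.
#' @return Activation energy, kJ/mol.
#' @examples
#' arrhenius_activation_energy(1, 2, 298, 358)   # ~10.2 kJ/mol
#' @export
arrhenius_activation_energy <- function(x_T1, x_T2, T1, T2,
                                        process = c("diffusion", "viscosity")) {
  process <- match.arg(process)
  if (x_T1 <= 0 || x_T2 <= 0) stop("property values must be positive",
                                   call. = FALSE)
  if (T1 <= 0 || T2 <= 0 || T1 == T2) {
    stop("temperatures must be positive and distinct", call. = FALSE)
  }
  Ea <- hb_constants$R * log(x_T1 / x_T2) / (1 / T2 - 1 / T1) / 1000
  if (process == "viscosity") Ea <- -Ea
  Ea
}
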