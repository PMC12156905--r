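## Physical constants and unit conversions.
##
## Internal unit policy: lengths in nm, times in ps, temperatures in K,
## pressures in bar.  Conversions to SI happen only inside the transport
## formulas, through the constants below.

#' Physical constants used by the transport formulas
#'
#' Boltzmann constant (J/K), molar gas constant (J/mol/K), the dimensionless
#' hydrodynamic self-interaction constant of the periodic-lattice finite-size
#' correction for a cubic box, and the conversion factors between simulation
#' units (nm, ps, bar) and SI.
#'
#' @format A named list:
#' \describe{
#'   \item{kB}{Boltzmann constant, 1.380649e-23 J/K (exact).}
#'   \item{R}{Molar gas constant, 8.314462618 J/mol/K.}
#'   \item{xi_cubic}{2.837298, the lattice constant entering the cubic-box
#'     finite-size diffusion correction.}
#'   \item{nm2_ps_to_m2_s}{1e-6: converts nm^2/ps to m^2/s.}
#'   \item{bar_to_Pa}{1e5.}
#'   \item{ps_to_s}{1e-12.}
#'   \item{nm_to_m}{1e-9.}
#' }
#' @export
hb_constants <- list(
  kB             = 1.380649e-23,
  R              = 8.314462618,
  xi_cubic       = 2.837298,
  nm2_ps_to_m2_s = 1e-6,
  bar_to_Pa      = 1e5,
  ps_to_s        = 1e-12,
  nm_to_m        = 1e-9
)
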