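#' Physical constants and membrane parameters
#'
#' Bundles the fundamental constants and the two membrane/bath parameters the
#' model depends on: absolute temperature and specific membrane capacitance.
#' All values are in strict SI units; conversions to mV/mM/pA happen only at
#' the I/O boundary.
#'
#' @param T_kelvin Absolute temperature (K). Default 310 K (body temperature).
#' @param c_m Specific membrane capacitance (F/m^2). Default 0.01 F/m^2,
#'   the standard 1 uF/cm^2 of neuronal membrane.
#' @return An object of class `pd_constants`: a list with elements `e`
#'   (elementary charge, C), `k_B` (Boltzmann constant, J/K), `N_A`
#'   (Avogadro constant, 1/mol), `T` (K) and `c_m` (F/m^2).
#' @examples
#' const <- physical_constants()
#' const$k_B * const$T   # thermal energy at 310 K, ~4.28e-21 J
#' @export
physical_constants <- function(T_kelvin = 310, c_m = 0.01) {
  stopifnot(T_kelvin > 0, c_m > 0)
  structure(
    list(
      e = 1.602176634e-19,
      k_B = 1.380649e-23,
      N_A = 6.02214076e23,
      T = T_kelvin,
      c_m = c_m
    ),
    class = "pd_constants"
  )
}

#' Convert a molar concentration to a number density
#'
#' The model equations work with number densities (particles per m^3) while
#' physiological concentrations are quoted in mM. 1 mM = 1 mmol/L = 1 mol/m^3
#' = N_A particles per m^3.
#'
#' @param c_mM Concentration in mM (millimol per litre). Must be >= 0.
#' @return Number density in 1/m^3.
#' @seealso [density_to_mm()] for the exact inverse.
#' @examples
#' mm_to_density(10)    # 6.022e24
#' @export
mm_to_density <- function(c_mM) {
  if (any(c_mM < 0)) stop("concentration must be non-negative")
  c_mM * 6.02214076e23
}

#' Convert a number density to a molar concentration
#'
#' @param n Number density in 1/m^3.
#' @return Concentration in mM.
#' @export
density_to_mm <- function(n) {
  n / 6.02214076e23
}
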