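#' Define a mobile ion species
#'
#' @param name Species label (e.g. "Na").
#' @param z Integer valence. Mobile physiological ions have z != 0; z = 0 is
#'   permitted for uncharged tracer species (they diffuse but carry no
#'   charge and do not enter the potential or the resistivities).
#' @param D Diffusion constant (m^2/s), > 0.
#' @param n_rest Resting concentration (mM), >= 0.
#' @return An object of class `ion_species`.
#' @examples
#' ion_species("Na", z = 1, D = 0.65e-9, n_rest = 10)
#' @export
ion_species <- function(name, z, D, n_rest) {
  stopifnot(is.character(name), length(name) == 1L,
            z == round(z), D > 0, n_rest >= 0)
  structure(list(name = name, z = as.integer(z), D = D, n_rest = n_rest),
            class = "ion_species")
}

#' Default intracellular ion species set
#'
#' Sodium, potassium and chloride at physiological resting concentrations
#' (10 / 140 / 10 mM) with diffusion constants 0.65, 1.00 and 1.00 x 1e-9
#' m^2/s. Sodium diffuses ~35% more slowly than potassium, which is what
#' makes the net diffusion current through the neck non-zero when sodium
#' accumulates and potassium is depleted by the same amount.
#'
#' @param D_Na,D_K,D_Cl Diffusion constants (m^2/s).
#' @param na,k,cl Resting concentrations (mM).
#' @return A named list of [ion_species()] objects.
#' @export
default_ion_species <- function(D_Na = 0.65e-9, D_K = 1.0e-9, D_Cl = 1.0e-9,
                                na = 10, k = 140, cl = 10) {
  list(
    Na = ion_species("Na", 1L, D_Na, na),
    K  = ion_species("K",  1L, D_K,  k),
    Cl = ion_species("Cl", -1L, D_Cl, cl)
  )
}

# internal: extract species vectors
species_table <- function(species) {
  list(
    name = vapply(species, `[[`, character(1), "name"),
    z = vapply(species, `[[`, integer(1), "z"),
    D = vapply(species, `[[`, numeric(1), "D"),
    n_rest = vapply(species, `[[`, numeric(1), "n_rest")
  )
}
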