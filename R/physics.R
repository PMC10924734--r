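#' Membrane potential from the net ionic charge
#'
#' The potential of each cylindrical segment follows from charging its
#' membrane capacitance with the net charge of the intracellular ions:
#' \deqn{\Phi_i = \frac{a_i}{2 c_m} \sum_k z_k e\, n_{k,i}}
#' where the sum runs over the mobile species plus the immobile background
#' charge (valence -1, density `n0`). The potential is never stored; it is
#' always recomputed from the concentrations, which keeps charge bookkeeping
#' exact by construction.
#'
#' @param n K x N matrix of number densities (1/m^3), one row per species in
#'   the order of `species`, one column per segment.
#' @param n0 Per-segment immobile background-charge density (1/m^3).
#' @param geom A [spine_geometry()].
#' @param species List of [ion_species()].
#' @param const A [physical_constants()].
#' @return Potential per segment (V).
#' @export
potential_from_concentrations <- function(n, n0, geom, species,
                                          const = physical_constants()) {
  sp <- species_table(species)
  stopifnot(nrow(n) == length(sp$z), ncol(n) == geom$n_seg,
            length(n0) == geom$n_seg)
  net <- drop(crossprod(n, sp$z)) - n0     # sum_k z_k n_k - n0
  geom$a / (2 * const$c_m) * const$e * net
}

#' Calibrate the immobile background charge for a target resting potential
#'
#' Inverts the capacitance relation segment-by-segment so that the resting
#' concentrations produce exactly `phi_rest` everywhere:
#' \deqn{n_{0,i} = \sum_k z_k n_k^{rest} - \frac{2 c_m \Phi^{rest}}{a_i e}}
#' Because the correction term scales with 1/a, the background charge is
#' per-segment (radius-dependent) even though it is constant in time.
#'
#' @inheritParams potential_from_concentrations
#' @param phi_rest Target resting potential (V), e.g. -0.070.
#' @return Per-segment background density (1/m^3).
#' @export
calibrate_background_charge <- function(geom, species, phi_rest,
                                        const = physical_constants()) {
  sp <- species_table(species)
  net_rest <- sum(sp$z * mm_to_density(sp$n_rest))
  n0 <- net_rest - 2 * const$c_m * phi_rest / (geom$a * const$e)
  if (any(n0 < 0))
    stop("calibrated background charge is negative; ",
         "resting concentrations and potential are inconsistent")
  n0
}

#' Drift resistivity of the electrolyte
#'
#' Axial resistivity for electric drift currents,
#' \deqn{r_e = \frac{k_B T}{\sum_k D_k e^2 z_k^2 n_k},}
#' summed over the mobile species only (the background charge is immobile
#' and carries no current).
#'
#' @param n K x N matrix (or K-vector) of number densities (1/m^3).
#' @inheritParams potential_from_concentrations
#' @return Resistivity per segment (Ohm m); `Inf` where all concentrations
#'   vanish.
#' @examples
#' sp <- default_ion_species()
#' n <- mm_to_density(vapply(sp, `[[`, numeric(1), "n_rest"))
#' drift_resistivity(n, sp)   # ~1.77 Ohm m at rest
#' @export
drift_resistivity <- function(n, species, const = physical_constants()) {
  sp <- species_table(species)
  n <- matrix(n, nrow = length(sp$z))
  w <- sp$D * const$e^2 * sp$z^2
  denom <- drop(crossprod(n, w))
  out <- const$k_B * const$T / denom
  out[denom == 0] <- Inf
  out
}

#' Per-species drift and diffusional resistivities
#'
#' For a single species, the drift resistivity is
#' \eqn{r_{e,k} = k_B T / (D_k e^2 z_k^2 n_k)} and the diffusional
#' resistivity (for electric currents carried by diffusion down a
#' chemical-potential gradient) is \eqn{r_{c,k} = r_{e,k}\, e z_k =
#' k_B T/(D_k e z_k n_k)}. The identity \eqn{r_{c,k} = r_{e,k} e z_k}
#' holds exactly; the parallel-conductance identity
#' \eqn{1/r_e = \sum_k 1/r_{e,k}} relates them to [drift_resistivity()].
#'
#' @param n_k Number density of the species (1/m^3), scalar or vector.
#' @param species_k A single [ion_species()] with z != 0.
#' @param const A [physical_constants()].
#' @return List with `r_e` (Ohm m) and `r_c` (Ohm m C); `Inf` at zero
#'   concentration.
#' @export
species_resistivities <- function(n_k, species_k,
                                  const = physical_constants()) {
  stopifnot(species_k$z != 0L)
  kT <- const$k_B * const$T
  r_e <- ifelse(n_k > 0,
                kT / (species_k$D * const$e^2 * species_k$z^2 * n_k), Inf)
  list(r_e = r_e, r_c = r_e * const$e * species_k$z)
}

#' Back-of-envelope estimators for spine ion budgets
#'
#' `estimate_ion_count()` counts the particles of a species in a given
#' volume; `estimate_influx_count()` counts the particles delivered by a
#' constant electric current; `estimate_decay_time()` is the classical
#' single-compartment diffusive equilibration time
#' \eqn{\tau = V L / (A D)} of a head of volume V coupled to a reservoir
#' through a neck of length L and cross-section A.
#'
#' @param volume Volume (m^3).
#' @param c_mM Concentration (mM).
#' @return `estimate_ion_count`: dimensionless particle count.
#' @examples
#' estimate_ion_count(0.02e-18, 10)            # ~1.2e5 sodium ions
#' estimate_influx_count(23e-12, 12e-3)        # ~1.72e6 ions
#' estimate_decay_time(0.01e-18, 0.5e-6, pi * 35e-9^2, 0.65e-9)  # ~2 ms
#' @export
estimate_ion_count <- function(volume, c_mM) {
  stopifnot(volume >= 0)
  volume * mm_to_density(c_mM)
}

#' @rdname estimate_ion_count
#' @param I Electric current (A).
#' @param duration Duration (s).
#' @param z Valence of the carrier (non-zero integer).
#' @export
estimate_influx_count <- function(I, duration, z = 1L) {
  stopifnot(I >= 0, duration >= 0)
  if (z == 0) stop("carrier valence must be non-zero")
  I * duration / (z * 1.602176634e-19)
}

#' @rdname estimate_ion_count
#' @param head_volume Head volume V (m^3).
#' @param neck_length Neck length L (m).
#' @param neck_area Neck cross-sectional area A (m^2).
#' @param D Diffusion constant (m^2/s).
#' @export
estimate_decay_time <- function(head_volume, neck_length, neck_area, D) {
  stopifnot(head_volume > 0, neck_length > 0, neck_area > 0, D > 0)
  head_volume * neck_length / (neck_area * D)
}
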