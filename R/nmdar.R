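#' NMDAR gating parameters
#'
#' Sigmoidal voltage dependence of the NMDAR conductance (magnesium
#' unblock), \eqn{g(V) = 1/(1 + a\,e^{bV})} with V in mV, and an Ohmic
#' normalized current \eqn{I = g(V)(\Phi - \Phi^{reversal})}. The readout
#' uses a resting potential of -85 mV; because the solver's dynamics depend
#' only on potential gradients, trajectories simulated at a different rest
#' are shifted by a constant offset rather than re-run.
#'
#' @param a_gate Dimensionless gating parameter (default 0.073).
#' @param b_gate Gating steepness (1/mV, default -0.074).
#' @param phi_reversal Reversal potential (mV, default 0).
#' @param phi_rest Resting potential of the NMDAR analysis (mV, default -85).
#' @return An object of class `nmdar_params`.
#' @export
nmdar_params <- function(a_gate = 0.073, b_gate = -0.074,
                         phi_reversal = 0, phi_rest = -85) {
  structure(list(a_gate = a_gate, b_gate = b_gate,
                 phi_reversal = phi_reversal, phi_rest = phi_rest),
            class = "nmdar_params")
}

#' Normalized NMDAR conductance
#'
#' @param v Membrane potential (mV), scalar or vector.
#' @param params A [nmdar_params()].
#' @return Normalized conductance in (0, 1), strictly increasing in `v`
#'   for negative `b_gate`.
#' @examples
#' nmdar_conductance(0)     # ~0.932
#' nmdar_conductance(-79)   # ~0.038
#' @export
nmdar_conductance <- function(v, params = nmdar_params()) {
  1 / (1 + params$a_gate * exp(params$b_gate * v))
}

#' Normalized NMDAR current
#'
#' Ohmic approximation \eqn{I = g(\Phi)\,(\Phi - \Phi^{reversal})}, with
#' the head membrane potential (first head segment, extracellular
#' reference 0) as the gating voltage. Negative values are inward.
#'
#' @param phi_head Head membrane potential (mV).
#' @param params A [nmdar_params()].
#' @return Normalized current (same units as `phi_head`).
#' @export
nmdar_current <- function(phi_head, params = nmdar_params()) {
  nmdar_conductance(phi_head, params) * (phi_head - params$phi_reversal)
}

#' NMDAR current trace of a trajectory
#'
#' Evaluates the normalized NMDAR current on the recorded head potential.
#' The trace is shifted by `params$phi_rest - phi_rest_sim` so the readout
#' is referenced to the NMDAR analysis rest potential; the shift is exact
#' because the simulated dynamics depend only on potential gradients.
#'
#' @param traj A `spine_trajectory`.
#' @param params A [nmdar_params()].
#' @return Data frame with `time` (s) and `I` (normalized).
#' @export
nmdar_current_trace <- function(traj, params = nmdar_params()) {
  phi_mV <- traj$phi[, 1] * 1e3 + (params$phi_rest - traj$phi_rest * 1e3)
  data.frame(time = traj$times, I = nmdar_current(phi_mV, params))
}

#' Peak NMDAR-current amplification by the depolarization boost
#'
#' Ratio of the peak NMDAR current magnitude during the dendritic
#' depolarization phase between a run with prior synaptic input (boosted)
#' and a run without it (unboosted baseline).
#'
#' @param traj_boost Trajectory of a pre/post pairing run.
#' @param traj_base Trajectory of the clamp-only baseline (same clamp
#'   phase, no injection).
#' @param params A [nmdar_params()].
#' @param delta Dead time after the clamp-phase onset (s); skips the
#'   microsecond capacitive transient of the phase switch (see
#'   [pairing_boost()]).
#' @return Peak-current ratio (>= 1 when the boosted head potential
#'   dominates during the clamp phase).
#' @export
nmdar_peak_boost_ratio <- function(traj_boost, traj_base,
                                   params = nmdar_params(), delta = 1e-4) {
  peak <- function(traj) {
    ph <- traj$phases
    i <- which(ph$clamp != 0)[1]
    if (is.na(i)) stop("trajectory has no dendritic depolarization phase")
    sel <- traj$times >= ph$t_start[i] + delta & traj$times <= ph$t_end[i]
    tr <- nmdar_current_trace(traj, params)
    max(abs(tr$I[sel]))
  }
  peak(traj_boost) / peak(traj_base)
}
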