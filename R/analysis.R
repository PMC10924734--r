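#' Decompose axial currents into drift and diffusion components
#'
#' For the recorded state closest to time `t`, computes the per-interface,
#' per-species axial electric currents
#' \deqn{I_{e,k} = -\pi\sigma_{e,k}\,\Delta\Phi/h, \qquad
#'       I_{c,k} = -\pi\sigma_{d,k}\,e z_k\,\Delta n_k/h,}
#' using exactly the harmonic-mean interface conductivities of the solver,
#' so the decomposition reproduces the fluxes that were actually stepped.
#' Interface 1 is the synaptic boundary (the injected current appears there
#' in the diffusion component), interface N+1 the dendritic boundary.
#' Positive currents flow toward the dendrite.
#'
#' @param traj A `spine_trajectory`.
#' @param t Time (s) of the recorded sample to analyse.
#' @return A data frame with one row per interface: `interface`, `x` (m,
#'   position of the interface), per-species drift and diffusion currents
#'   (`drift_<name>`, `diff_<name>`, A), and `drift_total`, `diff_total`,
#'   `total`.
#' @export
current_decomposition <- function(traj, t) {
  st <- state_at(traj, t)
  geom <- traj$geom; const <- traj$const
  sp <- species_table(traj$species)
  K <- length(sp$z); N <- geom$n_seg
  h <- geom$h; a2 <- geom$a^2
  kT <- const$k_B * const$T; e <- const$e

  I_in <- phase_current(traj, st$t)
  clamp_phi <- traj$phi_rest + phase_clamp(traj, st$t)
  n_rest <- mm_to_density(sp$n_rest)

  out <- data.frame(interface = seq_len(N + 1),
                    x = (seq_len(N + 1) - 1) * h)
  drift_total <- numeric(N + 1); diff_total <- numeric(N + 1)
  n_ghost_L <- synaptic_ghost_concentrations(st$n[, 1], I_in, geom,
                                             traj$species,
                                             traj$influx_species)
  for (k in seq_len(K)) {
    sig_e <- a2 * sp$D[k] * e^2 * sp$z[k]^2 * st$n[k, ] / kT
    sig_d <- a2 * sp$D[k]
    sig_e_ext <- c(sig_e[1], sig_e,
                   a2[N] * sp$D[k] * e^2 * sp$z[k]^2 * n_rest[k] / kT)
    sig_d_ext <- c(sig_d[1], sig_d, sig_d[N])
    phi_ext <- c(st$phi[1], st$phi, clamp_phi)
    n_ext <- c(n_ghost_L[k], st$n[k, ], n_rest[k])

    se <- interface_conductivity(sig_e_ext[1:(N + 1)], sig_e_ext[2:(N + 2)])
    sd <- interface_conductivity(sig_d_ext[1:(N + 1)], sig_d_ext[2:(N + 2)])
    I_drift <- -pi * se * diff(phi_ext) / h
    I_diff <- -pi * sd * e * sp$z[k] * diff(n_ext) / h
    out[[paste0("drift_", sp$name[k])]] <- I_drift
    out[[paste0("diff_", sp$name[k])]] <- I_diff
    drift_total <- drift_total + I_drift
    diff_total <- diff_total + I_diff
  }
  out$drift_total <- drift_total
  out$diff_total <- diff_total
  out$total <- drift_total + diff_total
  out
}

# internal: injected current / clamp offset of the phase containing time t
phase_current <- function(traj, t) {
  ph <- traj$phases
  i <- findInterval(t, ph$t_start, rightmost.closed = FALSE)
  i <- max(1, min(i, nrow(ph)))
  ph$I_in[i]
}
phase_clamp <- function(traj, t) {
  ph <- traj$phases
  i <- findInterval(t, ph$t_start, rightmost.closed = FALSE)
  i <- max(1, min(i, nrow(ph)))
  ph$clamp[i]
}

#' Cumulative drift resistance along the spine
#'
#' Total resistance for drift currents obtained by summing the per-segment
#' resistivity over the cross-section,
#' \deqn{R_e = \sum_i r_e(x_i)\,\Delta x / A(x_i).}
#'
#' @param n K x N matrix of number densities (1/m^3), or a
#'   `spine_trajectory` together with `t`.
#' @param geom,species,const Model objects (taken from the trajectory when
#'   one is supplied).
#' @param region `"all"` (default), `"neck"`, `"head"` or `"dendrite"`.
#' @param t Time (s) when `n` is a trajectory.
#' @return List with `total` (Ohm) and `profile` (cumulative resistance up
#'   to and including each segment of the selected region, Ohm).
#' @examples
#' ref <- reference_spine()
#' n <- mm_to_density(
#'   matrix(c(10, 140, 10), 3, ref$geometry$n_seg))
#' cumulative_resistance(n, ref$geometry, ref$species,
#'                       region = "neck")$total / 1e6  # 230 MOhm
#' @export
cumulative_resistance <- function(n, geom = NULL, species = NULL,
                                  const = physical_constants(),
                                  region = c("all", "neck", "head",
                                             "dendrite"),
                                  t = NULL) {
  region <- match.arg(region)
  if (inherits(n, "spine_trajectory")) {
    traj <- n
    st <- state_at(traj, if (is.null(t)) max(traj$times) else t)
    n <- st$n; geom <- traj$geom; species <- traj$species
    const <- traj$const
  }
  r_e <- drift_resistivity(n, species, const)
  terms <- r_e * geom$h / geom$area
  keep <- if (region == "all") rep(TRUE, geom$n_seg)
          else geom$region == if (region == "dendrite") "dendrite" else region
  list(total = sum(terms[keep]), profile = cumsum(terms[keep]))
}

#' Voltage-divider estimate of the neck resistance
#'
#' The experimental estimator \eqn{R_n = (V_{sp} - V_{den})/I_{syn}}, with
#' the spine-head potential read from the first head segment and the
#' dendritic potential from the last dendritic segment.
#'
#' @param v_sp Spine head potential (V), or a `spine_trajectory` (then
#'   `v_den` is ignored and `t` selects the sample).
#' @param v_den Dendritic potential (V).
#' @param I_syn Synaptic current (A), non-zero.
#' @param t Time (s) when a trajectory is supplied.
#' @return Resistance (Ohm).
#' @export
voltage_divider_neck_resistance <- function(v_sp, v_den = NULL, I_syn,
                                            t = NULL) {
  if (inherits(v_sp, "spine_trajectory")) {
    traj <- v_sp
    i <- sample_index(traj, if (is.null(t)) max(traj$times) else t)
    v_den <- traj$phi[i, traj$geom$n_seg]
    v_sp <- traj$phi[i, 1]
  }
  if (I_syn == 0) stop("I_syn must be non-zero")
  (v_sp - v_den) / I_syn
}

#' Predict the head depolarization from the drift currents
#'
#' Ohm's-law reconstruction of the voltage drop along the spine from the
#' total drift current and the local resistivity,
#' \deqn{\Phi_{est} = \sum_i I_e(x_i)\, r_e(x_i)\,\Delta x / A(x_i),}
#' with \eqn{I_e(x_i)} the total drift current leaving segment i toward the
#' dendrite (its right interface value; the synaptic boundary interface
#' carries no drift current by construction, so the right interface is the
#' representative one). During steady injection this accurately predicts
#' the measured head depolarization even though the injected current alone
#' does not — the excess drift current is the signature of the diffusion
#' boost.
#'
#' @param traj A `spine_trajectory`.
#' @param t Time (s).
#' @return Predicted head depolarization relative to the dendritic end (V).
#' @export
predicted_head_voltage <- function(traj, t) {
  st <- state_at(traj, t)
  geom <- traj$geom
  dec <- current_decomposition(traj, t)
  I_e <- dec$drift_total[2:(geom$n_seg + 1)]
  r_e <- drift_resistivity(st$n, traj$species, traj$const)
  sum(I_e * r_e * geom$h / geom$area)
}

#' Ohmic and diffusion-boosted depolarization of the spine head
#'
#' During a constant current injection the head membrane first charges
#' within microseconds to the Ohmic value `V_ohm`; over the following
#' milliseconds, concentration gradients build up and diffusion currents
#' boost the depolarization to `V_diff`. The relative increase of the
#' apparent (voltage-divider) neck resistance is
#' \deqn{B = (V_{diff} - V_{dend}) / (V_{ohm} - V_{dend}).}
#'
#' @param traj A `spine_trajectory` of a step-current run.
#' @param t_ohm Sampling time of the Ohmic plateau (s); default 10 us after
#'   the onset of the first injection phase.
#' @param t_end Sampling time of the boosted value (s); default the end of
#'   the first injection phase.
#' @return List with `V_ohm`, `V_diff` (head potentials, V), `V_dend`
#'   (dendritic potentials at the two times, V) and `B`.
#' @export
boost_metrics <- function(traj, t_ohm = NULL, t_end = NULL) {
  inj <- which(traj$phases$I_in != 0)[1]
  if (is.na(inj) && (is.null(t_ohm) || is.null(t_end)))
    stop("no injection phase; give t_ohm and t_end explicitly")
  if (is.null(t_ohm)) t_ohm <- traj$phases$t_start[inj] + 10e-6
  if (is.null(t_end)) t_end <- traj$phases$t_end[inj]
  i1 <- sample_index(traj, t_ohm); i2 <- sample_index(traj, t_end)
  N <- traj$geom$n_seg
  v_ohm <- traj$phi[i1, 1]; v_diff <- traj$phi[i2, 1]
  v_dend <- c(traj$phi[i1, N], traj$phi[i2, N])
  list(V_ohm = v_ohm, V_diff = v_diff, V_dend = v_dend,
       B = (v_diff - v_dend[2]) / (v_ohm - v_dend[1]))
}

#' Fit the exponential decay time of a concentration relaxation
#'
#' Log-linear least-squares fit of \eqn{n(t) - n_{rest}} in one segment
#' after the end of the injection. Fitting the log of the excursion over
#' the whole window is robust at coarse record strides, unlike a
#' single-point 1/e reading.
#'
#' @param traj A `spine_trajectory`.
#' @param species Species name (default the influx species).
#' @param segment Segment index (default 1, the leftmost head segment).
#' @param t_start Start of the relaxation (s); default the end of the last
#'   phase with non-zero current.
#' @param delta Dead time skipped after `t_start` (s) so the fast capacitive
#'   transient does not bias the fit; default 0.1 ms.
#' @param window Fit window length (s); default the full remaining trace.
#' @return Fitted time constant (s).
#' @export
fit_decay_time <- function(traj, species = traj$influx_species, segment = 1,
                           t_start = NULL, delta = 1e-4, window = NULL) {
  if (is.null(t_start)) {
    inj <- which(traj$phases$I_in != 0)
    if (!length(inj)) stop("no injection phase in the trajectory")
    t_start <- traj$phases$t_end[max(inj)]
  }
  t0 <- t_start + delta
  t1 <- if (is.null(window)) max(traj$times) else t0 + window
  sel <- traj$times >= t0 & traj$times <= t1
  if (sum(sel) < 3) stop("fit window contains fewer than 3 samples")
  sp <- species_table(traj$species)
  n_rest <- sp$n_rest[match(species, sp$name)]
  y <- traj$conc[[species]][sel, segment] - n_rest
  if (any(y <= 0)) stop("non-positive excursions in the fit window")
  fit <- lm(log(y) ~ traj$times[sel])
  -1 / coef(fit)[[2]]
}

#' Sweep head/neck radii and measure the neck-resistance boost
#'
#' Runs a 10 ms step-current injection for every combination of head
#' radius, neck radius and current, and computes the relative increase `B`
#' of the apparent neck resistance via [boost_metrics()]. `B` collapses
#' onto a function of the neck/head radius ratio and does not depend on
#' the current.
#'
#' @param head_radii,neck_radii Radii (m).
#' @param currents Injected currents (A); default 15, 25 and 35 pA.
#' @param t_inject Injection duration (s).
#' @param settings A [solver_settings()].
#' @param radius_dend Dendritic radius (m).
#' @return Data frame with one row per run: radii (m), `ratio`
#'   (neck/head), `I_in` (A), `V_ohm`, `V_diff` (V) and `B`.
#' @export
neck_resistance_sweep <- function(head_radii, neck_radii,
                                  currents = c(15e-12, 25e-12, 35e-12),
                                  t_inject = 10e-3,
                                  settings = solver_settings(dt = 5e-10),
                                  radius_dend = 0.25e-6) {
  grid <- morphology_current_grid(head_radii, neck_radii, currents,
                                  t_inject = t_inject,
                                  radius_dend = radius_dend)
  rows <- lapply(grid, function(cfg) {
    tr <- run_simulation(cfg$geometry, cfg$protocol, settings = settings)
    bm <- boost_metrics(tr)
    data.frame(head_radius = cfg$head_radius,
               neck_radius = cfg$neck_radius,
               ratio = cfg$neck_radius / cfg$head_radius,
               I_in = cfg$I_in,
               V_ohm = bm$V_ohm, V_diff = bm$V_diff, B = bm$B)
  })
  do.call(rbind, rows)
}

#' Pairing boost: head depolarization beyond the dendritic step
#'
#' For a pre/post pairing run ([pairing_protocol()]), measures the peak
#' head depolarization during the dendritic clamp phase, in excess of the
#' clamp value itself, in the leftmost head segment. The first `delta`
#' seconds of the phase are skipped: at the phase switch the membrane
#' capacitor discharges the injection depolarization within microseconds,
#' and that transient is not part of the diffusion-driven boost (which
#' decays on the ~20 ms concentration timescale, so the dead time costs
#' well under 1% of the signal).
#'
#' @param traj Trajectory of a pairing run.
#' @param delta Dead time after the clamp-phase onset (s), default 0.1 ms.
#' @return List with `boost` (V), `peak_head_depol` (V, relative to rest)
#'   and `clamp` (V).
#' @export
pairing_boost <- function(traj, delta = 1e-4) {
  ph <- traj$phases
  i <- which(ph$clamp != 0)[1]
  if (is.na(i)) stop("protocol has no dendritic depolarization phase")
  sel <- traj$times >= ph$t_start[i] + delta & traj$times <= ph$t_end[i]
  peak <- max(traj$phi[sel, 1]) - traj$phi_rest
  list(boost = peak - ph$clamp[i], peak_head_depol = peak, clamp = ph$clamp[i])
}
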