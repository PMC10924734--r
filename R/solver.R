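#' Harmonic interface conductivity
#'
#' Conductivity assigned to the interface between two adjacent segments.
#' Physically the path from one segment centre to the next crosses half of
#' each segment in series, which gives
#' \eqn{\sigma_{ij} = 2\sigma_i\sigma_j/(\sigma_i+\sigma_j)} (the harmonic
#' mean). A blocked side (zero conductivity) blocks the interface.
#'
#' @param s1,s2 Segment conductivities (>= 0), scalars or vectors.
#' @return Interface conductivity of the same length.
#' @examples
#' interface_conductivity(1, 3)  # 1.5
#' @export
interface_conductivity <- function(s1, s2) {
  if (any(s1 < 0) || any(s2 < 0)) stop("conductivities must be non-negative")
  out <- ifelse(s1 > 0 & s2 > 0, 2 * s1 * s2 / (s1 + s2), 0)
  out
}

#' Solver settings
#'
#' @param dt Time step (s). Default 0.1 ns, comfortably below the stability
#'   threshold of the default geometry (see [stability_scan()]).
#' @param record_dt Interval between recorded samples (s); the record stride
#'   is `max(1, round(record_dt/dt))` steps. Default 1 us, fine enough to
#'   resolve the microsecond-scale capacitive charging.
#' @param record_stride Explicit stride in steps; overrides `record_dt`.
#' @param guard_phi Instability guard: the run aborts with status
#'   `"unstable"` if any potential exceeds this magnitude (V) or becomes
#'   non-finite. Physical spine potentials are ~0.1 V, so 1 V only trips on
#'   numerical blow-up.
#' @return An object of class `solver_settings`.
#' @export
solver_settings <- function(dt = 1e-10, record_dt = 1e-6,
                            record_stride = NULL, guard_phi = 1) {
  stopifnot(dt > 0, guard_phi > 0)
  if (is.null(record_stride)) record_stride <- max(1, round(record_dt / dt))
  stopifnot(record_stride >= 1)
  structure(list(dt = dt, record_stride = as.integer(record_stride),
                 guard_phi = guard_phi),
            class = "solver_settings")
}

# internal: resting state matrix (K x N number densities)
rest_state <- function(geom, species) {
  sp <- species_table(species)
  matrix(mm_to_density(sp$n_rest), nrow = length(sp$n_rest),
         ncol = geom$n_seg,
         dimnames = list(sp$name, NULL))
}

#' Run an electrodiffusion simulation
#'
#' Integrates the coupled species equations of the electrodiffusive cable
#' model over all phases of a protocol, starting from the resting state.
#' The immobile background charge is calibrated once so that the resting
#' concentrations yield `phi_rest` in every segment; the potential is then
#' derived from the concentrations at every step. Time stepping runs in
#' compiled code; see [step_state()] for a pure-R reference of one step.
#'
#' @param geom A [spine_geometry()].
#' @param protocol A [protocol()] (ordered phases of injected current and
#'   optional dendritic clamp offset).
#' @param species Named list of [ion_species()]; the synaptic influx is
#'   carried by `influx_species`.
#' @param const A [physical_constants()].
#' @param phi_rest Resting potential (V). Ignored (recomputed from the
#'   concentrations) when `calibrate_n0 = FALSE`.
#' @param settings A [solver_settings()].
#' @param influx_species Name of the injected species (default "Na").
#' @param calibrate_n0 If `FALSE` the background charge is removed
#'   (`n0 = 0`) and the resting potential becomes whatever the mobile-ion
#'   charge imbalance produces (used by the symmetric-electrolyte variant).
#' @param closed_dendrite Test mode: make the dendritic end fully
#'   reflecting (no-flux) instead of clamped, so total particle numbers are
#'   conserved exactly.
#' @param freeze_conductivities Keep the drift conductivities at their
#'   resting values instead of recomputing them from the evolving state.
#' @param no_diffusion Drop the interior diffusion fluxes (the synaptic
#'   influx is retained). Together with `freeze_conductivities` this reduces
#'   the model to the classical cable equation.
#' @param n_init Optional K x N matrix of initial concentrations (mM),
#'   overriding the uniform resting state (the background charge is still
#'   calibrated against the resting concentrations).
#' @return An object of class `spine_trajectory` with elements `times` (s),
#'   `phi` (samples x segments, V), `conc` (per-species list of samples x
#'   segments matrices, mM), `phases` (data frame with phase windows),
#'   `status` ("stable"/"unstable"), `t_unstable`, plus the inputs needed by
#'   the analysis layer (`geom`, `species`, `const`, `n0`, `phi_rest`,
#'   `settings`).
#' @examples
#' fx <- fixture_spine("tiny")
#' tr <- run_simulation(fx$geometry, protocol(protocol_phase(1e-6, 5e-12)),
#'                      settings = solver_settings(dt = 5e-10, record_dt = 1e-7))
#' tr$status
#' @export
run_simulation <- function(geom, protocol,
                           species = default_ion_species(),
                           const = physical_constants(),
                           phi_rest = -70e-3,
                           settings = solver_settings(),
                           influx_species = "Na",
                           calibrate_n0 = TRUE,
                           closed_dendrite = FALSE,
                           freeze_conductivities = FALSE,
                           no_diffusion = FALSE,
                           n_init = NULL) {
  stopifnot(inherits(geom, "spine_geometry"),
            inherits(protocol, "spine_protocol"),
            inherits(settings, "solver_settings"))
  sp <- species_table(species)
  n <- rest_state(geom, species)
  if (!is.null(n_init)) {
    stopifnot(is.matrix(n_init), dim(n_init) == dim(n), all(n_init >= 0))
    n[] <- mm_to_density(n_init)
  }
  if (calibrate_n0) {
    n0 <- calibrate_background_charge(geom, species, phi_rest, const)
  } else {
    n0 <- rep(0, geom$n_seg)
    phi_rest <- unname(potential_from_concentrations(n, n0, geom, species,
                                                     const)[1])
  }

  idx <- match(influx_species, sp$name)
  if (any(vapply(protocol, `[[`, numeric(1), "I_in") != 0) && is.na(idx))
    stop("influx species '", influx_species, "' not in the species set")

  dt <- settings$dt
  phase_steps <- vapply(protocol, function(p) round(p$duration / dt),
                        numeric(1))
  phase_I <- vapply(protocol, `[[`, numeric(1), "I_in")
  phase_clamp <- phi_rest + vapply(protocol, `[[`, numeric(1), "clamp")

  res <- simulate_core(
    n_init = n, n0 = n0, a = geom$a, h = geom$h,
    z = sp$z, D = sp$D, n_ghost = mm_to_density(sp$n_rest),
    e = const$e, kB = const$k_B, T = const$T, cm = const$c_m,
    influx_species = if (is.na(idx)) -1L else idx - 1L,
    phase_steps = phase_steps, phase_I = phase_I, phase_clamp = phase_clamp,
    record_stride = settings$record_stride, dt = dt,
    closed_right = closed_dendrite,
    freeze_sigma = freeze_conductivities,
    no_diffusion = no_diffusion,
    guard_phi = settings$guard_phi)

  t_end <- cumsum(phase_steps) * dt
  phases <- data.frame(
    phase = seq_along(protocol),
    I_in = phase_I,
    clamp = vapply(protocol, `[[`, numeric(1), "clamp"),
    t_start = c(0, t_end[-length(t_end)]),
    t_end = t_end)

  conc <- lapply(res$conc, density_to_mm)
  names(conc) <- sp$name
  structure(
    list(times = res$times, phi = res$phi, conc = conc,
         phases = phases, status = res$status, t_unstable = res$t_unstable,
         geom = geom, species = species, const = const,
         n0 = n0, phi_rest = phi_rest, settings = settings,
         influx_species = influx_species),
    class = "spine_trajectory")
}

#' @export
print.spine_trajectory <- function(x, ...) {
  cat(sprintf(
    "<spine_trajectory> %s, %d samples over %.4g ms, %d segments, dt = %.3g ns\n",
    x$status, length(x$times), max(x$times) * 1e3, ncol(x$phi),
    x$settings$dt * 1e9))
  cat(sprintf("  rest potential %.4g mV; head potential now %.4g mV\n",
              x$phi_rest * 1e3, x$phi[length(x$times), 1] * 1e3))
  invisible(x)
}

#' Coerce a trajectory to a data frame
#'
#' One row per recorded sample: `time_ms`, then `phi_mV_<i>` per segment and
#' `<species>_mM_<i>` per species and segment.
#'
#' @param x A `spine_trajectory`.
#' @param ... Unused.
#' @export
as.data.frame.spine_trajectory <- function(x, ...) {
  N <- ncol(x$phi)
  out <- data.frame(time_ms = x$times * 1e3)
  phi <- x$phi * 1e3
  colnames(phi) <- paste0("phi_mV_", seq_len(N))
  out <- cbind(out, phi)
  for (nm in names(x$conc)) {
    m <- x$conc[[nm]]
    colnames(m) <- paste0(nm, "_mM_", seq_len(N))
    out <- cbind(out, m)
  }
  out
}

# internal: index of the recorded sample closest to time t
sample_index <- function(traj, t) {
  tol <- max(diff(traj$times))
  if (t < min(traj$times) - tol || t > max(traj$times) + tol)
    stop("time outside trajectory")
  which.min(abs(traj$times - t))
}

# internal: K x N density matrix at recorded time t
state_at <- function(traj, t) {
  i <- sample_index(traj, t)
  n <- t(vapply(traj$conc, function(m) m[i, ], numeric(ncol(traj$phi))))
  rownames(n) <- names(traj$conc)
  list(t = traj$times[i], n = mm_to_density(n), phi = traj$phi[i, ])
}

#' Ghost-segment values at the synaptic end
#'
#' The synaptic (left) boundary is a Neumann boundary: zero potential
#' gradient and zero flux for every species except the injected one, whose
#' ghost concentration exceeds the first head segment by
#' \eqn{h\,I_{in}/(D e z \pi a^2)}, which forces exactly the influx
#' \eqn{I_{in}/(z e)} particles per second through the boundary interface.
#'
#' @param n1 Named vector of first-segment number densities (1/m^3).
#' @param I_in Injected current (A).
#' @param geom A [spine_geometry()] (the first head segment radius is used).
#' @param species List of [ion_species()].
#' @param influx_species Name of the injected species.
#' @return Named vector of ghost number densities.
#' @export
synaptic_ghost_concentrations <- function(n1, I_in, geom, species,
                                          influx_species = "Na") {
  sp <- species_table(species)
  ghost <- n1
  if (I_in != 0) {
    i <- match(influx_species, sp$name)
    if (is.na(i)) stop("unknown influx species")
    a <- geom$a[1]
    ghost[i] <- ghost[i] +
      geom$h * I_in / (sp$D[i] * 1.602176634e-19 * sp$z[i] * pi * a^2)
  }
  ghost
}

#' Ghost-segment values at the dendritic end
#'
#' The dendritic (right) boundary is a Dirichlet boundary: the ghost
#' concentrations are held at the resting values at all times, and the
#' ghost potential is the resting potential plus the clamp offset of the
#' current protocol phase. The clamped potential is imposed directly — it
#' is never derived from the ghost concentrations, because the ghost
#' encodes a boundary condition, not physical charge.
#'
#' @param species List of [ion_species()].
#' @param phi_rest Resting potential (V).
#' @param clamp Clamp offset relative to rest (V); 0 outside
#'   dendritic-depolarization phases.
#' @return List with `n` (named ghost number densities, 1/m^3) and `phi`
#'   (ghost potential, V).
#' @export
dendritic_ghost_values <- function(species, phi_rest = -70e-3, clamp = 0) {
  sp <- species_table(species)
  list(n = setNames(mm_to_density(sp$n_rest), sp$name),
       phi = phi_rest + clamp)
}

#' One explicit time step (pure-R reference implementation)
#'
#' Advances the concentrations by a single forward-Euler step of the
#' finite-difference scheme, written directly from the update rule with
#' ghost segments at both ends. This is the readable reference for the
#' compiled loop used by [run_simulation()]; the two are cross-checked to
#' machine precision in the test suite.
#'
#' @param n K x N matrix of number densities (1/m^3).
#' @param n0 Background-charge density per segment (1/m^3).
#' @param geom,species,const Model objects as in [run_simulation()].
#' @param dt Time step (s).
#' @param I_in Injected current (A) during this step.
#' @param clamp_phi Dendritic ghost potential (V).
#' @param influx_species Name of the injected species.
#' @param closed_dendrite If `TRUE`, reflect at the dendritic end.
#' @param freeze_n Optional K x N matrix: evaluate the drift conductivities
#'   at these densities instead of `n` (used for rest-frozen runs).
#' @param no_diffusion Drop interior diffusion fluxes.
#' @return Updated K x N density matrix.
#' @export
step_state <- function(n, n0, geom, species, const, dt,
                       I_in = 0, clamp_phi = -70e-3,
                       influx_species = "Na",
                       closed_dendrite = FALSE,
                       freeze_n = NULL, no_diffusion = FALSE) {
  sp <- species_table(species)
  K <- nrow(n); N <- ncol(n)
  h <- geom$h; a2 <- geom$a^2
  kT <- const$k_B * const$T
  e <- const$e

  phi <- potential_from_concentrations(n, n0, geom, species, const)
  n_sig <- if (is.null(freeze_n)) n else freeze_n
  # sigma_e,k = a^2 D e^2 z^2 n / kT ; sigma_d,k = a^2 D
  dn <- matrix(0, K, N)
  n_ghost_L <- synaptic_ghost_concentrations(n[, 1], I_in, geom, species,
                                             influx_species)
  for (k in seq_len(K)) {
    sig_e <- a2 * sp$D[k] * e^2 * sp$z[k]^2 * n_sig[k, ] / kT
    sig_d <- a2 * sp$D[k]

    # interface potentials/concentration differences, left ghost first
    # ghost radii: a_0 = a_1 (synaptic), a_{N+1} = a_N (dendritic)
    phi_ext <- c(phi[1], phi, if (closed_dendrite) phi[N] else clamp_phi)
    n_ext <- c(n_ghost_L[k], n[k, ],
               if (closed_dendrite) n[k, N] else mm_to_density(sp$n_rest[k]))
    sig_e_ext <- c(sig_e[1], sig_e,
                   if (closed_dendrite) sig_e[N]
                   else a2[N] * sp$D[k] * e^2 * sp$z[k]^2 *
                        mm_to_density(sp$n_rest[k]) / kT)
    sig_d_ext <- c(sig_d[1], sig_d, sig_d[N])

    se_int <- interface_conductivity(sig_e_ext[1:(N + 1)],
                                     sig_e_ext[2:(N + 2)])
    sd_int <- interface_conductivity(sig_d_ext[1:(N + 1)],
                                     sig_d_ext[2:(N + 2)])
    dphi <- diff(phi_ext)        # interface m: v_m - v_{m-1}
    dnk <- diff(n_ext)
    flux <- numeric(N + 1)       # N+1 interfaces incl. both boundaries
    if (sp$z[k] != 0) flux <- flux + se_int * dphi / (sp$z[k] * e)
    if (!no_diffusion) {
      flux <- flux + sd_int * dnk
    } else if (I_in != 0 && sp$name[k] == influx_species) {
      flux[1] <- flux[1] + sd_int[1] * dnk[1]   # keep the boundary influx
    }
    # synaptic end: zero potential gradient makes the drift flux vanish
    dn[k, ] <- (flux[2:(N + 1)] - flux[1:N]) / (a2 * h^2)
  }
  n + dt * dn
}

#' Scan time steps for stability
#'
#' Runs the same protocol at each candidate time step (largest first) and
#' classifies each run by the instability guard. The explicit scheme has a
#' CFL-type bound proportional to h^2, and numerical blow-up grows by a
#' factor per step, so instability manifests within microseconds; the scan
#' duration can therefore be much shorter than the full protocol.
#'
#' @param geom,species,const,phi_rest As in [run_simulation()].
#' @param protocol Protocol to run (its phases are truncated to `duration`).
#' @param dt_list Candidate time steps (s), any order.
#' @param duration Total simulated time per candidate (s); default 0.5 ms.
#' @param guard_phi Instability threshold (V).
#' @return Data frame with `dt`, `status` and `t_unstable`; attribute
#'   `max_stable_dt` holds the largest stable dt (NA if none).
#' @export
stability_scan <- function(geom, protocol, dt_list,
                           species = default_ion_species(),
                           const = physical_constants(),
                           phi_rest = -70e-3,
                           duration = 5e-4, guard_phi = 1) {
  dt_list <- sort(dt_list, decreasing = TRUE)
  res <- lapply(dt_list, function(dt) {
    prot <- truncate_protocol(protocol, duration)
    tr <- run_simulation(geom, prot, species = species, const = const,
                         phi_rest = phi_rest,
                         settings = solver_settings(
                           dt = dt, record_stride = max(1, round(1e-7 / dt)),
                           guard_phi = guard_phi))
    data.frame(dt = dt, status = tr$status,
               t_unstable = if (is.na(tr$t_unstable)) NA_real_
                            else tr$t_unstable)
  })
  out <- do.call(rbind, res)
  stable <- out$dt[out$status == "stable"]
  attr(out, "max_stable_dt") <- if (length(stable)) max(stable) else NA_real_
  out
}
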