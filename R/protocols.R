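#' Stimulation protocols
#'
#' A protocol is an ordered list of phases; each phase has a duration, a
#' constant synaptic injection current and an optional dendritic clamp
#' offset. During a phase with a clamp offset the potential of the
#' dendritic ghost segment is held at `phi_rest + clamp` (a voltage-clamp
#' step mimicking e.g. a back-propagating action potential); otherwise the
#' ghost stays at the resting potential.
#'
#' @param duration Phase duration (s), > 0.
#' @param I_in Injected current (A) carried by the influx species.
#' @param clamp Dendritic clamp offset relative to rest (V); 0 = no
#'   depolarization.
#' @return `protocol_phase`: a `protocol_phase` object; `protocol`: a
#'   `spine_protocol` (list of phases).
#' @examples
#' # 25 pA for 10 ms, then 40 ms of relaxation
#' protocol(protocol_phase(10e-3, 25e-12), protocol_phase(40e-3))
#' @export
protocol_phase <- function(duration, I_in = 0, clamp = 0) {
  stopifnot(duration > 0)
  structure(list(duration = duration, I_in = I_in, clamp = clamp),
            class = "protocol_phase")
}

#' @rdname protocol_phase
#' @param ... `protocol_phase` objects (or a single list of them).
#' @export
protocol <- function(...) {
  phases <- list(...)
  if (length(phases) == 1L && !inherits(phases[[1]], "protocol_phase"))
    phases <- phases[[1]]
  stopifnot(length(phases) >= 1,
            all(vapply(phases, inherits, logical(1), "protocol_phase")))
  structure(phases, class = "spine_protocol")
}

#' Current step protocol
#'
#' Convenience builder: inject `I_in` for `duration`, then relax for
#' `relax` (omitted if zero).
#'
#' @param I_in Injected current (A).
#' @param duration Injection duration (s).
#' @param relax Relaxation time after the injection (s).
#' @export
step_protocol <- function(I_in, duration, relax = 0) {
  phases <- list(protocol_phase(duration, I_in))
  if (relax > 0) phases <- c(phases, list(protocol_phase(relax)))
  protocol(phases)
}

# internal: clip a protocol to a total duration (for stability scans)
truncate_protocol <- function(prot, duration) {
  out <- list(); left <- duration
  for (p in prot) {
    if (left <= 0) break
    d <- min(p$duration, left)
    out <- c(out, list(protocol_phase(d, p$I_in, p$clamp)))
    left <- left - d
  }
  protocol(out)
}

#' Reference spine morphology and stimulus
#'
#' The canonical simulation setup: a typical pyramidal-cell spine with head
#' radius 250 nm over five head segments of length 0.1 um (head volume
#' ~0.098 um^3), a neck of diameter 70 nm (radius 35 nm) and length 0.5 um
#' (five segments), and four dendritic segments, 1.4 um in total. The neck
#' resistance at resting concentrations is 230 MOhm and the diffusive
#' equilibration time of head sodium, V L/(A D), is 19.6 ms. The stimulus
#' injects 25 pA of sodium for 10 ms followed by 40 ms of relaxation.
#'
#' @param radius_head Head segment radius (m), default 250 nm.
#' @param radius_dend Dendritic segment radius (m), default 250 nm. The
#'   dendrite's share of the total resistance is negligible; its radius
#'   matters mainly for the stability threshold of the explicit scheme,
#'   which scales as 1/max(a) (see the package vignette).
#' @param I_in Injected current (A).
#' @param t_inject Injection duration (s).
#' @param t_relax Relaxation duration (s).
#' @return List with `geometry`, `protocol`, `species` and `const`.
#' @examples
#' ref <- reference_spine()
#' sum(ref$geometry$volume[ref$geometry$region == "head"]) * 1e18  # um^3
#' @export
reference_spine <- function(radius_head = 250e-9, radius_dend = 250e-9,
                            I_in = 25e-12, t_inject = 10e-3,
                            t_relax = 40e-3) {
  h <- 0.1e-6
  geom <- spine_geometry(5, 5, 4, h = h,
                         radius_head = radius_head,
                         radius_neck = 35e-9,
                         radius_dend = radius_dend)
  list(geometry = geom,
       protocol = step_protocol(I_in, t_inject, t_relax),
       species = default_ion_species(),
       const = physical_constants())
}

#' Morphology x current run grid
#'
#' Builds the cartesian product of head radii, neck radii and injected
#' currents, each a 10 ms step-current run on the reference layout
#' (5/5/4 segments of 0.1 um). Configurations are returned, not run; pass
#' each element's `geometry`/`protocol` to [run_simulation()].
#'
#' @param head_radii,neck_radii Radii (m), non-empty.
#' @param currents Injected currents (A), non-empty.
#' @param t_inject Injection duration (s).
#' @param t_relax Relaxation appended after the injection (s).
#' @param radius_dend Dendritic radius (m).
#' @return A list of configurations, each with `geometry`, `protocol`,
#'   `head_radius`, `neck_radius` and `I_in`.
#' @export
morphology_current_grid <- function(head_radii, neck_radii, currents,
                                    t_inject = 10e-3, t_relax = 0,
                                    radius_dend = 0.25e-6) {
  stopifnot(length(head_radii) > 0, length(neck_radii) > 0,
            length(currents) > 0)
  grid <- expand.grid(head = head_radii, neck = neck_radii, I = currents)
  lapply(seq_len(nrow(grid)), function(i) {
    list(geometry = spine_geometry(5, 5, 4, h = 0.1e-6,
                                   radius_head = grid$head[i],
                                   radius_neck = grid$neck[i],
                                   radius_dend = radius_dend),
         protocol = step_protocol(grid$I[i], t_inject, t_relax),
         head_radius = grid$head[i],
         neck_radius = grid$neck[i],
         I_in = grid$I[i])
  })
}

#' Parameter variants of the electrolyte
#'
#' `variant_equal_diffusivity()` sets all three diffusion constants to
#' 1.0e-9 m^2/s (removing the sodium/potassium diffusivity asymmetry); with
#' it, the total drift resistance decreases during current injection
#' instead of increasing. `variant_symmetric_electrolyte()` additionally
#' raises resting chloride to 150 mM and removes the immobile background
#' charge, so free anions and cations balance exactly; the capacitance
#' relation then puts the resting potential at 0 mV and depolarizations are
#' reported relative to that baseline (`calibrate_n0 = FALSE` in
#' [run_simulation()]).
#'
#' @return A list with `species` and `calibrate_n0` to splice into a
#'   [run_simulation()] call.
#' @export
variant_equal_diffusivity <- function() {
  list(species = default_ion_species(D_Na = 1.0e-9),
       calibrate_n0 = TRUE)
}

#' @rdname variant_equal_diffusivity
#' @export
variant_symmetric_electrolyte <- function() {
  list(species = default_ion_species(D_Na = 1.0e-9, cl = 150),
       calibrate_n0 = FALSE)
}

#' Pairing protocol: synaptic input and dendritic depolarization
#'
#' Two-phase protocol modelling the pairing of a synaptic current with a
#' back-propagating action potential (a dendritic voltage-clamp step).
#' In the `pre_post` order the injection comes first and the concentration
#' gradients it built up boost the head potential above the dendritic
#' depolarization; in `post_pre` the clamp comes first and propagates into
#' the head without attenuation.
#'
#' @param order `"pre_post"` (inject, then clamp) or `"post_pre"`.
#' @param I_in Injected current (A).
#' @param t_inject Injection duration (s).
#' @param clamp Dendritic depolarization (V), default 6 mV.
#' @param t_clamp Clamp duration (s), default 10 ms.
#' @return A [protocol()].
#' @export
pairing_protocol <- function(order = c("pre_post", "post_pre"),
                             I_in, t_inject,
                             clamp = 6e-3, t_clamp = 10e-3) {
  order <- match.arg(order)
  inject <- protocol_phase(t_inject, I_in = I_in)
  depol <- protocol_phase(t_clamp, clamp = clamp)
  if (order == "pre_post") protocol(inject, depol) else protocol(depol, inject)
}

#' Small deterministic test fixtures
#'
#' Coarse, fast configurations for unit tests: `"tiny"` is a 3/3/2-segment
#' spine, `"small"` an 8-segment uniform cable (no radius steps). Both run
#' in well under a second at their stable time steps.
#'
#' @param scale `"tiny"` or `"small"`.
#' @return List with `geometry`, `species`, `const` and a stable `dt`.
#' @export
fixture_spine <- function(scale = c("tiny", "small")) {
  scale <- match.arg(scale)
  if (scale == "tiny") {
    geom <- spine_geometry(3, 3, 2, h = 0.1e-6,
                           radius_head = 79.8e-9, radius_neck = 35e-9,
                           radius_dend = 0.25e-6)
    dt <- 5e-10
  } else {
    geom <- spine_geometry(4, 0, 4, h = 0.1e-6,
                           radius_head = 50e-9, radius_neck = 50e-9,
                           radius_dend = 50e-9)
    dt <- 2e-9
  }
  list(geometry = geom, species = default_ion_species(),
       const = physical_constants(), dt = dt)
}
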