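---
title: "An electrodiffusive cable model of dendritic spines"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{An electrodiffusive cable model of dendritic spines}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spinedrift)
```

## The model

Dendritic spines are so small that a physiological synaptic current changes
the ionic composition of their cytoplasm within milliseconds. The classical
cable equation ignores this: it treats the intracellular electrolyte as a
fixed resistor. `spinedrift` implements an extension of cable theory in
which every mobile ion species $k$ (Na⁺, K⁺, Cl⁻ by default) has its own
concentration field $n_k(x,t)$ along a one-dimensional chain of cylindrical
segments, and axial currents have two components:

* a **drift current** driven by the electric-potential gradient,
  $I_e = -\frac{\pi a^2}{r_e}\,\partial_x \Phi$, with the
  concentration-dependent resistivity
  $r_e = k_B T / \sum_k D_k e^2 z_k^2 n_k$;
* a **diffusion current** driven by the chemical-potential gradient,
  $I_{c,k} = -D_k e z_k \pi a^2\, \partial_x n_k$.

Both follow from the Nernst–Planck flux. The key simplification relative
to full Poisson–Nernst–Planck models is that no Poisson equation is solved:
the membrane potential of a segment is slaved to its net ionic charge
through the membrane capacitance,

$$\Phi_i \;=\; \frac{a_i}{2 c_m} \sum_k z_k e\, n_{k,i},$$

where the sum includes a fixed, immobile background charge $n_0$ (valence
−1). Because $\Phi$ is derived, the species equations

$$\frac{\partial n_k}{\partial t} =
  \frac{1}{a^2 z_k e}\,\partial_x\!\Big(\frac{a^2}{r_{e,k}}\,\partial_x\Phi\Big)
  + \frac{1}{a^2}\,\partial_x\!\big(a^2 D_k\,\partial_x n_k\big)$$

form a closed system of $K$ equations. Setting $\partial_t n_k = 0$ (or,
in the package, freezing the conductivities and dropping the diffusion
fluxes) recovers the standard cable equation; the test suite checks this
reduction against Ohm's law.

The slaving of potential to charge is an extremely stiff coupling: adding
1 mM of uncompensated monovalent charge to a 80 nm-radius segment shifts
its potential by ~0.4 V. Physiological trajectories therefore stay
near-electroneutral automatically, and all potential dynamics are carried
by sub-µM charge imbalances — which is why concentrations must be carried
at full double precision and the potential is recomputed from the state at
every step rather than integrated separately.

## Numerical scheme

The spatial operator is discretized with central differences on segments of
uniform length $h$; the flux between two segments uses an interface
conductivity, the series combination of the two half-segments
$\sigma_{ij} = 2\sigma_i\sigma_j/(\sigma_i + \sigma_j)$. Drift
conductivities $\sigma_{e,k} = a^2 D_k e^2 z_k^2 n_k/(k_B T)$ are
recomputed from the current state every step; diffusion conductivities
$a^2 D_k$ are constant and precomputed. Time stepping is explicit forward
Euler with all fluxes evaluated on the pre-step state, in compiled code
(about 4 × 10⁶ steps/s on one core for the 14-segment reference spine).
A readable pure-R single step (`step_state()`) is the reference
implementation; the test suite verifies the compiled loop against it to
machine precision.

Boundary conditions use ghost segments. The dendritic end is Dirichlet:
ghost concentrations stay at rest and the ghost potential is the resting
value, or a clamped value during dendritic-depolarization phases (the
clamp is imposed directly, never derived from ghost concentrations — the
ghost encodes a boundary condition, not physical charge). The synaptic end
is Neumann: zero potential gradient, zero flux for all species except the
injected one, whose ghost excess $h I_{in}/(D e z \pi a^2)$ forces exactly
$I_{in}/(ze)$ particles per second across the boundary. Internally the
solver applies this as the algebraically identical source term on the
first segment; `synaptic_ghost_concentrations()` exposes the ghost form,
and the particle-accounting test confirms the influx is exact to machine
precision.

### Stability

Linearizing the drift term around rest shows that the charge-relaxation
coupling acts like a diffusion operator with an effective coefficient
$D_{\text{eff}} \approx a/(2 c_m r_e)$ — proportional to the segment
*radius*, because a fatter segment holds more charge per unit membrane
area. The explicit scheme therefore has a CFL-type bound

$$\Delta t \;\lesssim\; \frac{h^2\, c_m\, r_e}{\max_i a_i},$$

about 0.7 ns for the reference spine (largest radius 250 nm, $h$ = 0.1 µm):
0.5 ns is stable, 1 ns is not. `stability_scan()` classifies candidate
time steps with an instability guard (non-finite state, potential above
1 V, or negative concentrations); blow-up grows by a factor per step, so a
scan of a fraction of a millisecond per candidate is conclusive and the
scan truncates the protocol accordingly. For an uncharged tracer the bound
reduces to the classical $h^2/(2D)$, which the tests verify together with
the $h^2$ scaling under grid refinement. The default time step is 0.1 ns;
analyses in this package use 0.5 ns, which the refinement tests show is
within the asymptotic regime (halving dt changes the recorded head
potential by well under 0.1%).

## Reference geometry and parameters

| Parameter | Default | Notes |
|---|---|---|
| T | 310 K | body temperature |
| $c_m$ | 0.01 F/m² | 1 µF/cm² |
| rest Na/K/Cl | 10 / 140 / 10 mM | physiological cytosol |
| $D_{Na}, D_K, D_{Cl}$ | 0.65, 1.0, 1.0 ×10⁻⁹ m²/s | sodium ~35% slower |
| resting potential | −70 mV | sets $n_0$ per segment |
| segments | 5 head / 5 neck / 4 dendrite | $h$ = 0.1 µm, 1.4 µm total |
| head radius | 250 nm | head volume ≈ 0.098 µm³ |
| neck radius | 35 nm | neck resistance 230 MΩ at rest |
| dendrite radius | 250 nm | <2% of total resistance |
| dt | 0.1 ns (default), 0.5 ns (analyses) | see stability |

Three geometry choices deserve comment, because published descriptions of
"typical" spines are not mutually consistent and we fixed them once, from
internal-consistency arguments, before running any acceptance checks:

* **Head radius 250 nm.** A cylindrical head of radius 250 nm over 0.5 µm
  has volume 0.098 µm³, and the single-compartment equilibration time
  $\tau = V L/(A D_{Na})$ of that head through the 35 nm neck is 19.6 ms —
  matching both the documented decay constant of head sodium and the
  measured Ohmic plateau (~6 mV ≈ 25 pA × 240 MΩ, with a negligible head
  contribution). A head constrained instead to 0.01 µm³ (radius 79.8 nm)
  yields τ ≈ 2 ms, a 10 mV depolarization and nearly threefold larger
  concentration excursions, inconsistent with the rest of the documented
  behaviour; we treat the smaller printed volume as an inconsistency and
  use 250 nm.
* **Dendrite radius 250 nm.** The dendritic segments contribute under 2%
  of the rest resistance, so their radius is electrically irrelevant; it
  does set the stability threshold ($\propto 1/a$). 250 nm reproduces the
  documented classification (0.5 ns stable, 1 ns unstable); a 0.5 µm
  dendrite would push the threshold to ~0.35 ns.
* **Per-segment background charge.** $n_0$ is calibrated per segment
  (radius-dependent) so the resting potential is uniform across regions;
  it is fixed in time and immobile — it never contributes to resistivities
  or currents.

## Analysis layer

`current_decomposition()` evaluates the drift and diffusion currents at
every interface with exactly the solver's interface conductivities, so the
decomposition is consistent with the stepped fluxes (tested to machine
precision). During steady injection the total current is spatially uniform
and equals the injected current, while drift and diffusion components
separately are not: sodium accumulation and potassium depletion in the
head drive a net *negative* diffusion current through the neck (sodium
diffuses out more slowly than potassium diffuses in), which the drift
current must over-compensate — that excess drift current is what raises
the head potential above the Ohmic value. `predicted_head_voltage()`
reconstructs the head depolarization from the drift currents and the local
resistivities; `boost_metrics()` quantifies the effect as
$B = (V_{diff} - V_{dend})/(V_{ohm} - V_{dend})$, sampling the Ohmic value
10 µs after stimulus onset (the membrane time constant of the head is a
few hundred nanoseconds, so the capacitor is charged but concentrations
are still at rest) and the boosted value at the end of the injection.

Two timing conventions matter and are configurable: the decay-time fit
(`fit_decay_time()`, log-linear least squares — robust at coarse record
strides, unlike a single-point 1/e reading) skips 0.1 ms after the
injection ends, and `pairing_boost()` skips 0.1 ms after the clamp-phase
onset. Both dead times exclude the microsecond-scale capacitive transient
from a signal that decays on the ~20 ms concentration timescale, biasing
the measured quantity by well under 1%.

The NMDAR readout is offline: the normalized conductance
$g(V) = 1/(1 + 0.073\,e^{-0.074 V})$ (V in mV — the gating curve spans the
physiological range only in these units) and the Ohmic current
$I = g(\Phi)(\Phi - \Phi^{rev})$ are evaluated on the recorded head
potential; the receptor does not feed back into the solver. The gating
voltage is the head membrane potential $\Phi(x_1)$ itself (extracellular
reference zero): a trans-synaptic voltage difference would be identically
zero under the zero-gradient synaptic boundary. The readout is referenced
to a −85 mV rest while the transport simulations rest at −70 mV; since the
dynamics depend only on potential *gradients*, changing the rest potential
shifts every trajectory by a constant offset, so the readout shifts the
recorded trace instead of re-running — this is exact, and tested.

For the symmetric-electrolyte variant (chloride raised to 150 mM, no
background charge) the capacitance relation forces a 0 mV rest potential:
with anions and cations exactly balanced and $n_0 = 0$ there is no charge
to hold the membrane at −70 mV. The variant therefore runs at its natural
0 mV baseline and reports depolarizations relative to it; re-balancing
concentrations to force −70 mV would have changed the electrolyte that the
variant is meant to isolate.

## What the experiments show

With the defaults, a 25 pA / 10 ms injection charges the head to ~5.9 mV
within 10 µs and then slowly to 7.2 mV; head sodium roughly triples while
potassium drops by the same amount, and the apparent (voltage-divider)
neck resistance exceeds its Ohmic value by ~20%. Across morphologies the
relative increase $B$ grows with the neck/head radius ratio — up to ~45%
for small heads with wide necks — and is independent of the injected
current. With equal diffusivities the net diffusion current loses its
sodium/potassium asymmetry and the total drift resistance *decreases*
during injection (ion accumulation wins); with the symmetric electrolyte
the decrease is stronger still. Pairing an injection with a subsequent
6 mV dendritic depolarization leaves concentration gradients that boost
the head potential above 6 mV (0.70 mV for 15 pA / 10 ms, 3.36 mV for
35 pA / 50 ms — up to ~56% of the dendritic step) and amplify the peak
NMDAR current by ~21%; in the reverse order the dendritic step propagates
into the head unattenuated and leaves no after-effect.

## Problem sizes and limitations

The analyses in this package use the 14-segment reference spine at
dt = 0.5 ns with samples every 1 µs: the reference experiment integrates
10⁸ steps (~half a minute on one core), the pairing grid
(15–35 pA × 10–50 ms) about 5 × 10⁸. Stability scans use 0.5 ms per
candidate time step and refinement checks 1 ms of injection, both chosen
as the shortest windows that are conclusive (blow-up is exponential;
discretization error is assessed against a doubled grid).

Known limitations, deliberate in scope: one spatial dimension with
cylindrical segments (no 3-D or branched geometry); no membrane leak or
channel currents besides the boundary influx; calcium is not carried as a
species (the NMDAR conductance is a readout, not a current source);
explicit time stepping only — the nanosecond stability bound is the price
of the scheme's simplicity, and simulated milliseconds cost ~10⁷ steps
each. The synthetic protocols emulate constant-current injections and
square voltage-clamp steps; real synaptic conductance transients and bAP
waveforms are not waveform-matched, so quantitative boosts in real spines
will differ from the square-pulse values even where the mechanism is the
same.
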