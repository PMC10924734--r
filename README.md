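# spinedrift

Electrodiffusive cable-equation modelling of dendritic spines.

## The problem

Excitatory synapses mostly terminate on dendritic spines — femtoliter
compartments connected to the dendrite by a neck tens of nanometres wide.
A synaptic current of a few tens of pA delivers more sodium ions in ten
milliseconds than a spine head contains at rest, so the intracellular
concentrations of Na⁺, K⁺ and Cl⁻ change substantially during a single
synaptic event. Classical cable theory cannot represent this: it treats
the cytosol as a fixed Ohmic resistor. The resulting ion-concentration
gradients across the spine neck drive *diffusion currents* that are
invisible to cable theory but large enough to change what experiments
measure — they boost the spine-head depolarization and inflate
voltage-divider estimates of the neck resistance.

`spinedrift` is for computational neuroscientists who want those effects
without the cost and fragility of full Poisson–Nernst–Planck solvers.

## The model

Each mobile species $k$ obeys a drift–diffusion continuity equation along
a 1-D chain of cylindrical segments (radius $a$, length $h$):

$$\frac{\partial n_k}{\partial t} =
  \frac{1}{a^2 z_k e}\,\frac{\partial}{\partial x}\Big(\frac{a^2}{r_{e,k}}
  \frac{\partial \Phi}{\partial x}\Big)
  + \frac{1}{a^2}\frac{\partial}{\partial x}\Big(a^2 D_k
  \frac{\partial n_k}{\partial x}\Big),
  \qquad r_{e,k} = \frac{k_B T}{D_k e^2 z_k^2 n_k},$$

and the membrane potential is slaved to the net ionic charge through the
membrane capacitance, $\Phi = \frac{a}{2c_m}\sum_k z_k e\, n_k$ (including
a fixed immobile background charge calibrated to the resting potential).
The system is integrated with an explicit finite-difference scheme
(harmonic-mean interface conductivities, ghost-segment boundary
conditions: Neumann sodium influx at the synaptic end, Dirichlet clamp at
the dendritic end) in compiled code. The analysis layer decomposes axial
currents into drift and diffusion components, tracks cumulative and
voltage-divider neck resistances, fits concentration decay times, and
evaluates a voltage-dependent NMDAR conductance on the recorded head
potential. See the vignette (`vignettes/electrodiffusion-model.Rmd`) for
the full account, including the stability analysis of the scheme.

## Worked example

A 25 pA sodium current injected for 10 ms into the reference spine (head
radius 250 nm, neck 35 nm × 0.5 µm, 230 MΩ at rest), followed by 40 ms of
relaxation:

```r
library(spinedrift)

ref <- reference_spine()           # geometry + 25 pA / 10 ms protocol
tr  <- run_simulation(ref$geometry, ref$protocol,
                      settings = solver_settings(dt = 5e-10))

i10 <- which.min(abs(tr$times - 9.999e-3))
(tr$phi[i10, 1] - tr$phi_rest) * 1e3       # head depolarization at 10 ms
#> [1] 7.214984
sapply(tr$conc, function(m) m[i10, 1])     # head Na / K / Cl (mM)
#>        Na         K        Cl
#>  29.46069 121.94800  11.40266
fit_decay_time(tr) * 1e3                   # sodium decay constant (ms)
#> [1] 19.62546
```

The head charges to its Ohmic value (~5.9 mV) within microseconds, then
creeps up to 7.2 mV as sodium accumulates (10 → 29 mM) and potassium is
depleted (140 → 122 mM): the concentration gradients drive a net outward
diffusion current through the neck that the drift current must
over-compensate, depolarizing the head beyond Ohm's law. After the
injection ends, head sodium relaxes with a ~20 ms time constant — the
diffusive equilibration time V·L/(A·D) of the head through the neck.

```r
dec <- current_decomposition(tr, 9.99e-3)
range(dec$total) * 1e12    # total current is uniform = injected 25 pA
#> [1] 24.99994 25.00000
```

A command-line interface wraps the same functions:

```sh
Rscript inst/cli/spinedrift.R simulate  --config my_run.yaml --out-dir out/
Rscript inst/cli/spinedrift.R reproduce --experiment reference
Rscript inst/cli/spinedrift.R stability
```

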