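# Shared simulation fixtures, computed once per test run and cached.
# Heavy runs (the reference experiment and the pairing protocols) are used
# by several tests; everything is deterministic so caching is safe.

.run_cache <- new.env(parent = emptyenv())

cached <- function(name, fn) {
  if (!exists(name, envir = .run_cache)) assign(name, fn(), envir = .run_cache)
  get(name, envir = .run_cache)
}

acc_settings <- function(dt = 5e-10) solver_settings(dt = dt, record_dt = 1e-6)

# the reference experiment: 25 pA for 10 ms, then 40 ms of relaxation
reference_run <- function() cached("reference", function() {
  ref <- reference_spine()
  run_simulation(ref$geometry, ref$protocol, settings = acc_settings())
})

pairing_run <- function(I_in, t_inject) {
  cached(sprintf("pair_%g_%g", I_in, t_inject), function() {
    ref <- reference_spine()
    run_simulation(ref$geometry,
                   pairing_protocol("pre_post", I_in, t_inject),
                   settings = acc_settings())
  })
}

# dendritic 6 mV depolarization without prior synaptic input
clamp_baseline <- function() cached("clamp_base", function() {
  ref <- reference_spine()
  run_simulation(ref$geometry, protocol(protocol_phase(10e-3, clamp = 6e-3)),
                 settings = acc_settings())
})

head_depol_at <- function(traj, t) {
  i <- which.min(abs(traj$times - t))
  traj$phi[i, 1] - traj$phi_rest
}

conc_at <- function(traj, species, t, segment = 1) {
  i <- which.min(abs(traj$times - t))
  traj$conc[[species]][i, segment]
}
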