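# Finite-difference solver: interface conductivities, boundary conditions,
# fixed point, compiled/pure-R step equivalence, heat-equation oracle,
# conservation and the CFL-type stability bound.

test_that("interface conductivity is the series combination of half-segments", {
  # series resistance over distance h: (h/2)/s1 + (h/2)/s2 => 2 s1 s2/(s1+s2)
  expect_equal(interface_conductivity(3, 3), 3)
  expect_equal(interface_conductivity(1, 3), 1.5)
  expect_equal(interface_conductivity(5, 0), 0)
  expect_equal(interface_conductivity(0, 0), 0)
  s <- c(0.3, 1.7, 4.2)
  expect_equal(interface_conductivity(s, rev(s)),
               1 / (0.5 / s + 0.5 / rev(s)))
  expect_error(interface_conductivity(-1, 2), "non-negative")
})

test_that("synaptic ghost encodes the Neumann influx", {
  ref <- reference_spine()
  geom79 <- spine_geometry(5, 5, 4, h = 0.1e-6, radius_head = 79.8e-9,
                           radius_neck = 35e-9, radius_dend = 0.25e-6)
  sp <- ref$species
  n1 <- mm_to_density(c(Na = 10, K = 140, Cl = 10))
  # I = 0: all ghosts equal the first segment
  expect_equal(synaptic_ghost_concentrations(n1, 0, geom79, sp), n1)
  g <- synaptic_ghost_concentrations(n1, 25e-12, geom79, sp)
  # only the injected species is offset, by h I/(D e z pi a^2)
  expect_equal(g[2:3], n1[2:3])
  excess <- g[[1]] - n1[[1]]
  expect_equal(excess,
               0.1e-6 * 25e-12 /
                 (0.65e-9 * 1.602176634e-19 * pi * (79.8e-9)^2))
  expect_equal(excess, 1.200e24, tolerance = 1e-3)
  expect_equal(density_to_mm(excess), 1.99, tolerance = 5e-3)
  # excess scales with 1/a^2
  geom2 <- spine_geometry(5, 5, 4, h = 0.1e-6, radius_head = 2 * 79.8e-9,
                          radius_neck = 35e-9, radius_dend = 0.25e-6)
  g2 <- synaptic_ghost_concentrations(n1, 25e-12, geom2, sp)
  expect_equal(g2[[1]] - n1[[1]], excess / 4, tolerance = 1e-12)
})

test_that("dendritic ghost holds resting concentrations and the clamped potential", {
  sp <- default_ion_species()
  g <- dendritic_ghost_values(sp)
  expect_equal(g$n, mm_to_density(c(Na = 10, K = 140, Cl = 10)))
  expect_equal(g$phi, -70e-3)
  # a 6 mV depolarization phase moves only the potential
  g6 <- dendritic_ghost_values(sp, clamp = 6e-3)
  expect_equal(g6$n, g$n)
  expect_equal(g6$phi, -64e-3)
})

test_that("the resting state is a fixed point of the scheme", {
  fx <- fixture_spine("tiny")
  tr <- run_simulation(fx$geometry, protocol(protocol_phase(5e-7)),
                       settings = solver_settings(dt = fx$dt,
                                                  record_stride = 100))
  expect_identical(tr$status, "stable")
  last <- length(tr$times)
  for (nm in names(tr$conc)) {
    expect_equal(tr$conc[[nm]][last, ], tr$conc[[nm]][1, ], tolerance = 1e-13)
  }
  expect_equal(tr$phi[last, ], rep(-70e-3, fx$geometry$n_seg),
               tolerance = 1e-12)
})

test_that("compiled step equals the pure-R reference step", {
  fx <- fixture_spine("tiny")
  geom <- fx$geometry; sp <- fx$species; const <- fx$const
  dt <- 1e-10
  n0 <- calibrate_background_charge(geom, sp, -70e-3, const)
  # start from a perturbed state so every flux term is exercised
  n_mM <- matrix(c(10, 140, 10), 3, geom$n_seg)
  n_mM[1, ] <- n_mM[1, ] + seq(5, 0.5, length.out = geom$n_seg)
  n_mM[2, ] <- n_mM[2, ] - seq(4, 0.4, length.out = geom$n_seg)
  rownames(n_mM) <- c("Na", "K", "Cl")

  n_R <- mm_to_density(n_mM)
  for (s in 1:3) {
    n_R <- step_state(n_R, n0, geom, sp, const, dt, I_in = 25e-12,
                      clamp_phi = -70e-3)
  }
  tr <- run_simulation(geom, protocol(protocol_phase(3 * dt, I_in = 25e-12)),
                       settings = solver_settings(dt = dt, record_stride = 3),
                       n_init = n_mM)
  n_C <- mm_to_density(t(vapply(tr$conc, function(m) m[nrow(m), ],
                                numeric(geom$n_seg))))
  expect_equal(unname(n_C), unname(n_R), tolerance = 1e-12)
})

test_that("a neutral species decays like the discrete heat equation", {
  # uniform closed cable, one uncharged tracer: the scheme reduces to
  # explicit diffusion; a cosine Neumann eigenmode decays by exactly
  # (1 - dt lambda_m)^steps with lambda_m = (2D/h^2)(1 - cos(m pi/N))
  N <- 8; h <- 0.1e-6; D <- 1e-9
  geom <- spine_geometry(4, 0, 4, h = h, radius_head = 50e-9,
                         radius_neck = 50e-9, radius_dend = 50e-9)
  tracer <- list(X = ion_species("X", 0L, D, 100))
  dt <- 1e-6; steps <- 50
  for (m in c(1, 2)) {
    mode <- cos(m * pi * (seq_len(N) - 0.5) / N)
    n_init <- matrix(100 + 5 * mode, 1, N, dimnames = list("X", NULL))
    tr <- run_simulation(geom, protocol(protocol_phase(steps * dt)),
                         species = tracer, phi_rest = 0,
                         settings = solver_settings(dt = dt,
                                                    record_stride = steps),
                         closed_dendrite = TRUE, n_init = n_init)
    lambda <- 2 * D / h^2 * (1 - cos(m * pi / N))
    expected <- 100 + 5 * mode * (1 - dt * lambda)^steps
    expect_equal(tr$conc$X[nrow(tr$conc$X), ], expected, tolerance = 1e-10)
  }
})

test_that("particle numbers are conserved with closed boundaries and track the injected flux", {
  fx <- fixture_spine("tiny")
  geom <- fx$geometry
  vol <- geom$volume
  n_mM <- matrix(c(10, 140, 10), 3, geom$n_seg,
                 dimnames = list(c("Na", "K", "Cl"), NULL))
  n_mM[1, ] <- n_mM[1, ] + seq(3, 0, length.out = geom$n_seg)
  totals <- function(tr, i) vapply(tr$conc, function(m)
    sum(mm_to_density(m[i, ]) * vol), numeric(1))

  # fully closed: every species total is constant to machine precision
  tr <- run_simulation(geom, protocol(protocol_phase(2e-6)),
                       settings = solver_settings(dt = fx$dt,
                                                  record_stride = 1000),
                       closed_dendrite = TRUE, n_init = n_mM)
  expect_equal(totals(tr, length(tr$times)), totals(tr, 1), tolerance = 1e-12)

  # closed except the synaptic influx: sodium grows by exactly I t / e
  I <- 5e-12; t_tot <- 2e-6
  tr2 <- run_simulation(geom, protocol(protocol_phase(t_tot, I_in = I)),
                        settings = solver_settings(dt = fx$dt,
                                                   record_stride = 1000),
                        closed_dendrite = TRUE)
  d <- totals(tr2, length(tr2$times)) - totals(tr2, 1)
  expect_equal(d[["Na"]], I * t_tot / 1.602176634e-19, tolerance = 1e-9)
  expect_equal(d[["K"]], 0, tolerance = 1e-3 * abs(d[["Na"]]))
  expect_equal(d[["Cl"]], 0, tolerance = 1e-3 * abs(d[["Na"]]))
})

test_that("explicit diffusion obeys the h^2/(2D) stability bound", {
  # neutral tracer on a uniform cable: the classical explicit-Euler bound
  h <- 0.1e-6; D <- 1e-9
  bound <- h^2 / (2 * D)   # 5 us
  geom <- spine_geometry(4, 0, 4, h = h, radius_head = 50e-9,
                         radius_neck = 50e-9, radius_dend = 50e-9)
  tracer <- list(X = ion_species("X", 0L, D, 100))
  mode <- cos(pi * (seq_len(8) - 0.5) / 8 * 7)   # near-Nyquist perturbation
  n_init <- matrix(100 + 5 * mode, 1, 8, dimnames = list("X", NULL))
  run_at <- function(dt) {
    run_simulation(geom, protocol(protocol_phase(400 * dt)),
                   species = tracer, phi_rest = 0,
                   settings = solver_settings(dt = dt, record_stride = 20),
                   closed_dendrite = TRUE, n_init = n_init)$status
  }
  expect_identical(run_at(0.8 * bound), "stable")
  expect_identical(run_at(1.6 * bound), "unstable")

  # refining h by 2 tightens the bound by 4
  geom2 <- spine_geometry(8, 0, 8, h = h / 2, radius_head = 50e-9,
                          radius_neck = 50e-9, radius_dend = 50e-9)
  mode2 <- cos(pi * (seq_len(16) - 0.5) / 16 * 15)
  n_init2 <- matrix(100 + 5 * mode2, 1, 16, dimnames = list("X", NULL))
  run2 <- function(dt) {
    run_simulation(geom2, protocol(protocol_phase(400 * dt)),
                   species = tracer, phi_rest = 0,
                   settings = solver_settings(dt = dt, record_stride = 20),
                   closed_dendrite = TRUE, n_init = n_init2)$status
  }
  expect_identical(run2(0.8 * bound / 4), "stable")
  expect_identical(run2(1.6 * bound / 4), "unstable")
})

test_that("dendritic clamp equal to rest is indistinguishable from no clamp phase", {
  fx <- fixture_spine("tiny")
  st <- solver_settings(dt = fx$dt, record_stride = 200)
  tr1 <- run_simulation(fx$geometry,
                        protocol(protocol_phase(1e-6, I_in = 10e-12),
                                 protocol_phase(1e-6, I_in = 10e-12,
                                                clamp = 0)),
                        settings = st)
  tr2 <- run_simulation(fx$geometry,
                        protocol(protocol_phase(2e-6, I_in = 10e-12)),
                        settings = st)
  expect_equal(tr1$phi, tr2$phi, tolerance = 1e-14)
  expect_equal(tr1$conc, tr2$conc, tolerance = 1e-14)
})

test_that("instability guard reports an unstable run instead of returning garbage", {
  ref <- reference_spine()
  tr <- run_simulation(ref$geometry, step_protocol(25e-12, 1e-4),
                       settings = solver_settings(dt = 2e-9,
                                                  record_stride = 50))
  expect_identical(tr$status, "unstable")
  expect_true(is.finite(tr$t_unstable))
})
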