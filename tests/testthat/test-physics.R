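# Closed-form physics: unit conversions, capacitance-derived potential,
# background-charge calibration, resistivities, estimators.

test_that("mM/number-density conversion is exact and invertible", {
  expect_identical(mm_to_density(0), 0)
  # 10 mM = 10 mol/m^3 = 10 * N_A per m^3
  expect_equal(mm_to_density(10), 6.02214076e24)
  expect_equal(mm_to_density(140), 140 * 6.02214076e23)
  for (c_mM in c(0.001, 1, 10, 140, 150)) {
    expect_equal(density_to_mm(mm_to_density(c_mM)), c_mM, tolerance = 1e-14)
  }
  expect_error(mm_to_density(-1), "non-negative")
})

test_that("resting state with calibrated background charge gives a uniform resting potential", {
  ref <- reference_spine()
  geom <- ref$geometry; sp <- ref$species
  n <- matrix(mm_to_density(c(10, 140, 10)), 3, geom$n_seg)
  n0 <- calibrate_background_charge(geom, sp, -70e-3)
  phi <- potential_from_concentrations(n, n0, geom, sp)
  expect_equal(phi, rep(-70e-3, geom$n_seg), tolerance = 1e-12)

  # charge-balanced state with n0 = net cation density gives exactly 0 mV
  n0_neutral <- calibrate_background_charge(geom, sp, 0)
  expect_equal(n0_neutral, rep(mm_to_density(140), geom$n_seg),
               tolerance = 1e-14)
  expect_equal(potential_from_concentrations(n, n0_neutral, geom, sp),
               rep(0, geom$n_seg), tolerance = 1e-15)
})

test_that("potential is linear in each concentration with slope a z e / (2 c_m)", {
  const <- physical_constants()
  geom <- spine_geometry(1, 1, 1, h = 0.1e-6, radius_head = 79.8e-9,
                         radius_neck = 35e-9, radius_dend = 0.25e-6)
  sp <- default_ion_species()
  n <- matrix(mm_to_density(c(10, 140, 10)), 3, 3)
  n0 <- calibrate_background_charge(geom, sp, -70e-3)
  base <- potential_from_concentrations(n, n0, geom, sp)
  # +1 mM of a monovalent cation in the 79.8 nm segment: delta phi = a e dn/(2 c_m)
  n2 <- n; n2[1, 1] <- n2[1, 1] + mm_to_density(1)
  dphi <- potential_from_concentrations(n2, n0, geom, sp) - base
  expect_equal(dphi[1],
               79.8e-9 * const$e * mm_to_density(1) / (2 * const$c_m),
               tolerance = 1e-12)
  expect_equal(dphi[1], 0.3849, tolerance = 1e-3)  # ~0.385 V per mM
  expect_equal(dphi[2:3], c(0, 0))
})

test_that("background-charge calibration inverts the capacitance relation", {
  const <- physical_constants()
  sp <- default_ion_species()
  geom <- spine_geometry(1, 1, 1, h = 0.1e-6, radius_head = 79.8e-9,
                         radius_neck = 35e-9, radius_dend = 159.6e-9)
  n0 <- calibrate_background_charge(geom, sp, -70e-3)
  # deviation from electroneutral 140 mM is 2 c_m |phi| / (a e)
  dev <- 2 * const$c_m * 70e-3 / (79.8e-9 * const$e)
  expect_equal(density_to_mm(n0[1]), 140 + density_to_mm(dev),
               tolerance = 1e-12)
  expect_equal(density_to_mm(n0[1]), 140.18, tolerance = 1e-4)
  # doubling the radius halves the deviation from 140 mM
  expect_equal(n0[3] - mm_to_density(140), (n0[1] - mm_to_density(140)) / 2,
               tolerance = 1e-12)
  # a strongly positive resting potential would need negative n0
  tiny <- spine_geometry(1, 1, 1, h = 0.1e-6, radius_head = 1e-9,
                         radius_neck = 1e-9, radius_dend = 1e-9)
  expect_error(calibrate_background_charge(tiny, sp, 0.7), "negative")
})

test_that("drift resistivity matches the explicit conductivity sum", {
  const <- physical_constants()
  sp <- default_ion_species()
  n <- mm_to_density(c(10, 140, 10))
  # independent evaluation of k_B T / sum(D e^2 z^2 n)
  denom <- sum(c(0.65e-9, 1e-9, 1e-9) * const$e^2 * c(1, 1, 1)^2 * n)
  expect_equal(drift_resistivity(n, sp), const$k_B * 310 / denom)
  expect_equal(drift_resistivity(n, sp), 1.769, tolerance = 1e-3)
  # doubling every concentration halves the resistivity
  expect_equal(drift_resistivity(2 * n, sp), drift_resistivity(n, sp) / 2)
  expect_identical(drift_resistivity(0 * n, sp), Inf)
})

test_that("per-species resistivities obey the definitional identities", {
  const <- physical_constants()
  sp <- default_ion_species()
  n <- mm_to_density(c(10, 140, 10))
  r <- lapply(seq_along(sp), function(k) species_resistivities(n[k], sp[[k]]))
  # r_c / r_e = e z for any species and concentration
  for (k in seq_along(sp)) {
    expect_equal(r[[k]]$r_c / r[[k]]$r_e, const$e * sp[[k]]$z)
  }
  # sodium at 10 mM, D = 0.65e-9: r_e ~ 42.6 Ohm m
  expect_equal(r[[1]]$r_e, 42.61, tolerance = 1e-3)
  # parallel conductances: 1/r_e = sum_k 1/r_e,k
  expect_equal(1 / drift_resistivity(n, sp),
               sum(vapply(r, function(x) 1 / x$r_e, numeric(1))),
               tolerance = 1e-12)
  # potassium dominates the rest conductivity: D_K n_K / sum(D_k n_k)
  share <- (1 / r[[2]]$r_e) / (1 / drift_resistivity(n, sp))
  expect_equal(share, (1e-9 * 140) / (0.65e-9 * 10 + 1e-9 * 140 + 1e-9 * 10),
               tolerance = 1e-12)
  expect_gt(share, 0.8)
  expect_identical(species_resistivities(0, sp$Na)$r_e, Inf)
})

test_that("ion-budget estimators reproduce the hand calculations", {
  # 0.02 um^3 at 10 mM ~ 1.2e5 ions
  expect_equal(estimate_ion_count(0.02e-18, 10), 0.02e-18 * 10 * 6.02214076e23)
  expect_equal(estimate_ion_count(0.02e-18, 10), 1.204e5, tolerance = 1e-3)
  expect_identical(estimate_ion_count(1e-18, 0), 0)
  expect_equal(estimate_ion_count(0.01e-18, 140), 8.431e5, tolerance = 1e-3)

  # influx count I t / (z e)
  expect_equal(estimate_influx_count(23e-12, 12e-3), 23e-12 * 12e-3 / 1.602176634e-19)
  expect_equal(estimate_influx_count(23e-12, 12e-3), 1.7227e6,
               tolerance = 1e-4)
  expect_equal(estimate_influx_count(25e-12, 10e-3), 1.5604e6,
               tolerance = 1e-4)
  expect_identical(estimate_influx_count(0, 1), 0)
  expect_error(estimate_influx_count(1e-12, 1e-3, z = 0), "valence")

  # diffusive equilibration time V L / (A D) and its scalings
  tau <- estimate_decay_time(0.01e-18, 0.5e-6, pi * (35e-9)^2, 0.65e-9)
  expect_equal(tau, 2.0e-3, tolerance = 1e-2)
  expect_equal(estimate_decay_time(0.01e-18, 1.0e-6, pi * (35e-9)^2, 0.65e-9),
               2 * tau)
  expect_equal(estimate_decay_time(0.01e-18, 0.5e-6, pi * (35e-9)^2 / 2,
                                   0.65e-9), 2 * tau)
})
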