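# Synthetic-data generators: determinism, ground truth, and the
# constant-kernel coalescence oracle.

test_that("micrograph generation is seed-deterministic with exact truth tables", {
  spec <- micrograph_spec(width = 256, height = 256, particle_count = 20,
                          seed = 21)
  g1 <- generate_micrograph(spec)
  g2 <- generate_micrograph(spec)
  expect_identical(g1$micrograph$pixels, g2$micrograph$pixels)
  expect_identical(g1$truth, g2$truth)
  expect_equal(nrow(g1$truth), 20)
  # different seed differs
  g3 <- generate_micrograph(micrograph_spec(
    width = 256, height = 256, particle_count = 20, seed = 22))
  expect_false(identical(g1$micrograph$pixels, g3$micrograph$pixels))
  # zero particles: blank noisy frame, empty truth
  g0 <- generate_micrograph(micrograph_spec(
    width = 64, height = 64, particle_count = 0, seed = 1))
  expect_equal(nrow(g0$truth), 0)
  expect_true(all(g0$micrograph$pixels >= 0 & g0$micrograph$pixels <= 1))
})

test_that("truth-table diameters follow the requested distribution", {
  spec <- micrograph_spec(particle_count = 300, diameter_mean = 2.0,
                          diameter_sd = 0.4, seed = 31)
  truth <- generate_micrograph(spec)$truth
  se <- 0.4 / sqrt(300)
  expect_lt(abs(mean(truth$diameter) - 2.0), 3 * se)
  expect_equal(truth$diameter, 2 * truth$radius * spec$scale)
})

test_that("impossible packings are rejected", {
  spec <- micrograph_spec(width = 64, height = 64, particle_count = 500,
                          diameter_mean = 1.0, scale = 0.05, seed = 1)
  expect_error(generate_micrograph(spec), "packing")
})

test_that("growth dataset generator follows the exact law without noise", {
  spec <- growth_dataset_spec(noise_cv = 0, seed = 2)
  d <- generate_growth_dataset(spec)
  expect_equal(nrow(d), 9)
  expect_equal(
    d$diameter,
    2 * (spec$rate_constant * d$delay_time * d$c_core)^(1 / 3),
    tolerance = 1e-12)
  expect_equal(estimate_growth_exponent(d)$exponent, 1 / 3,
               tolerance = 1e-10)
  # determinism with noise
  s <- growth_dataset_spec(seed = 5)
  expect_identical(generate_growth_dataset(s), generate_growth_dataset(s))
})

test_that("noisy growth data recover the cube-root exponent", {
  d <- generate_growth_dataset(growth_dataset_spec(seed = 17))
  expect_lt(abs(estimate_growth_exponent(d)$exponent - 1 / 3), 0.05)
})

test_that("coalescence conserves mass exactly and handles the two-cluster case", {
  traj <- simulate_aggregation(500, seed = 8)
  expect_true(all(traj$total_mass == 500))
  expect_equal(nrow(traj), 499) # runs to a single cluster
  expect_equal(traj$mean_mass[nrow(traj)], 500)
  # two monomers: exactly one coalescence event possible
  t2 <- simulate_aggregation(2, seed = 1)
  expect_equal(nrow(t2), 1)
  expect_equal(t2$mean_mass, 2)
  expect_error(simulate_aggregation(1), "at least 2")
  # determinism
  expect_identical(simulate_aggregation(100, seed = 3),
                   simulate_aggregation(100, seed = 3))
})

test_that("mean cluster mass grows linearly so equivalent radius grows as t^(1/3)", {
  traj <- simulate_aggregation(10000, seed = 3)
  est <- aggregation_exponent(traj)
  expect_lt(abs(est$exponent - 1 / 3), 0.05)
})

test_that("end-to-end micrograph pipeline recovers the generating PDI", {
  g <- generate_micrograph(micrograph_spec(particle_count = 250, seed = 41))
  det <- detect_particles(g$micrograph,
                          detection_params(radius_min = 8, radius_max = 40))
  dist <- pool_distributions(det)
  truth_pdi <- compute_pdi(g$truth$diameter)
  expect_lt(abs(dist$pdi - truth_pdi), 0.05)
  expect_lt(abs(dist$mean_diameter - mean(g$truth$diameter)) /
              mean(g$truth$diameter), 0.03)
})
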