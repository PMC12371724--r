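# Closed-form process calculators: worked values and exact scaling laws.

test_that("intrinsic viscosity follows the Mark-Houwink power law", {
  expect_equal(intrinsic_viscosity(pla_fixture()), 23.09007, tolerance = 1e-6)
  # zero exponent degenerates to K; exponent 1 with K = 1 returns M
  expect_equal(
    intrinsic_viscosity(polymer_spec(12345, mh_K = 0.5, mh_exponent = 1e-12)),
    0.5, tolerance = 1e-9)
  expect_equal(
    intrinsic_viscosity(polymer_spec(4321, mh_K = 1, mh_exponent = 1)),
    4321)
  expect_error(polymer_spec(-5, 0.0174, 0.736), "positive")
  expect_error(polymer_spec(17500, 0.0174, 2.4), "below 2")
})

test_that("Huggins solution viscosity reproduces the 40 and 100 mg/mL values", {
  thf <- thf_fixture()
  iv <- intrinsic_viscosity(pla_fixture())
  # polymer-only concentrations for 2 wt % dye formulations
  expect_equal(solution_viscosity(thf, iv, 39.2), 0.99, tolerance = 0.005)
  expect_equal(solution_viscosity(thf, iv, 98), 2.21, tolerance = 0.005)
  # pure solvent limit and monotonicity in concentration
  expect_identical(solution_viscosity(thf, iv, 0), thf$viscosity)
  concs <- seq(0, 120, by = 5)
  etas <- solution_viscosity(thf, iv, concs)
  expect_true(all(diff(etas) > 0))
  expect_error(solution_viscosity(thf, iv, -1), "non-negative")
})

test_that("chain dimension calculators reproduce Rg and C*", {
  pla <- pla_fixture()
  rg <- radius_of_gyration(pla)
  expect_equal(rg, 39.6, tolerance = 0.002)
  expect_equal(overlap_concentration(pla, rg), 112, tolerance = 0.005)
  # quadrupling N doubles Rg
  pla4 <- polymer_spec(17500, 0.0174, 0.736, kuhn_length = 8.81,
                       kuhn_segments = 484)
  expect_equal(radius_of_gyration(pla4), 79.1267, tolerance = 1e-4)
  expect_equal(radius_of_gyration(polymer_spec(1, 1, 1, kuhn_length = 1,
                                               kuhn_segments = 6)), 1)
  # C* scales inversely with Rg^3 and linearly with M
  expect_equal(overlap_concentration(pla, 2 * rg),
               overlap_concentration(pla, rg) / 8)
  pla2m <- polymer_spec(35000, 0.0174, 0.736, 8.81, 121)
  expect_equal(overlap_concentration(pla2m, rg),
               2 * overlap_concentration(pla, rg))
})

test_that("C*(M) scales as M^(-1/2) when N grows linearly with M", {
  base <- pla_fixture()
  scale_m <- function(lambda) {
    p <- polymer_spec(base$molecular_weight * lambda, base$mh_K,
                      base$mh_exponent, base$kuhn_length,
                      base$kuhn_segments * lambda, base$density)
    overlap_concentration(p)
  }
  for (lambda in c(2, 4, 9)) {
    expect_equal(scale_m(lambda) / scale_m(1), lambda^(-1 / 2),
                 tolerance = 1e-10)
  }
})

test_that("delay time equals channel volume over total flow", {
  # 0.06 mL tubing at 2 x 60 mL/min -> 30 ms
  ch30 <- delay_channel(fixed_volume = 0.06, stream_flow_rates = c(60, 60))
  expect_equal(delay_time(ch30), 30, tolerance = 1e-9)
  # 1.016 mm ID x 14.8 cm -> 0.12 mL -> ~60 ms at 120 mL/min
  ch60 <- delay_channel(0, tubing_inner_diameter = 1.016,
                        tubing_length = 14.8, stream_flow_rates = c(60, 60))
  expect_equal(delay_time(ch60), 60, tolerance = 0.01)
  # zero total volume -> 0 ms
  expect_equal(delay_time(delay_channel(stream_flow_rates = 10)), 0)
  expect_error(delay_time(delay_channel(fixed_volume = 1)), "flow")
})

test_that("delay time is linear in length and inverse-linear in flow", {
  withr::with_seed(11, {
    for (i in 1:20) {
      id <- runif(1, 0.2, 3)
      len <- runif(1, 1, 100)
      q <- runif(2, 5, 100)
      lam <- runif(1, 0.5, 4)
      base <- delay_time(delay_channel(0, id, len, q))
      expect_equal(delay_time(delay_channel(0, id, lam * len, q)),
                   lam * base, tolerance = 1e-12)
      expect_equal(delay_time(delay_channel(0, id, len, lam * q)),
                   base / lam, tolerance = 1e-12)
    }
  })
})

test_that("Smoluchowski radius matches an all-SI evaluation and scales by cube roots", {
  pla <- pla_fixture()
  form <- core_formulation(40, polymer_mass_fraction = 0.98,
                           dye_mass_fraction = 0.02)
  cond <- growth_conditions(temperature = 298.15, delay_time = 30,
                            viscosity = 0.99)
  r <- smoluchowski_radius(cond, form, pla)
  # independent evaluation entirely in SI base units
  r_si <- (0.03 * 1.380649e-23 * 298.15 * 40 /
             (pi * 9.9e-4 * 1250))^(1 / 3) * 1e6
  expect_equal(r, r_si, tolerance = 1e-12)
  expect_equal(r_si, 0.10831, tolerance = 1e-4)

  at <- function(t = 30, c = 40, eta = 0.99) {
    smoluchowski_radius(
      growth_conditions(delay_time = t, viscosity = eta),
      core_formulation(c, polymer_mass_fraction = 0.98,
                       dye_mass_fraction = 0.02),
      pla)
  }
  base <- at()
  for (lam in c(0.3, 2, 8, 17.5)) {
    expect_equal(at(t = 30 * lam), lam^(1 / 3) * base, tolerance = 1e-12)
    expect_equal(at(c = 40 * lam), lam^(1 / 3) * base, tolerance = 1e-12)
    expect_equal(at(eta = 0.99 * lam), lam^(-1 / 3) * base,
                 tolerance = 1e-12)
  }
  expect_equal(at(t = 0), 0)
  # purity: bit-identical repeat evaluation
  expect_identical(at(), base)
})

test_that("throughput arithmetic converts flow x concentration to g/h", {
  expect_identical(throughput(60, 40), 144)
  expect_identical(throughput(60, 100), 360)
  expect_identical(throughput(0, 100), 0)
})

test_that("design summary chains the calculators consistently", {
  pla <- pla_fixture()
  form <- core_formulation(40, polymer_mass_fraction = 0.98,
                           dye_mass_fraction = 0.02)
  ch <- delay_channel(fixed_volume = 0.06, stream_flow_rates = c(60, 60))
  ds <- design_summary(pla, thf_fixture(), form, ch)
  expect_s3_class(ds, "tbl_df")
  expect_equal(nrow(ds), 1L)
  expect_equal(ds$viscosity_mpas,
               solution_viscosity(thf_fixture(),
                                  intrinsic_viscosity(pla), 39.2))
  expect_equal(ds$delay_time_ms, 30, tolerance = 1e-9)
  expect_equal(ds$predicted_diameter_um, 2 * ds$predicted_radius_um)
  expect_equal(ds$throughput_g_h, 144)
  expect_identical(ds$regime, "diffusion_limited")
  # total-solids basis gives a slightly higher viscosity
  ds_total <- design_summary(pla, thf_fixture(), form, ch, basis = "total")
  expect_gt(ds_total$viscosity_mpas, ds$viscosity_mpas)
})
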