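# Growth-law fitting, scaling collapse and regime classification.

test_that("per-concentration log-log slopes match hand OLS on the measured table", {
  recs <- size_records_fixture()
  f40 <- fit_growth_exponent(recs, 40)
  expect_equal(f40$slope, 0.302749, tolerance = 1e-5)
  expect_equal(f40$intercept, -1.273410, tolerance = 1e-4)
  f100 <- fit_growth_exponent(recs, 100)
  expect_equal(f100$slope, 0.034466, tolerance = 1e-5)
  expect_lt(f100$slope, 0.1) # size nearly independent of delay time
  expect_error(fit_growth_exponent(recs[1, ], 40), "at least 2")
})

test_that("noiseless power-law data recover the exact exponent", {
  k <- 4.3e-4
  recs <- tidyr::expand_grid(c_core = c(40, 60, 80),
                             delay_time = c(30, 60, 90)) |>
    dplyr::mutate(diameter = 2 * (k * delay_time * c_core)^(1 / 3))
  for (cc in c(40, 60, 80)) {
    expect_equal(fit_growth_exponent(recs, cc)$slope, 1 / 3,
                 tolerance = 1e-10)
  }
  expect_equal(estimate_growth_exponent(recs)$exponent, 1 / 3,
               tolerance = 1e-10)
  # perfect collapse: r^2 = 1 and intercept ~ 0
  cf <- collapse_fit(recs, c(40, 60, 80))
  expect_equal(cf$r_squared, 1, tolerance = 1e-10)
  expect_equal(cf$intercept, 0, tolerance = 1e-8)
  expect_equal(cf$slope, 2 * k^(1 / 3), tolerance = 1e-8)
})

test_that("slope is invariant to radius-vs-diameter and logarithm base", {
  recs <- size_records_fixture()
  ref <- fit_growth_exponent(recs, 60)$slope
  # diameter instead of radius: same slope, shifted intercept
  x <- log(c(30, 60, 90))
  y_d <- log(recs$diameter[recs$c_core == 60])
  slope_d <- sum((x - mean(x)) * (y_d - mean(y_d))) /
    sum((x - mean(x))^2)
  expect_equal(slope_d, ref, tolerance = 1e-12)
  # base-10 logs: identical slope
  x10 <- log10(c(30, 60, 90))
  y10 <- log10(recs$diameter[recs$c_core == 60] / 2)
  slope10 <- sum((x10 - mean(x10)) * (y10 - mean(y10))) /
    sum((x10 - mean(x10))^2)
  expect_equal(slope10, ref, tolerance = 1e-12)
})

test_that("collapse fit reproduces the pooled OLS and degrades with the entangled rows", {
  recs <- size_records_fixture()
  cf <- collapse_fit(recs, c(40, 60, 80))
  expect_equal(cf$slope, 0.138607, tolerance = 1e-5)
  expect_equal(cf$intercept, 0.121619, tolerance = 1e-4)
  expect_equal(cf$r_squared, 0.964646, tolerance = 1e-5)
  expect_gte(cf$r_squared, 0.9)
  cf_all <- collapse_fit(recs, c(40, 60, 80, 100))
  expect_lt(cf_all$r_squared, cf$r_squared)
  expect_error(collapse_fit(recs[1:2, ], 40), "at least 3")
})

test_that("regime classification follows the phase-diagram rules", {
  expect_identical(classify_regime(120, 112)$regime, "unstable_above_cstar")
  expect_identical(classify_regime(40, 112, 0.30)$regime,
                   "diffusion_limited")
  expect_identical(classify_regime(100, 112, 0.03)$regime,
                   "entanglement_onset")
  # 100 mg/mL is inside the onset band (>= 0.85 C*) even without a slope
  expect_identical(classify_regime(100, 112)$regime, "entanglement_onset")
  expect_identical(classify_regime(112, 112)$regime, "unstable_above_cstar")
})

test_that("regime label is monotone in c_core at fixed c_star", {
  rank <- c(diffusion_limited = 1, entanglement_onset = 2,
            unstable_above_cstar = 3)
  labels <- classify_regime(seq(5, 200, by = 5), c_star = 112)$regime
  expect_true(all(diff(rank[labels]) >= 0))
})

test_that("growth_fit bundles per-concentration, pooled and collapse results", {
  recs <- size_records_fixture()
  gf <- growth_fit(recs, c_star = 112)
  expect_s3_class(gf, "snap_growth_fit")
  td <- tidy(gf)
  expect_equal(nrow(td), 4)
  expect_setequal(td$regime[td$c_core <= 80], "diffusion_limited")
  expect_identical(td$regime[td$c_core == 100], "entanglement_onset")
  gl <- glance(gf)
  expect_equal(gl$collapse_r_squared, 0.964646, tolerance = 1e-5)
  expect_equal(gl$n, 12L)
  p1 <- autoplot(gf, "loglog")
  p2 <- autoplot(gf, "collapse")
  expect_s3_class(p1, "ggplot")
  expect_s3_class(p2, "ggplot")
})
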