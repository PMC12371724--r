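# Circular Hough detection, pooling and PDI.

test_that("micrograph constructor normalizes and rejects color", {
  m <- micrograph(matrix(0:255, 16, 16), scale = 0.1)
  expect_true(all(m$pixels >= 0 & m$pixels <= 1))
  col <- array(runif(48), dim = c(4, 4, 3))
  expect_error(micrograph(col, 0.1), "color")
  # grayscale stored as identical channels is accepted
  gray3 <- array(rep(matrix(runif(16), 4, 4), 3), dim = c(4, 4, 3))
  expect_silent(micrograph(gray3, 0.1))
  expect_error(micrograph(matrix(0.5, 4, 4), scale = 0), "positive")
})

test_that("blank images yield no detections", {
  blank <- micrograph(matrix(0.5, 128, 128), scale = 0.05)
  expect_equal(nrow(detect_particles(
    blank, detection_params(radius_min = 8, radius_max = 30))), 0)
  withr::with_seed(2, {
    noisy <- micrograph(
      matrix(pmin(pmax(rnorm(128 * 128, 0.3, 0.05), 0), 1), 128, 128),
      scale = 0.05)
    expect_equal(nrow(detect_particles(
      noisy, detection_params(radius_min = 8, radius_max = 30))), 0)
  })
})

test_that("a single rendered circle is found within a pixel of its radius", {
  g <- generate_micrograph(micrograph_spec(
    width = 256, height = 256, particle_count = 1,
    diameter_mean = 2.0, diameter_sd = 1e-3, seed = 5))
  det <- detect_particles(g$micrograph,
                          detection_params(radius_min = 10, radius_max = 40))
  expect_equal(nrow(det), 1)
  expect_lt(abs(det$radius - g$truth$radius), 1)
  expect_lt(sqrt((det$center_x - g$truth$center_x)^2 +
                   (det$center_y - g$truth$center_y)^2), 2)
})

test_that("radius range must fit the image and ordering is validated", {
  small <- micrograph(matrix(0.5, 64, 64), scale = 0.05)
  expect_error(detect_particles(
    small, detection_params(radius_min = 8, radius_max = 80)), "dimension")
  expect_error(detection_params(radius_min = 20, radius_max = 10), "below")
  expect_error(detection_params(accumulator_threshold = 1.5), "\\(0, 1\\]")
})

test_that("a dense occluded field is recovered with high recall and accurate radii", {
  g <- generate_micrograph(micrograph_spec(particle_count = 200, seed = 7))
  det <- detect_particles(g$micrograph,
                          detection_params(radius_min = 8, radius_max = 40))
  err <- match_detections(det, g$truth)
  expect_gte(mean(!is.na(err)), 0.95)          # recall
  expect_lte(mean(err, na.rm = TRUE), 0.03)    # per-particle radius error
})

test_that("duplicate suppression is idempotent and counts stay bounded", {
  g <- generate_micrograph(micrograph_spec(
    width = 512, height = 512, particle_count = 60, seed = 9))
  params <- detection_params(radius_min = 8, radius_max = 40)
  det <- detect_particles(g$micrograph, params)
  # no two surviving centers are closer than the separation limit
  if (nrow(det) > 1) {
    dmat <- as.matrix(dist(cbind(det$center_x, det$center_y)))
    expect_gte(min(dmat[upper.tri(dmat)]), params$min_center_separation)
  }
  # detection count cannot exceed the number of placed particles by much
  # (no duplicate peaks per particle survive suppression)
  expect_lte(nrow(det), nrow(g$truth) + 2)
})

test_that("pooling converts radii to microns per image scale and conserves counts", {
  d1 <- tibble::tibble(image = "a", center_x = 1, center_y = 1,
                       radius = 10, score = 1, diameter = 2 * 10 * 0.05)
  expect_equal(pool_distributions(d1)$diameters, 1.0)
  # two images, mixed scales, count conservation
  d2 <- tibble::tibble(image = "b", center_x = 1:5, center_y = 1:5,
                       radius = c(5, 6, 7, 8, 9), score = 1,
                       diameter = 2 * c(5, 6, 7, 8, 9) * 0.10)
  d3 <- tibble::tibble(image = "c", center_x = 1:3, center_y = 1:3,
                       radius = c(10, 11, 12), score = 1,
                       diameter = 2 * c(10, 11, 12) * 0.05)
  pooled <- pool_distributions(list(d2, d3))
  expect_equal(pooled$n, 8)
  expect_equal(sort(pooled$diameters),
               sort(c(1.0, 1.2, 1.4, 1.6, 1.8, 1.0, 1.1, 1.2)))
  expect_warning(empty <- pool_distributions(list()), "empty")
  expect_equal(empty$n, 0)
  expect_true(is.na(empty$mean_diameter))
})

test_that("PDI is the relative population variance and is scale invariant", {
  expect_equal(compute_pdi(c(2, 2, 2)), 0)
  expect_equal(compute_pdi(c(1, 2, 3)), (2 / 3) / 4)
  expect_error(compute_pdi(2.0), "at least 2")
  withr::with_seed(13, {
    d <- rlnorm(200, 0.5, 0.2)
    for (lam in c(0.1, 3, 42)) {
      expect_equal(compute_pdi(lam * d), compute_pdi(d), tolerance = 1e-12)
    }
  })
  # distribution object agrees with the bare vector
  dist <- size_distribution(c(1, 2, 3))
  expect_equal(compute_pdi(dist), dist$pdi)
  expect_equal(dist$std_dev, sqrt(2 / 3)) # population, not sample, SD
  expect_s3_class(autoplot(dist), "ggplot")
})
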