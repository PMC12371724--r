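# Seeded generators producing ground-truthed inputs for every pipeline
# stage: SEM-like micrographs, cube-root growth datasets, and a
# constant-kernel stochastic coalescence oracle.

#' Specification of a synthetic micrograph
#'
#' @param width,height Image size, px.
#' @param scale Physical scale, um per pixel.
#' @param particle_count Number of discs to place.
#' @param diameter_family `"gaussian"` or `"lognormal"`.
#' @param diameter_mean,diameter_sd Diameter distribution parameters, um.
#' @param max_occlusion_fraction Maximum fraction of a disc's area that may
#'   be covered by previously placed discs, in `[0, 1)`.
#' @param background_noise_sd Additive Gaussian noise SD (intensity units on
#'   the `[0, 1]` scale).
#' @param seed Integer seed; generation is deterministic per seed.
#' @return An object of class `micrograph_spec`.
#' @export
micrograph_spec <- function(width = 1024, height = 768, scale = 0.05,
                            particle_count = 300,
                            diameter_family = c("gaussian", "lognormal"),
                            diameter_mean = 2.0, diameter_sd = 0.4,
                            max_occlusion_fraction = 0.3,
                            background_noise_sd = 0.05, seed = 1L) {
  diameter_family <- match.arg(diameter_family)
  check_positive(width, "width")
  check_positive(height, "height")
  check_positive(scale, "scale")
  check_non_negative(particle_count, "particle_count")
  check_positive(diameter_mean, "diameter_mean")
  check_non_negative(diameter_sd, "diameter_sd")
  if (max_occlusion_fraction < 0 || max_occlusion_fraction >= 1) {
    abort("`max_occlusion_fraction` must lie in [0, 1).")
  }
  check_non_negative(background_noise_sd, "background_noise_sd")
  structure(
    list(width = as.integer(width), height = as.integer(height),
         scale = scale, particle_count = as.integer(particle_count),
         diameter_family = diameter_family, diameter_mean = diameter_mean,
         diameter_sd = diameter_sd,
         max_occlusion_fraction = max_occlusion_fraction,
         background_noise_sd = background_noise_sd, seed = as.integer(seed)),
    class = "micrograph_spec"
  )
}

# Area of the lens formed by two overlapping circles.
circle_overlap_area <- function(d, r1, r2) {
  if (d >= r1 + r2) return(0)
  if (d <= abs(r1 - r2)) return(pi * min(r1, r2)^2)
  a1 <- r1^2 * acos((d^2 + r1^2 - r2^2) / (2 * d * r1))
  a2 <- r2^2 * acos((d^2 + r2^2 - r1^2) / (2 * d * r2))
  a3 <- 0.5 * sqrt(pmax(0, (-d + r1 + r2) * (d + r1 - r2) *
                          (d - r1 + r2) * (d + r1 + r2)))
  a1 + a2 - a3
}

#' Generate a ground-truthed SEM-like micrograph
#'
#' Renders bright anti-aliased discs with a soft (~2 px) edge profile on a
#' dim noisy background, emulating secondary-electron images of spherical
#' particles. Placement is rejection-sampled so that no disc is occluded by
#' more than `max_occlusion_fraction` of its area; discs lie fully inside
#' the frame. Deterministic for a given seed.
#'
#' @param spec A [micrograph_spec()].
#' @return A list with elements `micrograph` (a [micrograph()]) and `truth`
#'   (a tibble with `center_x`, `center_y`, `radius` in px and `diameter`
#'   in um for every rendered disc).
#' @export
generate_micrograph <- function(spec) {
  stopifnot(inherits(spec, "micrograph_spec"))
  withr::with_seed(spec$seed, {
    w <- spec$width; h <- spec$height
    n <- spec$particle_count
    diam_um <- draw_diameters(n, spec)
    radii <- diam_um / (2 * spec$scale)
    if (any(radii < 2)) {
      abort("diameter distribution produces discs below 2 px radius; increase the scale or sizes.")
    }
    if (sum(pi * radii^2) > 0.9 * w * h) {
      abort("impossible packing: disc area demand exceeds 90% of the frame.")
    }
    radii <- sort(radii, decreasing = TRUE) # place large discs first
    cx <- numeric(0); cy <- numeric(0); cr <- numeric(0)
    occ <- numeric(0) # cumulative occluded area fraction per placed disc
    max_tries <- max(2000L, 400L * n)
    tries <- 0L
    for (i in seq_len(n)) {
      placed <- FALSE
      while (!placed) {
        tries <- tries + 1L
        if (tries > max_tries) {
          abort("impossible packing: could not place all discs under the occlusion limit.")
        }
        x <- runif(1, radii[i] + 1, w - radii[i])
        y <- runif(1, radii[i] + 1, h - radii[i])
        pair_frac <- numeric(0)
        near <- integer(0)
        occ_new <- 0
        if (length(cx) > 0) {
          d <- sqrt((cx - x)^2 + (cy - y)^2)
          near <- which(d < cr + radii[i])
          overlap <- vapply(near, function(j) {
            circle_overlap_area(d[j], radii[i], cr[j])
          }, numeric(1))
          occ_new <- sum(overlap) / (pi * radii[i]^2)
          pair_frac <- overlap / (pi * cr[near]^2)
          # the cap is cumulative on both the new and every existing disc
          if (occ_new > spec$max_occlusion_fraction ||
              any(occ[near] + pair_frac > spec$max_occlusion_fraction)) next
        }
        occ[near] <- occ[near] + pair_frac
        cx <- c(cx, x); cy <- c(cy, y); cr <- c(cr, radii[i])
        occ <- c(occ, occ_new)
        placed <- TRUE
      }
    }

    img <- matrix(0, h, w)
    edge_w <- 2 # px, soft SEM-like edge ramp
    brightness <- runif(n, 0.75, 0.95)
    for (i in seq_along(cx)) {
      r <- cr[i]
      x0 <- max(1L, floor(cx[i] - r - edge_w))
      x1 <- min(w, ceiling(cx[i] + r + edge_w))
      y0 <- max(1L, floor(cy[i] - r - edge_w))
      y1 <- min(h, ceiling(cy[i] + r + edge_w))
      xs <- x0:x1; ys <- y0:y1
      dx <- xs - cx[i]
      dy <- ys - cy[i]
      dist <- sqrt(outer(dy^2, dx^2, `+`))
      prof <- pmin(1, pmax(0, (r - dist) / edge_w + 0.5)) * brightness[i]
      img[ys, xs] <- pmax(img[ys, xs], prof)
    }
    base <- 0.12
    img <- pmax(img, base)
    if (spec$background_noise_sd > 0) {
      img <- img + matrix(rnorm(w * h, 0, spec$background_noise_sd), h, w)
    }
    img[img < 0] <- 0
    img[img > 1] <- 1

    truth <- tibble(center_x = cx, center_y = cy, radius = cr,
                    diameter = 2 * cr * spec$scale)
    list(
      micrograph = micrograph(img, spec$scale,
                              id = sprintf("synthetic-%d", spec$seed)),
      truth = truth
    )
  })
}

draw_diameters <- function(n, spec) {
  if (n == 0) return(numeric())
  if (spec$diameter_family == "gaussian") {
    d <- rnorm(n, spec$diameter_mean, spec$diameter_sd)
    # resample the rare non-physical tail
    bad <- d < 0.25 * spec$diameter_mean
    while (any(bad)) {
      d[bad] <- rnorm(sum(bad), spec$diameter_mean, spec$diameter_sd)
      bad <- d < 0.25 * spec$diameter_mean
    }
    d
  } else {
    cv <- spec$diameter_sd / spec$diameter_mean
    sdlog <- sqrt(log(1 + cv^2))
    meanlog <- log(spec$diameter_mean) - sdlog^2 / 2
    rlnorm(n, meanlog, sdlog)
  }
}

#' Specification of a synthetic growth dataset
#'
#' @param concentrations Core concentrations, mg/mL.
#' @param delay_times Delay times, ms.
#' @param replicates Independent batches per condition.
#' @param rate_constant Growth-law prefactor k in
#'   \eqn{R = (k t C)^{exponent}} with t in ms and C in mg/mL; the default
#'   produces low-micron particles over 30-90 ms at 40-100 mg/mL.
#' @param exponent Growth exponent (1/3 for diffusion-limited growth).
#' @param noise_cv Coefficient of variation of the multiplicative lognormal
#'   measurement noise applied per replicate.
#' @param seed Integer seed.
#' @return An object of class `growth_dataset_spec`.
#' @export
growth_dataset_spec <- function(concentrations = c(40, 60, 80),
                                delay_times = c(30, 60, 90),
                                replicates = 3, rate_constant = 4.3e-4,
                                exponent = 1 / 3, noise_cv = 0.05,
                                seed = 1L) {
  check_non_negative(concentrations, "concentrations")
  check_non_negative(delay_times, "delay_times")
  check_positive(replicates, "replicates")
  check_positive(rate_constant, "rate_constant")
  check_positive(exponent, "exponent")
  check_non_negative(noise_cv, "noise_cv")
  structure(
    list(concentrations = concentrations, delay_times = delay_times,
         replicates = as.integer(replicates), rate_constant = rate_constant,
         exponent = exponent, noise_cv = noise_cv, seed = as.integer(seed)),
    class = "growth_dataset_spec"
  )
}

#' Generate a synthetic size dataset on the growth law
#'
#' Per replicate, diameter \eqn{= 2 (k t C)^{e}} times lognormal noise with
#' unit mean and the requested coefficient of variation; replicates are then
#' averaged per condition, mirroring how batch means are reported.
#' Deterministic per seed.
#'
#' @param spec A [growth_dataset_spec()].
#' @return A tibble of size records: `c_core`, `delay_time`, `diameter`
#'   (replicate mean, um), `sd` (replicate SD, um), `pdi` (`NA`; the
#'   generator models batch means, not within-batch spread),
#'   `n_replicates`.
#' @export
generate_growth_dataset <- function(spec) {
  stopifnot(inherits(spec, "growth_dataset_spec"))
  withr::with_seed(spec$seed, {
    grid <- tidyr::expand_grid(c_core = spec$concentrations,
                               delay_time = spec$delay_times)
    noise <- function(n) {
      if (spec$noise_cv == 0) return(rep(1, n))
      sdlog <- sqrt(log(1 + spec$noise_cv^2))
      rlnorm(n, -sdlog^2 / 2, sdlog)
    }
    grid |>
      dplyr::rowwise() |>
      dplyr::mutate(reps = list(
        2 * (spec$rate_constant * .data$delay_time * .data$c_core)^spec$exponent *
          noise(spec$replicates)
      )) |>
      dplyr::ungroup() |>
      dplyr::mutate(
        diameter = purrr::map_dbl(.data$reps, mean),
        sd = purrr::map_dbl(.data$reps, function(r) {
          if (length(r) > 1) sd(r) else NA_real_
        }),
        pdi = NA_real_,
        n_replicates = spec$replicates
      ) |>
      dplyr::select("c_core", "delay_time", "diameter", "sd", "pdi",
                    "n_replicates")
  })
}

#' Stochastic constant-kernel coalescence (Marcus-Lushnikov) trajectory
#'
#' Simulates pairwise coalescence of `n_monomers` unit-mass clusters in
#' which every pair merges at the same rate (2/n per pair, so the mean
#' cluster mass grows as ~1 + t). Total mass is conserved exactly at every
#' event. Because mean mass grows linearly in time in the scaling regime,
#' the mass-equivalent radius \eqn{m^{1/3}} grows as \eqn{t^{1/3}} — the
#' same exponent as Brownian diffusion-limited growth — making this a fast
#' independent oracle for cube-root growth, not a physical simulator of the
#' precipitation process.
#'
#' @param n_monomers Initial number of unit-mass monomers (at least 2).
#' @param end_time Dimensionless simulation end time (`Inf` runs to a
#'   single cluster).
#' @param seed Integer seed.
#' @return A tibble with one row per coalescence event: `time`,
#'   `n_clusters`, `mean_mass`, `total_mass`, `mean_radius`
#'   (\eqn{= mean\_mass^{1/3}}).
#' @export
simulate_aggregation <- function(n_monomers, end_time = Inf, seed = 1L) {
  if (!is.numeric(n_monomers) || n_monomers < 2) {
    abort("`n_monomers` must be at least 2.")
  }
  n <- as.integer(n_monomers)
  withr::with_seed(as.integer(seed), {
    masses <- rep(1, n)
    k <- n
    t_now <- 0
    m_events <- n - 1L
    ev_time <- numeric(m_events)
    ev_k <- integer(m_events)
    ev_total <- numeric(m_events)
    e <- 0L
    pair_rate <- 2 / n
    while (k > 1) {
      rate <- pair_rate * k * (k - 1) / 2
      t_now <- t_now + rexp(1, rate)
      if (t_now > end_time) break
      ij <- sample.int(k, 2)
      i <- ij[1]; j <- ij[2]
      masses[i] <- masses[i] + masses[j]
      masses[j] <- masses[k]
      k <- k - 1L
      e <- e + 1L
      ev_time[e] <- t_now
      ev_k[e] <- k
      ev_total[e] <- sum(masses[seq_len(k)])
    }
    idx <- seq_len(e)
    tibble(
      time = ev_time[idx], n_clusters = ev_k[idx],
      mean_mass = n / ev_k[idx], total_mass = ev_total[idx],
      mean_radius = (n / ev_k[idx])^(1 / 3)
    )
  })
}

#' Growth exponent of an aggregation trajectory
#'
#' Regresses log mean radius on log time over the scaling regime (mean
#' cluster mass between `mass_min` and a fraction of the monomer count),
#' where the constant-kernel process has settled into linear mass growth
#' but finite-size depletion has not yet set in.
#'
#' @param trajectory A tibble from [simulate_aggregation()].
#' @param mass_min Lower mean-mass bound of the regression window.
#' @param mass_max_fraction Upper bound as a fraction of the initial
#'   monomer count.
#' @return A one-row tibble: `exponent`, `n_points`.
#' @export
aggregation_exponent <- function(trajectory, mass_min = 10,
                                 mass_max_fraction = 0.1) {
  trajectory <- as_tibble(trajectory)
  n0 <- max(trajectory$mean_mass) * min(trajectory$n_clusters)
  window <- dplyr::filter(trajectory,
                          .data$mean_mass >= mass_min,
                          .data$mean_mass <= mass_max_fraction * n0,
                          .data$time > 0)
  if (nrow(window) < 10) abort("too few events in the scaling window.")
  res <- ols_line(log(window$time), log(window$mean_radius))
  tibble(exponent = res$slope, n_points = nrow(window))
}
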