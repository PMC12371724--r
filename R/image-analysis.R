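# Circular Hough transform particle detection for SEM-like micrographs.
#
# Pipeline: intensity gradient -> edge pixels -> gradient-direction voting
# into one accumulator slice per candidate radius -> per-slice box smoothing
# and radius-normalized scoring -> max over radii -> greedy non-maximum
# suppression -> sub-pixel refinement by algebraic circle fit on the
# supporting edge pixels.

#' Micrograph container
#'
#' A grayscale intensity field with its physical pixel scale. Intensities
#' are normalized to `[0, 1]` on construction (integer-coded images are
#' divided by their maximum representable value). Color inputs are rejected.
#'
#' @param pixels Numeric matrix of intensities (rows = image rows).
#' @param scale Physical scale, um per pixel.
#' @param id Identifier carried through to detection tables.
#' @return An object of class `snap_micrograph`.
#' @export
micrograph <- function(pixels, scale, id = "micrograph") {
  if (is.array(pixels) && length(dim(pixels)) == 3) {
    ch <- dim(pixels)[3]
    same <- all(apply(pixels, 3, function(p) isTRUE(all.equal(p, pixels[, , 1]))))
    if (ch > 1 && !same) {
      abort("color images are not supported; supply a grayscale image.")
    }
    pixels <- pixels[, , 1]
  }
  if (!is.matrix(pixels) || !is.numeric(pixels) || length(pixels) == 0) {
    abort("`pixels` must be a non-empty numeric matrix.")
  }
  check_positive(scale, "scale")
  mx <- max(pixels)
  if (mx > 1) {
    # integer-coded image: 8- or 16-bit
    denom <- if (mx <= 255) 255 else 65535
    pixels <- pixels / denom
  }
  pixels[pixels < 0] <- 0
  pixels[pixels > 1] <- 1
  structure(list(pixels = pixels, scale = scale, id = as.character(id)),
            class = "snap_micrograph")
}

#' @export
print.snap_micrograph <- function(x, ...) {
  cat(sprintf("<snap_micrograph> %s: %d x %d px at %g um/px\n",
              x$id, ncol(x$pixels), nrow(x$pixels), x$scale))
  invisible(x)
}

#' Detection parameters for the circular Hough transform
#'
#' @param radius_min,radius_max Radius search range, px (1 px steps).
#' @param edge_sensitivity Edge threshold as a fraction of the maximum
#'   gradient magnitude, in (0, 1].
#' @param accumulator_threshold Peak acceptance threshold as a fraction of
#'   the strongest accumulator peak, in (0, 1].
#' @param min_center_separation Minimum distance between accepted centers,
#'   px. Defaults to `radius_min`.
#' @param min_support Absolute floor on the perimeter-support score (the
#'   accumulator value divided by the circle circumference); rejects noise
#'   peaks on near-empty images.
#' @param min_arc_coverage Minimum fraction of a refined circle's perimeter
#'   that must be covered by aligned edge pixels, in `[0, 1)`. This is the
#'   occlusion tolerance: 0.55 accepts circles with up to ~45% of their
#'   outline hidden while rejecting phantom circles assembled from
#'   unrelated arcs.
#' @return An object of class `detection_params`.
#' @export
detection_params <- function(radius_min = 8, radius_max = 80,
                             edge_sensitivity = 0.25,
                             accumulator_threshold = 0.15,
                             min_center_separation = radius_min,
                             min_support = 0.3,
                             min_arc_coverage = 0.55) {
  check_positive(radius_min, "radius_min")
  check_positive(radius_max, "radius_max")
  if (radius_min >= radius_max) abort("`radius_min` must be below `radius_max`.")
  if (edge_sensitivity <= 0 || edge_sensitivity > 1) {
    abort("`edge_sensitivity` must lie in (0, 1].")
  }
  if (accumulator_threshold <= 0 || accumulator_threshold > 1) {
    abort("`accumulator_threshold` must lie in (0, 1].")
  }
  check_positive(min_center_separation, "min_center_separation")
  check_non_negative(min_support, "min_support")
  if (min_arc_coverage < 0 || min_arc_coverage >= 1) {
    abort("`min_arc_coverage` must lie in [0, 1).")
  }
  structure(
    list(radius_min = radius_min, radius_max = radius_max,
         edge_sensitivity = edge_sensitivity,
         accumulator_threshold = accumulator_threshold,
         min_center_separation = min_center_separation,
         min_support = min_support,
         min_arc_coverage = min_arc_coverage),
    class = "detection_params"
  )
}

# Central-difference image gradient; returns list(gx, gy, mag).
image_gradient <- function(m) {
  nr <- nrow(m)
  nc <- ncol(m)
  gx <- (m[, c(2:nc, nc)] - m[, c(1, 1:(nc - 1))]) / 2
  gy <- (m[c(2:nr, nr), ] - m[c(1, 1:(nr - 1)), ]) / 2
  list(gx = gx, gy = gy, mag = sqrt(gx^2 + gy^2))
}

# 3x3 box filter via shifted sums (no padding artifacts beyond edge clamp).
box3 <- function(m) {
  nr <- nrow(m)
  nc <- ncol(m)
  up <- m[c(1, 1:(nr - 1)), ]
  down <- m[c(2:nr, nr), ]
  v <- m + up + down
  left <- v[, c(1, 1:(nc - 1))]
  right <- v[, c(2:nc, nc)]
  (v + left + right) / 9
}

# Algebraic (Kasa) circle fit. Returns c(cx, cy, r) or NULL if degenerate.
circle_fit <- function(x, y) {
  if (length(x) < 3) return(NULL)
  A <- cbind(2 * x, 2 * y, 1)
  b <- x^2 + y^2
  sol <- tryCatch(qr.solve(A, b), error = function(e) NULL)
  if (is.null(sol)) return(NULL)
  r2 <- sol[3] + sol[1]^2 + sol[2]^2
  if (!is.finite(r2) || r2 <= 0) return(NULL)
  c(sol[1], sol[2], sqrt(r2))
}

#' Detect spherical particles with a circular Hough transform
#'
#' Edge pixels vote along their gradient direction for circle centers at
#' each candidate radius; accumulator peaks become detections after
#' radius-normalized scoring, greedy suppression of centers closer than
#' `min_center_separation` (ties broken by higher score, then smaller
#' radius), and sub-pixel refinement of center and radius by a least-squares
#' circle fit to the supporting edge pixels. Partially occluded particles
#' are still found because the visible arc of their perimeter votes for the
#' true center.
#'
#' @param image A [micrograph()] (or a numeric matrix, taken at 1 um/px).
#' @param params A [detection_params()].
#' @return A tibble with one row per detection: `image`, `center_x`,
#'   `center_y` (px, 1-based), `radius` (px), `score` (fraction of perimeter
#'   supported by edge pixels), `diameter` (um).
#' @export
detect_particles <- function(image, params = detection_params()) {
  if (is.matrix(image)) image <- micrograph(image, scale = 1)
  stopifnot(inherits(image, "snap_micrograph"),
            inherits(params, "detection_params"))
  m <- image$pixels
  nr <- nrow(m)
  nc <- ncol(m)
  if (2 * params$radius_max > min(nr, nc)) {
    abort("radius range exceeds the image dimensions.")
  }

  g <- image_gradient(m)
  gmax <- max(g$mag)
  empty <- tibble(image = character(), center_x = numeric(),
                  center_y = numeric(), radius = numeric(),
                  score = numeric(), diameter = numeric())
  if (gmax == 0) return(empty)
  edge <- which(g$mag >= params$edge_sensitivity * gmax & g$mag > 0)
  if (length(edge) == 0) return(empty)

  ey <- ((edge - 1) %% nr) + 1
  ex <- ((edge - 1) %/% nr) + 1
  ux <- g$gx[edge] / g$mag[edge]
  uy <- g$gy[edge] / g$mag[edge]

  radii <- seq(params$radius_min, params$radius_max, by = 1)
  best_score <- matrix(0, nr, nc)
  best_radius <- matrix(0, nr, nc)
  npix <- nr * nc
  for (r in radii) {
    # bright-on-dark: the gradient points uphill, toward the disc interior
    cx <- round(ex + r * ux)
    cy <- round(ey + r * uy)
    ok <- cx >= 1 & cx <= nc & cy >= 1 & cy <= nr
    if (!any(ok)) next
    idx <- (cx[ok] - 1L) * nr + cy[ok]
    votes <- tabulate(idx, nbins = npix)
    acc <- box3(matrix(votes, nr, nc)) * 9 # summed votes in 3x3 window
    score <- acc / (2 * pi * r)
    upd <- score > best_score
    if (any(upd)) {
      best_score[upd] <- score[upd]
      best_radius[upd] <- r
    }
  }

  peak_max <- max(best_score)
  thr <- max(params$accumulator_threshold * peak_max, params$min_support)
  cand <- which(best_score >= thr)
  if (length(cand) == 0) return(empty)
  cand_y <- ((cand - 1) %% nr) + 1
  cand_x <- ((cand - 1) %/% nr) + 1
  cand_s <- best_score[cand]
  cand_r <- best_radius[cand]
  ord <- order(-cand_s, cand_r)
  cand_x <- cand_x[ord]; cand_y <- cand_y[ord]
  cand_s <- cand_s[ord]; cand_r <- cand_r[ord]

  # greedy non-maximum suppression on center distance
  sep2 <- params$min_center_separation^2
  keep <- integer(0)
  for (i in seq_along(cand_x)) {
    if (length(keep) > 0) {
      d2 <- (cand_x[keep] - cand_x[i])^2 + (cand_y[keep] - cand_y[i])^2
      if (any(d2 < sep2)) next
    }
    keep <- c(keep, i)
  }
  det <- tibble(center_x = as.numeric(cand_x[keep]),
                center_y = as.numeric(cand_y[keep]),
                radius = as.numeric(cand_r[keep]),
                score = cand_s[keep])

  det <- refine_circles(det, ex, ey, ux, uy, params)
  if (nrow(det) == 0) return(empty)

  # refinement can merge neighbours; suppress residual duplicates
  ord <- order(-det$score, det$radius)
  det <- det[ord, ]
  keep <- integer(0)
  for (i in seq_len(nrow(det))) {
    if (length(keep) > 0) {
      d2 <- (det$center_x[keep] - det$center_x[i])^2 +
        (det$center_y[keep] - det$center_y[i])^2
      if (any(d2 < sep2)) next
    }
    keep <- c(keep, i)
  }
  det <- det[keep, ]

  diam_um <- 2 * det$radius * image$scale
  tibble(image = image$id, det, diameter = diam_um)
}

# Sub-pixel refinement: fit a circle to edge pixels that lie in an annulus
# around the current estimate and whose gradient points toward the center.
# The returned score is the arc coverage — the fraction of the perimeter
# (36 angular bins) supported by aligned edge pixels — which discriminates
# occluded true circles from phantom peaks better than raw votes.
refine_circles <- function(det, ex, ey, ux, uy, params, band = 3,
                           iterations = 2, n_bins = 36L) {
  if (nrow(det) == 0) return(det)
  out <- vector("list", nrow(det))
  for (i in seq_len(nrow(det))) {
    cx <- det$center_x[i]; cy <- det$center_y[i]; r <- det$radius[i]
    ok <- TRUE
    coverage <- 0
    for (it in seq_len(iterations)) {
      dx <- cx - ex
      dy <- cy - ey
      d <- sqrt(dx^2 + dy^2)
      inlier <- abs(d - r) <= band & d > 0
      if (sum(inlier) < 6) { ok <- FALSE; break }
      # gradient should point from the edge pixel toward the center
      ali <- (ux[inlier] * dx[inlier] + uy[inlier] * dy[inlier]) / d[inlier]
      sel <- ali > 0.7
      if (sum(sel) < 6) { ok <- FALSE; break }
      px <- ex[inlier][sel]
      py <- ey[inlier][sel]
      fit <- circle_fit(px, py)
      if (is.null(fit)) { ok <- FALSE; break }
      cx <- fit[1]; cy <- fit[2]; r <- fit[3]
      ang <- atan2(py - cy, px - cx)
      bins <- pmin(n_bins, floor((ang + pi) / (2 * pi) * n_bins) + 1L)
      coverage <- length(unique(bins)) / n_bins
    }
    if (!ok || coverage < params$min_arc_coverage ||
        r < params$radius_min - 1 || r > params$radius_max + 1) {
      out[[i]] <- NULL
    } else {
      out[[i]] <- tibble(center_x = cx, center_y = cy, radius = r,
                         score = coverage)
    }
  }
  purrr::list_rbind(purrr::compact(out))
}

#' Pool detections across micrographs into a size distribution
#'
#' Concatenates per-particle diameters (already converted to microns by
#' [detect_particles()] using each image's scale) across fields of view.
#'
#' @param detections A detection tibble with a `diameter` column, or a list
#'   of such tibbles (one per micrograph).
#' @return A [size_distribution()] object. An empty pooled set returns a
#'   distribution with `n = 0` and `NA` statistics, with a warning.
#' @export
pool_distributions <- function(detections) {
  if (is.data.frame(detections)) detections <- list(detections)
  tbl <- purrr::list_rbind(purrr::map(detections, as_tibble))
  if (nrow(tbl) > 0 && !"diameter" %in% names(tbl)) {
    abort("detections must carry a `diameter` column (um).")
  }
  size_distribution(if (nrow(tbl) == 0) numeric() else tbl$diameter)
}

#' Particle size distribution summary
#'
#' Holds pooled diameters with their mean, population standard deviation and
#' polydispersity index \eqn{PDI = \sigma^2 / D^2}.
#'
#' @param diameters Particle diameters, um.
#' @return An object of class `snap_size_distribution` with fields
#'   `diameters`, `n`, `mean_diameter`, `std_dev`, `pdi`.
#' @export
size_distribution <- function(diameters) {
  diameters <- as.numeric(diameters)
  if (any(!is.finite(diameters)) || any(diameters <= 0)) {
    abort("diameters must be positive and finite.")
  }
  n <- length(diameters)
  if (n == 0) {
    warn("empty pooled set: size statistics are undefined.")
    mean_d <- sd_d <- pdi <- NA_real_
  } else {
    mean_d <- mean(diameters)
    sd_d <- sqrt(mean((diameters - mean_d)^2)) # population SD
    pdi <- if (n >= 2) sd_d^2 / mean_d^2 else NA_real_
  }
  structure(
    list(diameters = diameters, n = n, mean_diameter = mean_d,
         std_dev = sd_d, pdi = pdi),
    class = "snap_size_distribution"
  )
}

#' @export
print.snap_size_distribution <- function(x, ...) {
  cat(sprintf(
    "<snap_size_distribution> n = %d, mean %.3f um, sd %.3f um, PDI %.3f\n",
    x$n, x$mean_diameter, x$std_dev, x$pdi))
  invisible(x)
}

#' @describeIn size_distribution One-row summary tibble
#'   (`n`, `mean_diameter`, `std_dev`, `pdi`).
#' @param x A `snap_size_distribution`.
#' @param ... Unused.
#' @export
glance.snap_size_distribution <- function(x, ...) {
  tibble(n = x$n, mean_diameter = x$mean_diameter, std_dev = x$std_dev,
         pdi = x$pdi)
}

#' Polydispersity index of a size distribution
#'
#' The relative variance of particle diameter, \eqn{\sigma^2 / D^2}, using
#' the population variance of the pooled diameters. Dimensionless and
#' invariant under uniform rescaling of all diameters.
#'
#' @param dist A [size_distribution()] or a numeric vector of diameters
#'   (um).
#' @return The PDI (dimensionless).
#' @examples
#' compute_pdi(c(1, 2, 3)) # 0.1667
#' @export
compute_pdi <- function(dist) {
  if (inherits(dist, "snap_size_distribution")) {
    d <- dist$diameters
  } else {
    d <- as.numeric(dist)
  }
  if (length(d) < 2) abort("PDI needs at least 2 diameters.")
  if (any(d <= 0)) abort("diameters must be positive.")
  mean_d <- mean(d)
  mean((d - mean_d)^2) / mean_d^2
}
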