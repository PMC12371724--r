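# Growth-law fitting and regime classification. Size records are tibbles
# with columns c_core (mg/mL), delay_time (ms), diameter (um) and optionally
# pdi and sd (replicate SD, um).

validate_size_records <- function(records) {
  records <- as_tibble(records)
  needed <- c("c_core", "delay_time", "diameter")
  missing <- setdiff(needed, names(records))
  if (length(missing) > 0) {
    abort(paste0("size records need columns: ",
                 paste(missing, collapse = ", ")))
  }
  if (any(records$c_core <= 0) || any(records$delay_time <= 0) ||
      any(records$diameter <= 0)) {
    abort("c_core, delay_time and diameter must all be positive.")
  }
  records
}

ols_line <- function(x, y) {
  fit <- lm(y ~ x)
  rss <- sum(fit$residuals^2)
  tss <- sum((y - mean(y))^2)
  r2 <- if (tss > 0) 1 - rss / tss else 1
  list(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
       r_squared = r2, fit = fit)
}

#' Fit the growth exponent at one core concentration
#'
#' Ordinary least squares of log(radius) on log(delay time) for the records
#' at one concentration. Diffusion-limited growth gives a slope of 1/3; a
#' slope near zero indicates size decoupled from delay time. The slope is
#' invariant to fitting radius versus diameter and to the base of the
#' logarithm.
#'
#' @param records A data frame of size records (columns `c_core`,
#'   `delay_time`, `diameter`).
#' @param c_core Concentration to fit, mg/mL. If `NULL`, `records` must
#'   already be restricted to a single concentration.
#' @return A one-row tibble: `c_core`, `slope`, `intercept`, `r_squared`,
#'   `n`.
#' @examples
#' recs <- tibble::tibble(
#'   c_core = 40, delay_time = c(30, 60, 90),
#'   diameter = c(1.59, 1.86, 2.24)
#' )
#' fit_growth_exponent(recs, 40) # slope ~0.30
#' @export
fit_growth_exponent <- function(records, c_core = NULL) {
  records <- validate_size_records(records)
  if (!is.null(c_core)) {
    records <- dplyr::filter(records, .data$c_core == !!c_core)
  } else {
    if (dplyr::n_distinct(records$c_core) != 1L) {
      abort("supply `c_core` or restrict `records` to one concentration.")
    }
    c_core <- records$c_core[1]
  }
  if (nrow(records) < 2 || dplyr::n_distinct(records$delay_time) < 2) {
    abort("need at least 2 records with distinct delay times.")
  }
  res <- ols_line(log(records$delay_time), log(records$diameter / 2))
  tibble(c_core = c_core, slope = res$slope, intercept = res$intercept,
         r_squared = res$r_squared, n = nrow(records))
}

#' Scaling collapse of sizes onto (delay time x concentration)^(1/3)
#'
#' Ordinary least squares (with intercept) of mean diameter against
#' \eqn{(T_d \cdot C_{core})^{1/3}} pooled over the supplied concentrations.
#' A high r-squared indicates the sizes collapse onto the single
#' diffusion-limited growth curve.
#'
#' @param records A data frame of size records.
#' @param concentrations Concentrations to pool (mg/mL); the collapse is
#'   expected to hold only below the entanglement region.
#' @return A one-row tibble: `slope`, `intercept`, `r_squared`, `n`,
#'   `concentrations` (list column).
#' @export
collapse_fit <- function(records, concentrations = c(40, 60, 80)) {
  records <- validate_size_records(records)
  records <- dplyr::filter(records, .data$c_core %in% concentrations)
  if (nrow(records) < 3) abort("need at least 3 records for the collapse fit.")
  x <- (records$delay_time * records$c_core)^(1 / 3)
  res <- ols_line(x, records$diameter)
  tibble(slope = res$slope, intercept = res$intercept,
         r_squared = res$r_squared, n = nrow(records),
         concentrations = list(sort(unique(records$c_core))))
}

#' Pooled growth-exponent estimate across concentrations
#'
#' Fits log(radius) on log(delay time) with a separate intercept per
#' concentration and a shared slope — the dataset-level estimate of the
#' growth exponent used in parameter-recovery checks.
#'
#' @param records A data frame of size records.
#' @return A one-row tibble: `exponent`, `std_error`, `n`,
#'   `n_concentrations`.
#' @export
estimate_growth_exponent <- function(records) {
  records <- validate_size_records(records)
  if (dplyr::n_distinct(records$delay_time) < 2) {
    abort("need at least 2 distinct delay times.")
  }
  x <- log(records$delay_time)
  y <- log(records$diameter / 2)
  if (dplyr::n_distinct(records$c_core) > 1L) {
    fit <- lm(y ~ x + factor(records$c_core))
  } else {
    fit <- lm(y ~ x)
  }
  # slope SE computed directly so exact fits do not trip summary.lm warnings
  X <- stats::model.matrix(fit)
  sigma2 <- sum(fit$residuals^2) / fit$df.residual
  se <- sqrt(diag(solve(crossprod(X)))["x"] * sigma2)
  tibble(exponent = unname(coef(fit)["x"]),
         std_error = unname(se),
         n = nrow(records),
         n_concentrations = dplyr::n_distinct(records$c_core))
}

#' Classify the process regime of a core concentration
#'
#' Places a core concentration on the process phase diagram relative to the
#' polymer overlap concentration \eqn{C^*}:
#' * `unstable_above_cstar` — at or above \eqn{C^*}; entangled chains
#'   precipitate as macroscopic aggregates rather than discrete particles.
#' * `entanglement_onset` — within `entanglement_fraction` of \eqn{C^*}, or
#'   an observed growth exponent below `exponent_threshold`; size becomes
#'   insensitive to delay time.
#' * `diffusion_limited` — otherwise; sizes follow the cube-root growth law.
#'
#' @param c_core Core concentration(s), mg/mL.
#' @param c_star Overlap concentration, mg/mL.
#' @param growth_exponent Optional fitted log-log slope(s); recycled.
#' @param entanglement_fraction Fraction of \eqn{C^*} marking the onset
#'   region (default 0.85).
#' @param exponent_threshold Growth exponent below which size is considered
#'   decoupled from delay time (default 0.15).
#' @return A tibble with one row per `c_core`: `c_core`, `c_star`,
#'   `growth_exponent`, `regime`.
#' @examples
#' classify_regime(c(40, 100, 120), c_star = 112,
#'                 growth_exponent = c(0.30, 0.03, NA))
#' @export
classify_regime <- function(c_core, c_star, growth_exponent = NULL,
                            entanglement_fraction = 0.85,
                            exponent_threshold = 0.15) {
  check_positive(c_star, "c_star")
  check_non_negative(c_core, "c_core")
  n <- length(c_core)
  expo <- if (is.null(growth_exponent)) rep(NA_real_, n) else
    rep_len(as.numeric(growth_exponent), n)
  regime <- dplyr::case_when(
    c_core >= c_star ~ "unstable_above_cstar",
    c_core >= entanglement_fraction * c_star ~ "entanglement_onset",
    !is.na(expo) & expo < exponent_threshold ~ "entanglement_onset",
    TRUE ~ "diffusion_limited"
  )
  tibble(c_core = c_core, c_star = c_star, growth_exponent = expo,
         regime = regime)
}

#' Full growth-law analysis of a size dataset
#'
#' Runs the per-concentration log-log fits, the pooled exponent estimate and
#' the scaling collapse in one pass, returning an object with [tidy()],
#' [glance()] and [autoplot()] methods.
#'
#' @param records A data frame of size records.
#' @param collapse_concentrations Concentrations pooled for the collapse
#'   (default 40, 60, 80 mg/mL).
#' @param c_star Optional overlap concentration for regime labelling, mg/mL.
#' @return An object of class `snap_growth_fit`.
#' @export
growth_fit <- function(records, collapse_concentrations = c(40, 60, 80),
                       c_star = NULL) {
  records <- validate_size_records(records)
  per_conc <- records |>
    dplyr::group_by(.data$c_core) |>
    dplyr::group_split() |>
    purrr::map(fit_growth_exponent) |>
    purrr::list_rbind()
  collapse <- collapse_fit(records, collapse_concentrations)
  regimes <- if (!is.null(c_star)) {
    classify_regime(per_conc$c_core, c_star, per_conc$slope)
  } else {
    NULL
  }
  structure(
    list(records = records, per_concentration = per_conc,
         collapse = collapse, pooled = estimate_growth_exponent(records),
         regimes = regimes,
         collapse_concentrations = collapse_concentrations),
    class = "snap_growth_fit"
  )
}

#' @export
print.snap_growth_fit <- function(x, ...) {
  cat("<snap_growth_fit>\n")
  cat("Per-concentration log-log slopes:\n")
  print(x$per_concentration, ...)
  cat(sprintf("Pooled exponent: %.3f (SE %.3f)\n",
              x$pooled$exponent, x$pooled$std_error))
  cat(sprintf("Collapse (C in {%s}): slope %.3f, intercept %.3f, r^2 %.3f\n",
              paste(x$collapse_concentrations, collapse = ", "),
              x$collapse$slope, x$collapse$intercept, x$collapse$r_squared))
  if (!is.null(x$regimes)) {
    cat("Regimes:\n")
    print(x$regimes, ...)
  }
  invisible(x)
}

#' @describeIn growth_fit Per-concentration slopes and intercepts as a
#'   tibble.
#' @param x A `snap_growth_fit`.
#' @param ... Unused.
#' @export
tidy.snap_growth_fit <- function(x, ...) {
  out <- x$per_concentration
  if (!is.null(x$regimes)) {
    out <- dplyr::left_join(out,
                            dplyr::select(x$regimes, "c_core", "regime"),
                            by = "c_core")
  }
  out
}

#' @describeIn growth_fit One-row dataset-level summary (pooled exponent and
#'   collapse statistics).
#' @export
glance.snap_growth_fit <- function(x, ...) {
  tibble(
    exponent = x$pooled$exponent,
    exponent_se = x$pooled$std_error,
    collapse_slope = x$collapse$slope,
    collapse_intercept = x$collapse$intercept,
    collapse_r_squared = x$collapse$r_squared,
    n = nrow(x$records),
    n_concentrations = dplyr::n_distinct(x$records$c_core)
  )
}
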