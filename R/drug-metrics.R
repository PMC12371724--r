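# Drug loading, encapsulation efficiency and cumulative release.

#' Drug loading of a purified particle suspension
#'
#' Drug mass as a weight percent of total dissolved solids:
#' \eqn{DL = 100 \cdot C_{drug} / C_{total}}.
#'
#' @param c_drug Drug mass concentration, mg/mL. Vectorized.
#' @param c_total Total solids concentration (gravimetric), mg/mL.
#' @return Drug loading, wt %.
#' @examples
#' drug_loading(0.85, 10) # 8.5 wt %
#' @export
drug_loading <- function(c_drug, c_total) {
  check_non_negative(c_drug, "c_drug")
  if (any(!is.finite(c_total)) || any(c_total <= 0)) {
    abort("`c_total` must be positive.")
  }
  if (any(c_drug > c_total)) {
    abort("`c_drug` cannot exceed `c_total`.")
  }
  100 * c_drug / c_total
}

#' Encapsulation efficiency
#'
#' Achieved drug loading as a percent of the targeted loading:
#' \eqn{EE\% = 100 \cdot DL / DL_{target}}.
#'
#' @param dl Measured drug loading, wt %.
#' @param dl_target Target drug loading, wt % (in (0, 100]).
#' @return Encapsulation efficiency, %.
#' @examples
#' encapsulation_efficiency(8.3, 10) # 83 %
#' @export
encapsulation_efficiency <- function(dl, dl_target) {
  check_non_negative(dl, "dl")
  if (any(!is.finite(dl_target)) || any(dl_target <= 0) ||
      any(dl_target > 100)) {
    abort("`dl_target` must lie in (0, 100].")
  }
  100 * dl / dl_target
}

#' Summarize loading measurements
#'
#' Data-frame-first wrapper computing drug loading and encapsulation
#' efficiency per measurement row.
#'
#' @param measurements A data frame with columns `c_drug`, `c_total` (mg/mL)
#'   and `dl_target` (wt %).
#' @return The input as a tibble with `dl_pct` and `ee_pct` columns added.
#' @export
loading_summary <- function(measurements) {
  measurements <- as_tibble(measurements)
  needed <- c("c_drug", "c_total", "dl_target")
  missing <- setdiff(needed, names(measurements))
  if (length(missing) > 0) {
    abort(paste0("loading measurements need columns: ",
                 paste(missing, collapse = ", ")))
  }
  measurements |>
    dplyr::mutate(
      dl_pct = drug_loading(.data$c_drug, .data$c_total),
      ee_pct = encapsulation_efficiency(.data$dl_pct, .data$dl_target)
    )
}

#' Cumulative release time course
#'
#' Converts released-drug concentrations at each sampling time into percent
#' of the initial drug content: \eqn{100 \cdot C_{released} / C_{initial}}.
#' Values are not clamped to 100; small decreases between time points (from
#' sampling noise) are allowed but flagged with a warning.
#'
#' @param series A data frame with columns `time_h` (strictly increasing)
#'   and `c_released` (mg/mL, non-negative).
#' @param c_initial Initial drug concentration of the dispersion, mg/mL.
#' @return A tibble with columns `time_h`, `c_released`, `released_pct`.
#' @examples
#' rel <- tibble::tibble(time_h = c(1, 24, 120),
#'                       c_released = c(0.23, 0.28, 0.40))
#' cumulative_release(rel, c_initial = 1)
#' @export
cumulative_release <- function(series, c_initial) {
  series <- as_tibble(series)
  missing <- setdiff(c("time_h", "c_released"), names(series))
  if (length(missing) > 0) {
    abort(paste0("release series needs columns: ",
                 paste(missing, collapse = ", ")))
  }
  check_positive(c_initial, "c_initial")
  if (any(diff(series$time_h) <= 0)) {
    abort("`time_h` must be strictly increasing.")
  }
  check_non_negative(series$c_released, "c_released")
  out <- dplyr::mutate(series,
                       released_pct = 100 * .data$c_released / c_initial)
  if (any(diff(out$released_pct) < 0)) {
    warn("cumulative release decreases between some time points (sampling noise?).")
  }
  out
}

#' Characterize a release profile as burst plus sustained phases
#'
#' Reports the initial burst (the first measured release fraction), the
#' final cumulative release, and the mean release rate over the sustained
#' phase (after the first time point).
#'
#' @param release A tibble from [cumulative_release()].
#' @return A one-row tibble: `burst_pct`, `final_pct`, `sustained_rate_pct_per_h`,
#'   `duration_h`.
#' @export
release_profile_summary <- function(release) {
  release <- as_tibble(release)
  if (!"released_pct" %in% names(release)) {
    abort("`release` must come from cumulative_release().")
  }
  if (nrow(release) < 2) abort("need at least 2 time points.")
  first <- release[1, ]
  last <- release[nrow(release), ]
  tibble(
    burst_pct = first$released_pct,
    final_pct = last$released_pct,
    sustained_rate_pct_per_h =
      (last$released_pct - first$released_pct) /
      (last$time_h - first$time_h),
    duration_h = last$time_h - first$time_h
  )
}
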