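# ggplot2 visualisations for the main result types.

#' @describeIn size_distribution Histogram of pooled diameters with the
#'   mean marked.
#' @param object A `snap_size_distribution`.
#' @param bins Number of histogram bins.
#' @export
autoplot.snap_size_distribution <- function(object, bins = 40, ...) {
  df <- tibble(diameter = object$diameters)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$diameter)) +
    ggplot2::geom_histogram(bins = bins, fill = "grey35", colour = "white") +
    ggplot2::geom_vline(xintercept = object$mean_diameter,
                        linetype = "dashed", colour = "red") +
    ggplot2::labs(
      x = "Diameter (µm)", y = "Count",
      title = sprintf("n = %d, mean %.2f µm, PDI %.3f",
                      object$n, object$mean_diameter, object$pdi)
    ) +
    ggplot2::theme_minimal()
}

#' @describeIn growth_fit Log-log growth plot or scaling collapse.
#' @param object A `snap_growth_fit`.
#' @param which `"loglog"` (radius vs delay time per concentration, log
#'   axes) or `"collapse"` (diameter vs \eqn{(T_d C)^{1/3}} with the pooled
#'   fit line).
#' @export
autoplot.snap_growth_fit <- function(object, which = c("loglog", "collapse"),
                                     ...) {
  which <- match.arg(which)
  records <- object$records
  if (which == "loglog") {
    ggplot2::ggplot(records,
                    ggplot2::aes(x = .data$delay_time,
                                 y = .data$diameter / 2,
                                 colour = factor(.data$c_core))) +
      ggplot2::geom_point(size = 2) +
      ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                           linewidth = 0.5) +
      ggplot2::scale_x_log10() +
      ggplot2::scale_y_log10() +
      ggplot2::labs(x = "Delay time (ms)", y = "Radius (µm)",
                    colour = "C (mg/mL)",
                    title = "Growth-law linearization (slope 1/3 expected)") +
      ggplot2::theme_minimal()
  } else {
    df <- dplyr::filter(records,
                        .data$c_core %in% object$collapse_concentrations)
    df <- dplyr::mutate(df,
                        x = (.data$delay_time * .data$c_core)^(1 / 3))
    cf <- object$collapse
    ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$diameter,
                                     colour = factor(.data$c_core))) +
      ggplot2::geom_point(size = 2) +
      ggplot2::geom_abline(slope = cf$slope, intercept = cf$intercept,
                           linetype = "dashed") +
      ggplot2::labs(
        x = expression((T[d] %.% C[core])^{1 / 3}),
        y = "Diameter (µm)", colour = "C (mg/mL)",
        title = sprintf("Scaling collapse, r² = %.3f", cf$r_squared)
      ) +
      ggplot2::theme_minimal()
  }
}

#' Plot a cumulative release curve
#'
#' @param release A tibble from [cumulative_release()].
#' @return A ggplot object.
#' @export
plot_release_curve <- function(release) {
  stopifnot("released_pct" %in% names(release))
  ggplot2::ggplot(release, ggplot2::aes(x = .data$time_h,
                                        y = .data$released_pct)) +
    ggplot2::geom_line(colour = "grey40") +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(x = "Time (h)", y = "Cumulative release (%)") +
    ggplot2::theme_minimal()
}

#' Plot the concentration-regime map
#'
#' Shades the process phase regions (diffusion-limited, entanglement onset,
#' unstable) over a core-concentration range relative to the overlap
#' concentration, optionally overlaying observed conditions.
#'
#' @param c_star Overlap concentration, mg/mL.
#' @param c_core_range Concentration range to display, mg/mL.
#' @param conditions Optional tibble with columns `c_core` and `delay_time`
#'   of conditions to overlay.
#' @param entanglement_fraction,exponent_threshold Passed to
#'   [classify_regime()].
#' @return A ggplot object.
#' @export
plot_regime_map <- function(c_star, c_core_range = c(20, 140),
                            conditions = NULL,
                            entanglement_fraction = 0.85,
                            exponent_threshold = 0.15) {
  grid <- tibble(c_core = seq(c_core_range[1], c_core_range[2],
                              length.out = 200))
  grid <- dplyr::bind_cols(
    grid,
    dplyr::select(
      classify_regime(grid$c_core, c_star,
                      entanglement_fraction = entanglement_fraction,
                      exponent_threshold = exponent_threshold),
      "regime")
  )
  p <- ggplot2::ggplot(grid) +
    ggplot2::geom_tile(ggplot2::aes(x = .data$c_core, y = 1,
                                    fill = .data$regime), height = 2) +
    ggplot2::scale_fill_manual(values = c(
      diffusion_limited = "#7fbf7f", entanglement_onset = "#ffd27f",
      unstable_above_cstar = "#e88a8a")) +
    ggplot2::geom_vline(xintercept = c_star, linetype = "dashed") +
    ggplot2::labs(x = expression(C[core] ~ "(mg/mL)"), y = NULL,
                  fill = "Regime") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_blank())
  if (!is.null(conditions)) {
    p <- p + ggplot2::geom_point(
      data = conditions,
      ggplot2::aes(x = .data$c_core, y = 1), shape = 4, size = 2)
  }
  p
}
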