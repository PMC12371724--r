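# Aggregated reporting: one call that chains the design calculators, the
# growth-law fits and the drug metrics from a configuration.

#' Run the full process-analysis report
#'
#' Computes the design summary (viscosities, chain dimensions, overlap
#' concentration, delay time, predicted size, throughput, regime) from the
#' configuration; if size data are configured, fits the growth law and the
#' scaling collapse and classifies each concentration's regime; if drug
#' measurements are configured, computes loading, encapsulation efficiency
#' and the cumulative release curve. Deterministic given the configuration
#' and its seed.
#'
#' @param config A `snap_config` from [read_design_config()] /
#'   [as_snap_config()], or a path to a YAML configuration.
#' @return An object of class `snap_report`: a list with elements `design`
#'   (one-row tibble), `growth` (a [growth_fit()] or `NULL`), `regimes`,
#'   `drug` (list with `loading` and `release` tibbles or `NULL`), and
#'   `seed`.
#' @export
run_report <- function(config) {
  if (is.character(config)) config <- read_design_config(config)
  stopifnot(inherits(config, "snap_config"))

  design <- design_summary(
    config$polymer, config$solvent, config$formulation, config$channel,
    temperature = config$growth$temperature,
    huggins = config$growth$huggins,
    viscosity = config$growth$viscosity,
    dilution = config$growth$dilution
  )

  growth <- NULL
  regimes <- NULL
  if (!is.null(config$size_data)) {
    records <- if (is.character(config$size_data)) {
      read_size_records(config$size_data)
    } else {
      validate_size_records(config$size_data)
    }
    growth <- growth_fit(records,
                         collapse_concentrations =
                           config$collapse_concentrations,
                         c_star = design$c_star_mg_ml)
    regimes <- growth$regimes
  } else {
    warn("no size data configured: growth-law fit block omitted from the report.")
  }

  drug <- NULL
  if (!is.null(config$drug)) {
    loading <- NULL
    release <- NULL
    if (!is.null(config$drug$loading)) {
      loading <- loading_summary(as_tibble(
        purrr::map(config$drug$loading, as.numeric)))
    }
    if (!is.null(config$drug_release_path)) {
      series <- read_release_series(config$drug_release_path)
      release <- cumulative_release(series,
                                    c_initial = config$drug$c_initial)
    } else if (is.data.frame(config$drug$release)) {
      release <- cumulative_release(config$drug$release,
                                    c_initial = config$drug$c_initial)
    }
    drug <- list(loading = loading, release = release)
  }

  structure(
    list(design = design, growth = growth, regimes = regimes, drug = drug,
         seed = config$seed),
    class = "snap_report"
  )
}

#' @export
print.snap_report <- function(x, ...) {
  cat("<snap_report>\n\n-- Design summary --\n")
  print(x$design, ...)
  if (!is.null(x$growth)) {
    cat("\n-- Growth-law fits --\n")
    print(x$growth, ...)
  }
  if (!is.null(x$drug)) {
    cat("\n-- Drug metrics --\n")
    if (!is.null(x$drug$loading)) print(x$drug$loading, ...)
    if (!is.null(x$drug$release)) print(x$drug$release, ...)
  }
  invisible(x)
}

round_sig <- function(x, digits = 6) {
  if (is.list(x) && !is.data.frame(x)) return(lapply(x, round_sig, digits))
  if (is.data.frame(x)) {
    return(lapply(as.list(x), function(col) {
      if (is.numeric(col)) signif(col, digits) else col
    }))
  }
  if (is.numeric(x)) signif(x, digits) else x
}

#' Write a report as canonical JSON
#'
#' Serializes the report with all floats at 6 significant digits so repeated
#' runs produce byte-identical files.
#'
#' @param report A `snap_report` from [run_report()].
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_report_json <- function(report, path) {
  stopifnot(inherits(report, "snap_report"))
  payload <- list(
    seed = report$seed,
    design = round_sig(report$design)
  )
  if (!is.null(report$growth)) {
    payload$growth <- list(
      per_concentration = round_sig(
        dplyr::select(report$growth$per_concentration, -dplyr::any_of("fit"))),
      pooled = round_sig(report$growth$pooled),
      collapse = round_sig(
        dplyr::select(report$growth$collapse, -"concentrations"))
    )
    if (!is.null(report$regimes)) {
      payload$regimes <- round_sig(report$regimes)
    }
  }
  if (!is.null(report$drug)) {
    payload$drug <- list(
      loading = if (!is.null(report$drug$loading))
        round_sig(report$drug$loading),
      release = if (!is.null(report$drug$release))
        round_sig(report$drug$release)
    )
  }
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}
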