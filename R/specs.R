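# Validated parameter bundles for the process model. Each constructor is a
# light-weight record with invariant checks; all fields use the units a
# formulation scientist reports (mg/mL, mL/min, mm, cm, ms, Angstrom, mPa.s).

check_positive <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0) {
    abort(sprintf("`%s` must be a single positive finite number.", name))
  }
  invisible(x)
}

check_non_negative <- function(x, name) {
  if (!is.numeric(x) || any(!is.finite(x)) || any(x < 0)) {
    abort(sprintf("`%s` must be non-negative and finite.", name))
  }
  invisible(x)
}

check_fraction <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < 0 || x > 1) {
    abort(sprintf("`%s` must lie in [0, 1].", name))
  }
  invisible(x)
}

#' Polymer physical constants
#'
#' Bundles the constants of the core-forming polymer used throughout the
#' process model: the Mark-Houwink-Sakurada parameters relating intrinsic
#' viscosity to molecular weight, the Kuhn description of the chain used for
#' its radius of gyration, and the bulk density of the precipitated core.
#'
#' @param molecular_weight Molar mass, g/mol.
#' @param mh_K Mark-Houwink prefactor K, mL/g.
#' @param mh_exponent Mark-Houwink exponent (often written a), dimensionless,
#'   in (0, 2).
#' @param kuhn_length Kuhn segment length b, Angstrom.
#' @param kuhn_segments Number of Kuhn segments N.
#' @param density Density of the precipitated core material, g/mL.
#'
#' @return An object of class `polymer_spec`.
#' @examples
#' pla <- polymer_spec(
#'   molecular_weight = 17500, mh_K = 0.0174, mh_exponent = 0.736,
#'   kuhn_length = 8.81, kuhn_segments = 121, density = 1.25
#' )
#' intrinsic_viscosity(pla)
#' @export
polymer_spec <- function(molecular_weight, mh_K, mh_exponent,
                         kuhn_length = NA_real_, kuhn_segments = NA_real_,
                         density = NA_real_) {
  check_positive(molecular_weight, "molecular_weight")
  check_positive(mh_K, "mh_K")
  check_positive(mh_exponent, "mh_exponent")
  if (mh_exponent >= 2) abort("`mh_exponent` must be below 2.")
  if (!is.na(kuhn_length)) check_positive(kuhn_length, "kuhn_length")
  if (!is.na(kuhn_segments)) {
    check_positive(kuhn_segments, "kuhn_segments")
    if (kuhn_segments < 1) abort("`kuhn_segments` must be at least 1.")
  }
  if (!is.na(density)) check_positive(density, "density")
  structure(
    list(
      molecular_weight = molecular_weight, mh_K = mh_K,
      mh_exponent = mh_exponent, kuhn_length = kuhn_length,
      kuhn_segments = kuhn_segments, density = density
    ),
    class = "polymer_spec"
  )
}

#' @export
print.polymer_spec <- function(x, ...) {
  cat("<polymer_spec>\n")
  cat(sprintf("  M        : %g g/mol\n", x$molecular_weight))
  cat(sprintf("  K, a     : %g mL/g, %g\n", x$mh_K, x$mh_exponent))
  cat(sprintf("  Kuhn b, N: %g Angstrom, %g segments\n",
              x$kuhn_length, x$kuhn_segments))
  cat(sprintf("  density  : %g g/mL\n", x$density))
  invisible(x)
}

#' Solvent description
#'
#' @param name Solvent name.
#' @param viscosity Dynamic viscosity of the pure solvent, mPa·s.
#' @return An object of class `solvent_spec`.
#' @examples
#' solvent_spec("THF", viscosity = 0.46)
#' @export
solvent_spec <- function(name, viscosity) {
  check_positive(viscosity, "viscosity")
  structure(list(name = as.character(name), viscosity = viscosity),
            class = "solvent_spec")
}

#' @export
print.solvent_spec <- function(x, ...) {
  cat(sprintf("<solvent_spec> %s, viscosity %g mPa.s\n", x$name, x$viscosity))
  invisible(x)
}

#' Core stream formulation
#'
#' Total dissolved solids of the organic (core-forming) stream and its mass
#' split between the viscosifying polymer, drug and dye. Fractions must sum
#' to at most 1; any remainder is unclassified solids.
#'
#' @param c_core_total Total dissolved solids, mg/mL.
#' @param polymer_mass_fraction Fraction of solids that is the polymer.
#' @param drug_mass_fraction Fraction of solids that is drug.
#' @param dye_mass_fraction Fraction of solids that is dye.
#' @return An object of class `core_formulation`.
#' @examples
#' core_formulation(40, polymer_mass_fraction = 0.98, dye_mass_fraction = 0.02)
#' @export
core_formulation <- function(c_core_total, polymer_mass_fraction = 1,
                             drug_mass_fraction = 0, dye_mass_fraction = 0) {
  check_positive(c_core_total, "c_core_total")
  check_fraction(polymer_mass_fraction, "polymer_mass_fraction")
  check_fraction(drug_mass_fraction, "drug_mass_fraction")
  check_fraction(dye_mass_fraction, "dye_mass_fraction")
  total <- polymer_mass_fraction + drug_mass_fraction + dye_mass_fraction
  if (total > 1 + 1e-9) abort("mass fractions must sum to at most 1.")
  structure(
    list(
      c_core_total = c_core_total,
      polymer_mass_fraction = polymer_mass_fraction,
      drug_mass_fraction = drug_mass_fraction,
      dye_mass_fraction = dye_mass_fraction
    ),
    class = "core_formulation"
  )
}

#' Concentration of a formulation component
#'
#' The viscosity model is evaluated with the polymer-only concentration by
#' default, because only the polymer viscosifies the stream; small-molecule
#' dye or drug loads contribute solids but negligible viscosity.
#'
#' @param formulation A [core_formulation()].
#' @param basis `"polymer"` (polymer-only, default) or `"total"` (all solids).
#' @return Concentration in mg/mL.
#' @export
core_polymer_concentration <- function(formulation,
                                       basis = c("polymer", "total")) {
  basis <- match.arg(basis)
  stopifnot(inherits(formulation, "core_formulation"))
  if (basis == "total") {
    formulation$c_core_total
  } else {
    formulation$c_core_total * formulation$polymer_mass_fraction
  }
}

#' Delay channel geometry
#'
#' The tubing that connects the core-forming mixer to the stabilizing mixer.
#' Its volume divided by the total volumetric flow gives the delay time, the
#' residence time during which cores grow.
#'
#' @param fixed_volume Volume of fixed channel segments (fittings etc.), mL.
#' @param tubing_inner_diameter Inner diameter of the interchangeable tubing,
#'   mm.
#' @param tubing_length Length of the interchangeable tubing, cm.
#' @param stream_flow_rates Flow rate of each stream feeding the channel,
#'   mL/min.
#' @return An object of class `delay_channel`.
#' @examples
#' ch <- delay_channel(
#'   fixed_volume = 0, tubing_inner_diameter = 1.016,
#'   tubing_length = 14.8, stream_flow_rates = c(60, 60)
#' )
#' delay_time(ch)
#' @export
delay_channel <- function(fixed_volume = 0, tubing_inner_diameter = 0,
                          tubing_length = 0, stream_flow_rates = numeric()) {
  check_non_negative(fixed_volume, "fixed_volume")
  check_non_negative(tubing_inner_diameter, "tubing_inner_diameter")
  check_non_negative(tubing_length, "tubing_length")
  check_non_negative(stream_flow_rates, "stream_flow_rates")
  structure(
    list(
      fixed_volume = fixed_volume,
      tubing_inner_diameter = tubing_inner_diameter,
      tubing_length = tubing_length,
      stream_flow_rates = stream_flow_rates
    ),
    class = "delay_channel"
  )
}

#' Growth conditions for the diffusion-limited size prediction
#'
#' @param temperature Absolute temperature, K.
#' @param delay_time Growth time (the inter-mixer delay), ms.
#' @param viscosity Dynamic viscosity of the growth medium, mPa·s. The
#'   organic-stream solution viscosity is the conventional choice.
#' @param huggins_coefficient Huggins coefficient used when deriving the
#'   solution viscosity (0.3 for good solvents).
#' @return An object of class `growth_conditions`.
#' @export
growth_conditions <- function(temperature = 298.15, delay_time = 0,
                              viscosity = NULL, huggins_coefficient = 0.3) {
  check_positive(temperature, "temperature")
  check_non_negative(delay_time, "delay_time")
  if (!is.null(viscosity)) check_positive(viscosity, "viscosity")
  check_non_negative(huggins_coefficient, "huggins_coefficient")
  structure(
    list(
      temperature = temperature, delay_time = delay_time,
      viscosity = viscosity, huggins_coefficient = huggins_coefficient
    ),
    class = "growth_conditions"
  )
}
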