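# Closed-form physical calculators for the SNaP process model. All functions
# are pure; public units follow lab reporting conventions (mg/mL, ms, um,
# Angstrom, mPa.s) with SI conversions handled internally.

#' Intrinsic viscosity from the Mark-Houwink-Sakurada equation
#'
#' \eqn{[\eta] = K M^a}, the dilute-solution intrinsic viscosity of a linear
#' polymer of molar mass M.
#'
#' @param polymer A [polymer_spec()].
#' @return Intrinsic viscosity, mL/g.
#' @examples
#' pla <- polymer_spec(17500, mh_K = 0.0174, mh_exponent = 0.736)
#' intrinsic_viscosity(pla) # ~23.1 mL/g for 17.5 kDa PLA in THF
#' @export
intrinsic_viscosity <- function(polymer) {
  stopifnot(inherits(polymer, "polymer_spec"))
  polymer$mh_K * polymer$molecular_weight^polymer$mh_exponent
}

#' Solution dynamic viscosity from the Huggins equation
#'
#' \eqn{\eta = \eta_s (1 + [\eta] c + k_H [\eta]^2 c^2)}: a virial-like
#' expansion of the solution viscosity in polymer concentration, truncated at
#' second order. Valid below the overlap concentration.
#'
#' @param solvent A [solvent_spec()] providing the pure-solvent viscosity
#'   \eqn{\eta_s}.
#' @param intrinsic_visc Intrinsic viscosity \eqn{[\eta]}, mL/g.
#' @param conc Polymer concentration, mg/mL (converted internally to g/mL to
#'   pair with \eqn{[\eta]}). May be a vector.
#' @param huggins Huggins coefficient \eqn{k_H} (0.3 for good solvents).
#' @return Dynamic viscosity, mPa·s (same length as `conc`).
#' @examples
#' thf <- solvent_spec("THF", 0.46)
#' pla <- polymer_spec(17500, 0.0174, 0.736)
#' solution_viscosity(thf, intrinsic_viscosity(pla), conc = c(39.2, 98))
#' @export
solution_viscosity <- function(solvent, intrinsic_visc, conc, huggins = 0.3) {
  stopifnot(inherits(solvent, "solvent_spec"))
  check_positive(intrinsic_visc, "intrinsic_visc")
  if (any(!is.finite(conc)) || any(conc < 0)) {
    abort("`conc` must be non-negative (mg/mL).")
  }
  c_g_ml <- conc / 1000
  red <- intrinsic_visc * c_g_ml
  solvent$viscosity * (1 + red + huggins * red^2)
}

#' Radius of gyration of an ideal Kuhn chain
#'
#' \eqn{R_g = \sqrt{N b^2 / 6}} for a chain of N Kuhn segments of length b.
#'
#' @param polymer A [polymer_spec()] with `kuhn_length` and `kuhn_segments`.
#' @return Radius of gyration, Angstrom.
#' @examples
#' pla <- polymer_spec(17500, 0.0174, 0.736, kuhn_length = 8.81,
#'                     kuhn_segments = 121)
#' radius_of_gyration(pla) # 39.6 Angstrom
#' @export
radius_of_gyration <- function(polymer) {
  stopifnot(inherits(polymer, "polymer_spec"))
  if (is.na(polymer$kuhn_length) || is.na(polymer$kuhn_segments)) {
    abort("polymer must define `kuhn_length` and `kuhn_segments`.")
  }
  sqrt(polymer$kuhn_segments * polymer$kuhn_length^2 / 6)
}

#' Coil overlap concentration
#'
#' \eqn{C^* \simeq 3M / (4 \pi N_A R_g^3)}: the concentration at which coils
#' of radius \eqn{R_g} fill the solution volume. Above it chains entangle and
#' precipitation no longer proceeds through individual collapsed globules.
#'
#' @param polymer A [polymer_spec()].
#' @param rg Radius of gyration, Angstrom. Defaults to
#'   [radius_of_gyration()] of `polymer`.
#' @return Overlap concentration, mg/mL.
#' @examples
#' pla <- polymer_spec(17500, 0.0174, 0.736, 8.81, 121)
#' overlap_concentration(pla) # ~112 mg/mL
#' @export
overlap_concentration <- function(polymer, rg = radius_of_gyration(polymer)) {
  stopifnot(inherits(polymer, "polymer_spec"))
  check_positive(rg, "rg")
  rg_cm <- rg * 1e-8
  c_g_ml <- 3 * polymer$molecular_weight /
    (4 * pi * AVOGADRO_PER_MOL * rg_cm^3)
  c_g_ml * 1000
}

#' Delay time of the inter-mixer channel
#'
#' Total channel volume (fixed segments plus interchangeable tubing of
#' cross-section \eqn{\pi (d/2)^2} and length L) divided by the summed
#' volumetric flow of all streams passing through it.
#'
#' @param channel A [delay_channel()].
#' @return Delay time, ms.
#' @export
delay_time <- function(channel) {
  stopifnot(inherits(channel, "delay_channel"))
  q_total <- sum(channel$stream_flow_rates)
  if (q_total <= 0) abort("total flow rate must be positive to compute a delay time.")
  # mm -> cm for the radius; cross-section cm^2 * length cm = mL
  radius_cm <- channel$tubing_inner_diameter / 20
  volume_ml <- channel$fixed_volume + pi * radius_cm^2 * channel$tubing_length
  minutes <- volume_ml / q_total
  minutes * 60000
}

#' Diffusion-limited (Smoluchowski) growth radius
#'
#' Mean aggregate radius after growth time t under Brownian
#' diffusion-limited aggregation of core material at mass concentration
#' \eqn{C}: \eqn{R = (t k_B T C / (\pi \eta \rho))^{1/3}}. The prediction
#' captures the cube-root scaling in time and concentration; absolute sizes
#' depend on nucleation details it does not model.
#'
#' @param conditions A [growth_conditions()] (temperature K, delay time ms,
#'   viscosity mPa·s).
#' @param formulation A [core_formulation()] providing the core
#'   concentration.
#' @param polymer A [polymer_spec()] providing the core density.
#' @param dilution Factor by which the core stream is diluted between
#'   nucleation and stabilization (e.g. 2 for a 1:1 antisolvent mix). The
#'   concentration entering the growth law is `c_core_total / dilution`.
#'   Default 1 (organic-stream concentration).
#' @return Predicted radius, um. Zero when the delay time is zero.
#' @export
smoluchowski_radius <- function(conditions, formulation, polymer,
                                dilution = 1) {
  stopifnot(inherits(conditions, "growth_conditions"),
            inherits(formulation, "core_formulation"),
            inherits(polymer, "polymer_spec"))
  if (is.null(conditions$viscosity)) {
    abort("`conditions$viscosity` is required for the growth prediction.")
  }
  if (is.na(polymer$density)) abort("polymer must define `density`.")
  check_positive(dilution, "dilution")
  t_s <- conditions$delay_time / 1000
  if (t_s == 0) return(0)
  conc_kg_m3 <- formulation$c_core_total / dilution # mg/mL == kg/m^3
  eta_pa_s <- conditions$viscosity / 1000
  rho_kg_m3 <- polymer$density * 1000
  r_m <- (t_s * BOLTZMANN_J_PER_K * conditions$temperature * conc_kg_m3 /
            (pi * eta_pa_s * rho_kg_m3))^(1 / 3)
  r_m * 1e6
}

#' Mass throughput of the core stream
#'
#' Dissolved-solids mass delivered per hour through the core stream at the
#' given flow rate; for a fully converting continuous process this is the
#' particle production rate.
#'
#' @param core_flow_rate Core stream flow rate, mL/min.
#' @param c_core_total Total dissolved solids, mg/mL.
#' @return Production rate, g/h.
#' @examples
#' throughput(60, 40)  # 144 g/h
#' throughput(60, 100) # 360 g/h
#' @export
throughput <- function(core_flow_rate, c_core_total) {
  check_non_negative(core_flow_rate, "core_flow_rate")
  check_non_negative(c_core_total, "c_core_total")
  core_flow_rate * c_core_total * 60 / 1000
}

#' One-row design summary for a formulation and channel
#'
#' Chains the calculators into the quantities a process designer reviews
#' before a run: organic-stream viscosity, chain dimensions, overlap
#' concentration, delay time, predicted particle size, throughput and a
#' concentration-regime flag.
#'
#' @param polymer A [polymer_spec()].
#' @param solvent A [solvent_spec()].
#' @param formulation A [core_formulation()].
#' @param channel A [delay_channel()].
#' @param temperature Growth temperature, K.
#' @param huggins Huggins coefficient.
#' @param viscosity Optional override of the growth-medium viscosity, mPa·s;
#'   defaults to the computed organic-stream solution viscosity.
#' @param basis Concentration basis for the viscosity model; see
#'   [core_polymer_concentration()].
#' @param core_flow_rate Core stream flow rate for throughput, mL/min.
#'   Defaults to the first entry of `channel$stream_flow_rates`.
#' @param dilution Passed to [smoluchowski_radius()].
#' @return A one-row tibble with columns `intrinsic_viscosity_ml_g`,
#'   `viscosity_mpas`, `rg_angstrom`, `c_star_mg_ml`, `delay_time_ms`,
#'   `predicted_radius_um`, `predicted_diameter_um`, `throughput_g_h`,
#'   `regime`.
#' @export
design_summary <- function(polymer, solvent, formulation, channel,
                           temperature = 298.15, huggins = 0.3,
                           viscosity = NULL,
                           basis = c("polymer", "total"),
                           core_flow_rate = channel$stream_flow_rates[1],
                           dilution = 1) {
  basis <- match.arg(basis)
  iv <- intrinsic_viscosity(polymer)
  conc <- core_polymer_concentration(formulation, basis)
  eta <- solution_viscosity(solvent, iv, conc, huggins)
  eta_growth <- viscosity %||% eta
  rg <- radius_of_gyration(polymer)
  c_star <- overlap_concentration(polymer, rg)
  td <- delay_time(channel)
  cond <- growth_conditions(temperature = temperature, delay_time = td,
                            viscosity = eta_growth,
                            huggins_coefficient = huggins)
  r_pred <- smoluchowski_radius(cond, formulation, polymer,
                                dilution = dilution)
  regime <- classify_regime(formulation$c_core_total, c_star)$regime
  tibble(
    intrinsic_viscosity_ml_g = iv,
    viscosity_mpas = eta,
    rg_angstrom = rg,
    c_star_mg_ml = c_star,
    delay_time_ms = td,
    predicted_radius_um = r_pred,
    predicted_diameter_um = 2 * r_pred,
    throughput_g_h = throughput(core_flow_rate, formulation$c_core_total),
    regime = regime
  )
}
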