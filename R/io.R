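# Readers and writers for the package's tabular formats, image loading and
# the YAML design configuration.

#' Read a micrograph from a PNG or TIFF file
#'
#' @param path Path to a grayscale PNG or TIFF image.
#' @param scale Physical scale, um per pixel (not stored in the image).
#' @param id Identifier; defaults to the file name.
#' @return A [micrograph()].
#' @export
read_micrograph <- function(path, scale, id = basename(path)) {
  if (!file.exists(path)) abort(sprintf("image file not found: %s", path))
  ext <- tolower(tools::file_ext(path))
  pixels <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    abort(sprintf("unsupported image format: .%s (use PNG or TIFF)", ext))
  )
  micrograph(pixels, scale = scale, id = id)
}

#' Write a micrograph to a PNG file
#'
#' @param image A [micrograph()].
#' @param path Output path (.png).
#' @return `path`, invisibly.
#' @export
write_micrograph <- function(image, path) {
  stopifnot(inherits(image, "snap_micrograph"))
  png::writePNG(image$pixels, target = path)
  invisible(path)
}

#' Read and write size-record tables
#'
#' CSV columns: `c_core_mg_per_mL`, `delay_time_ms`, `diameter_um`, and
#' optionally `pdi` and `sd_um`; mapped to the package's canonical column
#' names (`c_core`, `delay_time`, `diameter`, `pdi`, `sd`).
#'
#' @param path CSV file path.
#' @return `read_size_records()`: a tibble of size records.
#' @export
read_size_records <- function(path) {
  if (!file.exists(path)) abort(sprintf("size-record file not found: %s", path))
  raw <- readr::read_csv(path, show_col_types = FALSE, comment = "#")
  rename_map <- c(c_core = "c_core_mg_per_mL", delay_time = "delay_time_ms",
                  diameter = "diameter_um", sd = "sd_um")
  for (new in names(rename_map)) {
    old <- rename_map[[new]]
    if (old %in% names(raw)) names(raw)[names(raw) == old] <- new
  }
  validate_size_records(raw)
}

#' @rdname read_size_records
#' @param records A tibble of size records.
#' @return `write_size_records()`: `path`, invisibly.
#' @export
write_size_records <- function(records, path) {
  records <- validate_size_records(records)
  out <- dplyr::rename(records,
    c_core_mg_per_mL = "c_core", delay_time_ms = "delay_time",
    diameter_um = "diameter")
  if ("sd" %in% names(out)) out <- dplyr::rename(out, sd_um = "sd")
  readr::write_csv(out, path)
  invisible(path)
}

#' Read a release time course
#'
#' CSV columns: `time_h`, `c_released_mg_per_mL` (mapped to `c_released`).
#'
#' @param path CSV file path.
#' @return A tibble with columns `time_h`, `c_released`.
#' @export
read_release_series <- function(path) {
  if (!file.exists(path)) abort(sprintf("release file not found: %s", path))
  raw <- readr::read_csv(path, show_col_types = FALSE, comment = "#")
  if ("c_released_mg_per_mL" %in% names(raw)) {
    names(raw)[names(raw) == "c_released_mg_per_mL"] <- "c_released"
  }
  missing <- setdiff(c("time_h", "c_released"), names(raw))
  if (length(missing) > 0) {
    abort(paste0("release series needs columns: ",
                 paste(missing, collapse = ", ")))
  }
  as_tibble(raw)
}

#' Write per-particle detections and distribution summaries
#'
#' @param detections A detection tibble from [detect_particles()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_particles_csv <- function(detections, path) {
  out <- dplyr::select(as_tibble(detections),
                       "image", "center_x", "center_y",
                       diameter_um = "diameter")
  readr::write_csv(out, path)
  invisible(path)
}

#' @rdname write_particles_csv
#' @param dist A [size_distribution()].
#' @export
write_distribution_csv <- function(dist, path) {
  stopifnot(inherits(dist, "snap_size_distribution"))
  readr::write_csv(glance(dist), path)
  invisible(path)
}

#' Load a design configuration from YAML
#'
#' Reads a key/value configuration with blocks `polymer`, `solvent`,
#' `formulation`, `channel` and optional `growth` (temperature, huggins,
#' viscosity), `collapse_concentrations`, `size_data` (CSV path), `drug`
#' (loading measurements and release path) and `seed`, returning validated
#' spec objects. See the bundled example:
#' `system.file("extdata", "pla_design.yaml", package = "snapmp")`.
#'
#' @param path YAML file path.
#' @param base_dir Directory against which relative data paths are
#'   resolved; defaults to the configuration file's directory.
#' @return A named list of class `snap_config`.
#' @export
read_design_config <- function(path, base_dir = dirname(path)) {
  if (!file.exists(path)) abort(sprintf("config file not found: %s", path))
  raw <- yaml::read_yaml(path)
  as_snap_config(raw, base_dir = base_dir)
}

#' @rdname read_design_config
#' @param x A named list with the same structure as the YAML file.
#' @export
as_snap_config <- function(x, base_dir = ".") {
  need <- function(block) {
    if (is.null(x[[block]])) abort(sprintf("config is missing the `%s` block.", block))
    x[[block]]
  }
  p <- need("polymer")
  s <- need("solvent")
  f <- need("formulation")
  ch <- need("channel")
  resolve <- function(path) {
    if (is.null(path)) return(NULL)
    if (file.exists(path)) path else file.path(base_dir, path)
  }
  cfg <- list(
    polymer = polymer_spec(
      molecular_weight = p$molecular_weight, mh_K = p$mh_K,
      mh_exponent = p$mh_exponent,
      kuhn_length = p$kuhn_length %||% NA_real_,
      kuhn_segments = p$kuhn_segments %||% NA_real_,
      density = p$density %||% NA_real_
    ),
    solvent = solvent_spec(s$name %||% "solvent", s$viscosity),
    formulation = core_formulation(
      c_core_total = f$c_core_total,
      polymer_mass_fraction = f$polymer_mass_fraction %||% 1,
      drug_mass_fraction = f$drug_mass_fraction %||% 0,
      dye_mass_fraction = f$dye_mass_fraction %||% 0
    ),
    channel = delay_channel(
      fixed_volume = ch$fixed_volume %||% 0,
      tubing_inner_diameter = ch$tubing_inner_diameter %||% 0,
      tubing_length = ch$tubing_length %||% 0,
      stream_flow_rates = as.numeric(ch$stream_flow_rates %||% numeric())
    ),
    growth = list(
      temperature = x$growth$temperature %||% 298.15,
      huggins = x$growth$huggins %||% 0.3,
      viscosity = x$growth$viscosity,
      dilution = x$growth$dilution %||% 1
    ),
    collapse_concentrations =
      as.numeric(x$collapse_concentrations %||% c(40, 60, 80)),
    size_data = resolve(x$size_data),
    drug = x$drug,
    drug_release_path = resolve(x$drug$release),
    seed = as.integer(x$seed %||% 1L)
  )
  structure(cfg, class = "snap_config")
}
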