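## Configuration file handling.  A configuration holds the four core
## objects (conditions, ion, geometry, charges) plus optional rate and
## generator sections, serialised as JSON or YAML by file extension.

#' Default analysis configuration
#'
#' @return A named list with `conditions`, `ion`, `geometry` and `charges`
#'   entries built from the package defaults.
#' @examples
#' cfg <- default_config()
#' names(cfg)
#' @export
default_config <- function() {
  list(conditions = conditions(),
       ion = ion_species(),
       geometry = pore_geometry(),
       charges = crown_ether_charges())
}

config_builders <- list(
  conditions = function(x) do.call(conditions, x),
  ion        = function(x) do.call(ion_species, x),
  geometry   = function(x) do.call(pore_geometry, x),
  charges    = function(x) do.call(pore_charge_set, x)
)

## fields accepted by each section constructor (used for validation and for
## stripping derived fields on write)
config_fields <- list(
  conditions = c("temperature", "concentration", "bulk_resistivity", "epsilon_r"),
  ion        = c("valence", "mobility", "diffusion", "vdw_radius",
                 "hydration_radii", "hydration_energies", "hydration_eta",
                 "temperature"),
  geometry   = c("nominal_radius_0", "strain_coefficient", "oxygen_vdw_radius",
                 "effective_radius", "effective_length", "internal_site_length",
                 "staging_spread", "crossing_spread", "abf_radius",
                 "carbon_vdw_radius"),
  charges    = c("charge", "count", "radial_position", "axial_position")
)

#' Read and write analysis configurations
#'
#' Configurations are stored as JSON (`.json`) or YAML (`.yml`/`.yaml`).
#' Unknown fields and malformed values produce errors naming the offending
#' section and field.  Sections omitted from the file fall back to package
#' defaults.
#'
#' @param path file path; the extension selects the format.
#' @return `read_config()` returns a list with `conditions`, `ion`,
#'   `geometry` and `charges` objects; `write_config()` returns `path`
#'   invisibly.
#' @examples
#' p <- tempfile(fileext = ".json")
#' write_config(default_config(), p)
#' cfg <- read_config(p)
#' cfg$geometry$effective_radius
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  raw <- switch(config_format(path),
                json = jsonlite::fromJSON(path, simplifyVector = TRUE),
                yaml = yaml::read_yaml(path))
  if (!is.list(raw)) stop("config must be a mapping of sections", call. = FALSE)
  out <- default_config()
  for (section in names(raw)) {
    if (!section %in% names(config_builders))
      stop(sprintf("unknown config section '%s' (expected: %s)", section,
                   paste(names(config_builders), collapse = ", ")), call. = FALSE)
    vals <- raw[[section]]
    unknown <- setdiff(names(vals), config_fields[[section]])
    if (length(unknown))
      stop(sprintf("unknown field(s) in config section '%s': %s", section,
                   paste(unknown, collapse = ", ")), call. = FALSE)
    out[[section]] <- tryCatch(config_builders[[section]](vals),
      error = function(e) stop(sprintf("config section '%s': %s",
                                       section, conditionMessage(e)), call. = FALSE))
  }
  out
}

#' @rdname read_config
#' @param config a list as returned by [default_config()] or [read_config()].
#' @export
write_config <- function(config, path) {
  ser <- lapply(names(config_fields), function(section) {
    obj <- config[[section]]
    if (is.null(obj)) return(NULL)
    unclass(obj)[intersect(config_fields[[section]], names(obj))]
  })
  names(ser) <- names(config_fields)
  ser <- Filter(Negate(is.null), ser)
  switch(config_format(path),
         json = jsonlite::write_json(ser, path, auto_unbox = TRUE, digits = NA,
                                     pretty = TRUE),
         yaml = yaml::write_yaml(ser, path, precision = 15))
  invisible(path)
}

config_format <- function(path) {
  ext <- tolower(sub(".*\\.", "", path))
  if (ext == "json") return("json")
  if (ext %in% c("yml", "yaml")) return("yaml")
  stop("unsupported config extension '.", ext, "' (use .json, .yml or .yaml)",
       call. = FALSE)
}
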