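# Reference constants and lookup tables: carbon intensities, PUE values,
# processor power draws, and the physical constants of the energy model.

the <- new.env(parent = emptyenv())

#' Load a reference data file
#'
#' Reads a YAML reference file (constants, carbon-intensity table, PUE
#' table, processor catalog) and makes it the active registry for all
#' subsequent lookups. The bundled file is loaded automatically on first
#' use; call this only to substitute an edited copy.
#'
#' @param path Path to a YAML reference file. `NULL` restores the bundled
#'   tables.
#' @return Invisibly, the previously active registry (a list), so callers
#'   can restore it; see [reset_reference_data()].
#' @export
use_reference_data <- function(path = NULL) {
  old <- the$registry
  if (is.null(path)) {
    path <- system.file("extdata", "reference_data.yaml", package = "greencompute")
  }
  if (!file.exists(path)) {
    gc_stop(sprintf("reference data file not found: '%s'", path), "lookup")
  }
  reg <- yaml::read_yaml(path)
  required <- c("schema_version", "constants", "carbon_intensity", "pue", "processors")
  missing <- setdiff(required, names(reg))
  if (length(missing) > 0) {
    gc_stop(sprintf("reference data file is missing sections: %s",
                    paste(missing, collapse = ", ")), "validation")
  }
  the$registry <- reg
  invisible(old)
}

#' Restore reference tables
#'
#' Reinstates a registry previously returned by [use_reference_data()],
#' or the bundled tables when called with no argument.
#'
#' @param registry A registry list, or `NULL` for the bundled tables.
#' @return Invisibly, the registry now in effect.
#' @export
reset_reference_data <- function(registry = NULL) {
  if (is.null(registry)) {
    use_reference_data(NULL)
  } else {
    the$registry <- registry
  }
  invisible(the$registry)
}

registry <- function() {
  if (is.null(the$registry)) use_reference_data(NULL)
  the$registry
}

#' Model constants
#'
#' Returns the registry of physical constants used throughout the energy
#' model: memory power density (0.3725 W/GB), the Wh-to-kWh conversion
#' (0.001), the car emission factor (0.175 kgCO2e/km), the tree-month
#' sequestration constant (0.917 kgCO2e), the default per-core power
#' (12 W) and the default core usage factor (1).
#'
#' @param name Optional constant name; when given, the single value is
#'   returned instead of the full list.
#' @return A named list of constants, or one numeric value.
#' @examples
#' gc_constants("memory_power_per_gb")
#' @export
gc_constants <- function(name = NULL) {
  consts <- registry()$constants
  if (is.null(name)) return(consts)
  if (!name %in% names(consts)) {
    gc_stop(sprintf("unknown constant '%s'; valid constants: %s",
                    name, paste(names(consts), collapse = ", ")), "lookup")
  }
  consts[[name]]
}

#' Carbon intensity table
#'
#' @return A tibble of region keys and carbon intensities (kgCO2e/kWh).
#' @export
carbon_intensity_table <- function() {
  tab <- registry()$carbon_intensity
  tibble::tibble(region = names(tab), ci = as.numeric(unlist(tab)))
}

#' PUE table
#'
#' @return A tibble of facility keys and power usage effectiveness values.
#' @export
pue_table <- function() {
  tab <- registry()$pue
  tibble::tibble(facility = names(tab), pue = as.numeric(unlist(tab)))
}

#' Processor catalog
#'
#' Known processors with core counts and total power draw. Per-core power
#' is derived as `total_power / core_count`. The `provenance` column marks
#' whether the power figure comes from the curated benchmark sources
#' (`curated`) or from a vendor TDP sheet (`vendor`).
#'
#' @return A tibble with columns `name`, `kind`, `core_count`,
#'   `total_power`, `power_per_core`, `provenance`.
#' @export
processor_catalog <- function() {
  procs <- registry()$processors
  out <- tibble::tibble(
    name = vapply(procs, `[[`, character(1), "name"),
    kind = vapply(procs, `[[`, character(1), "kind"),
    core_count = vapply(procs, function(p) as.integer(p$core_count), integer(1)),
    total_power = vapply(procs, function(p) as.numeric(p$total_power), numeric(1)),
    provenance = vapply(procs, `[[`, character(1), "provenance")
  )
  out$power_per_core <- out$total_power / out$core_count
  out[, c("name", "kind", "core_count", "total_power", "power_per_core", "provenance")]
}

canonical_key <- function(key) {
  key <- tolower(trimws(key))
  gsub("[ _]+", "-", key)
}

resolve_key <- function(key, table, aliases, what) {
  k <- canonical_key(key)
  if (!is.null(aliases) && k %in% names(aliases)) k <- aliases[[k]]
  if (!k %in% names(table)) {
    gc_stop(sprintf("unknown %s '%s'; valid keys: %s", what, key,
                    paste(sort(unique(c(names(table), names(aliases)))),
                          collapse = ", ")), "lookup")
  }
  k
}

#' Look up the carbon intensity of a region
#'
#' Carbon intensity (CI) is the mass of CO2-equivalent emitted per kWh of
#' electricity produced; it varies widely between national grids.
#' Matching is case-insensitive on a documented key set with aliases
#' (e.g. `"uk"` for `"united-kingdom"`).
#'
#' @param region Region key, e.g. `"global"`, `"australia"`, `"uk"`.
#' @return Carbon intensity in kgCO2e/kWh.
#' @examples
#' get_carbon_intensity("global")     # 0.475
#' get_carbon_intensity("australia")  # 0.88
#' @export
get_carbon_intensity <- function(region) {
  reg <- registry()
  k <- resolve_key(region, reg$carbon_intensity, reg$carbon_intensity_aliases,
                   "region")
  as.numeric(reg$carbon_intensity[[k]])
}

#' Look up the power usage effectiveness of a facility
#'
#' PUE is the ratio of a data centre's total energy draw to the energy
#' delivered to computing hardware (1 is ideal). The default facility is
#' the global average (1.67).
#'
#' @param facility Facility key, e.g. `"google-cloud"`, `"aws"`. Defaults
#'   to `"global-average"`.
#' @return PUE (unitless, >= 1).
#' @examples
#' get_pue()               # 1.67
#' get_pue("google-cloud") # 1.11
#' @export
get_pue <- function(facility = "global-average") {
  reg <- registry()
  k <- resolve_key(facility, reg$pue, reg$pue_aliases, "facility")
  as.numeric(reg$pue[[k]])
}

#' Parse a human-readable duration into decimal hours
#'
#' Accepts durations in the form `"<int> h <int> min <number> s"` with any
#' component optional (at least one required), plus bare decimal hours
#' such as `"60.97 h"`. Thousands separators in the hour figure
#' (`"300,000 h"`) are accepted.
#'
#' @param text Character vector of duration strings.
#' @return Numeric vector of hours.
#' @examples
#' parse_duration("60 h 58 min")
#' parse_duration("3 min 21 s")
#' @export
parse_duration <- function(text) {
  vapply(text, parse_duration_one, numeric(1), USE.NAMES = FALSE)
}

parse_duration_one <- function(text) {
  if (length(text) != 1 || is.na(text) || !nzchar(trimws(text))) {
    gc_stop("empty duration string", "parse")
  }
  s <- tolower(trimws(text))
  s <- gsub(",", "", s)
  num <- "[0-9]+(?:\\.[0-9]+)?"
  pat <- sprintf(
    "^(?:(%s)\\s*h(?:ours?)?)?\\s*(?:(%s)\\s*min(?:utes?)?)?\\s*(?:(%s)\\s*s(?:ec(?:onds?)?)?)?$",
    num, num, num)
  m <- regmatches(s, regexec(pat, s))[[1]]
  if (length(m) == 0 || all(!nzchar(m[-1]))) {
    gc_stop(sprintf("cannot parse duration '%s'", text), "parse")
  }
  part <- function(i) if (nzchar(m[i + 1])) as.numeric(m[i + 1]) else 0
  part(1) + part(2) / 60 + part(3) / 3600
}

#' Render hours as an h/min/s duration string
#'
#' Inverse of [parse_duration()]: re-parsing the output recovers the
#' input hours to within 1e-9 relative.
#'
#' @param hours Numeric vector of non-negative durations in hours.
#' @return Character vector like `"1 h 35 min"` or `"3 min 21 s"`.
#' @export
format_duration <- function(hours) {
  vapply(hours, function(t) {
    if (is.na(t) || t < 0) gc_stop("duration must be a non-negative number", "validation")
    h <- floor(t)
    rem_min <- (t - h) * 60
    m <- floor(rem_min)
    s <- (rem_min - m) * 60
    parts <- character(0)
    if (h > 0) parts <- c(parts, sprintf("%.0f h", h))
    if (m > 0) parts <- c(parts, sprintf("%.0f min", m))
    if (s > 1e-9 || length(parts) == 0) parts <- c(parts, sprintf("%.12g s", s))
    paste(parts, collapse = " ")
  }, character(1))
}

# Classed conditions so callers (and the CLI) can map error kinds to
# exit codes.
gc_stop <- function(msg, kind = c("validation", "lookup", "parse", "usage")) {
  kind <- match.arg(kind)
  stop(structure(
    class = c(sprintf("greencompute_%s_error", kind), "greencompute_error",
              "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}
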