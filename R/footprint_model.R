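# Core energy and carbon model.
#
# A job's energy draw is
#   E [kWh] = t * (sum_i nc_i * Pc_i * uc_i + nm * Pm) * PUE * 0.001
# with t the running time in hours, nc cores drawing Pc watts each at
# usage uc, nm GB of memory drawing Pm W/GB, and PUE the facility
# overhead. Its carbon footprint is C [kgCO2e] = E * CI with CI the
# carbon intensity of the electricity grid in kgCO2e/kWh.

#' Describe a processor allocation
#'
#' @param cores Number of cores (or GPU devices) allocated, >= 1.
#' @param power_per_core Power draw per core in W, > 0. Defaults to the
#'   registry's 12 W average CPU core.
#' @param usage Core usage factor in `[0, 1]`; 1 means fully used.
#' @param label Free-text label (`"cpu"`, `"gpu"`, ...), bookkeeping only.
#' @return A `processor_allocation` object.
#' @export
processor_allocation <- function(cores,
                                 power_per_core = gc_constants("default_core_power"),
                                 usage = gc_constants("default_usage_factor"),
                                 label = "cpu") {
  cores <- as.numeric(cores)
  if (length(cores) != 1 || is.na(cores) || cores < 1 || cores != round(cores)) {
    gc_stop("'cores' must be a single integer >= 1", "validation")
  }
  if (!is.numeric(power_per_core) || power_per_core <= 0 || !is.finite(power_per_core)) {
    gc_stop("'power_per_core' must be a positive, finite number of watts", "validation")
  }
  if (!is.numeric(usage) || usage < 0 || usage > 1) {
    gc_stop("'usage' must lie in [0, 1]", "validation")
  }
  structure(
    list(cores = as.integer(cores), power_per_core = as.numeric(power_per_core),
         usage = as.numeric(usage), label = as.character(label)),
    class = "processor_allocation"
  )
}

#' Describe a memory allocation
#'
#' Memory draws power in proportion to the amount *allocated*, not used,
#' for the whole duration of the job. When the true allocation of a
#' recorded job is unknown, set `known = FALSE`: the memory term is then
#' zero and a `memory_excluded` flag is carried into results.
#'
#' @param size_gb Memory allocated in GB, >= 0.
#' @param power_per_gb Memory power density in W/GB (default 0.3725).
#' @param known Set `FALSE` when the allocation was not reported.
#' @return A `memory_allocation` object.
#' @export
memory_allocation <- function(size_gb,
                              power_per_gb = gc_constants("memory_power_per_gb"),
                              known = TRUE) {
  if (!isTRUE(known)) size_gb <- 0
  if (!is.numeric(size_gb) || length(size_gb) != 1 || is.na(size_gb) || size_gb < 0) {
    gc_stop("'size_gb' must be a single number >= 0", "validation")
  }
  if (!is.numeric(power_per_gb) || power_per_gb <= 0) {
    gc_stop("'power_per_gb' must be > 0", "validation")
  }
  structure(
    list(size_gb = as.numeric(size_gb), power_per_gb = as.numeric(power_per_gb),
         known = isTRUE(known)),
    class = "memory_allocation"
  )
}

#' Describe the resources a job consumed
#'
#' @param duration Running time in hours (numeric) or a duration string
#'   understood by [parse_duration()].
#' @param processors A [processor_allocation()] or a list of them
#'   (heterogeneous CPU+GPU jobs sum their power terms).
#' @param memory A [memory_allocation()]; defaults to none.
#' @param duration_kind `"wall-clock"` (default) or `"core-hours"`.
#'   Aggregated benchmarks reported as total core-hours are modelled as a
#'   single core running for the full core-hour duration, so
#'   `"core-hours"` requires exactly one allocation with `cores = 1`;
#'   memory is then charged over the whole core-hour span.
#' @return A `task_resources` object.
#' @examples
#' task_resources("60 h 58 min",
#'                processor_allocation(4, power_per_core = 12),
#'                memory_allocation(100))
#' @export
task_resources <- function(duration, processors,
                           memory = memory_allocation(0),
                           duration_kind = c("wall-clock", "core-hours")) {
  duration_kind <- match.arg(duration_kind)
  if (is.character(duration)) duration <- parse_duration(duration)
  if (!is.numeric(duration) || length(duration) != 1 || is.na(duration) || duration < 0) {
    gc_stop("'duration' must be a single number of hours >= 0", "validation")
  }
  if (inherits(processors, "processor_allocation")) processors <- list(processors)
  if (!is.list(processors) || length(processors) == 0 ||
      !all(vapply(processors, inherits, logical(1), "processor_allocation"))) {
    gc_stop("'processors' must be one or more processor_allocation objects", "validation")
  }
  if (!inherits(memory, "memory_allocation")) {
    gc_stop("'memory' must be a memory_allocation object", "validation")
  }
  if (duration_kind == "core-hours" &&
      (length(processors) != 1 || processors[[1]]$cores != 1)) {
    gc_stop("core-hour durations require exactly one processor allocation with cores = 1",
            "validation")
  }
  structure(
    list(duration = as.numeric(duration), processors = processors,
         memory = memory, duration_kind = duration_kind),
    class = "task_resources"
  )
}

#' Describe where a job ran
#'
#' @param pue Power usage effectiveness, >= 1. Ignored when `facility`
#'   is given.
#' @param ci Carbon intensity in kgCO2e/kWh, >= 0. Ignored when `region`
#'   is given.
#' @param region Optional region key resolved via [get_carbon_intensity()].
#' @param facility Optional facility key resolved via [get_pue()].
#' @return A `facility_context` object.
#' @examples
#' facility_context()                      # global averages: PUE 1.67, CI 0.475
#' facility_context(facility = "google-cloud", region = "uk")
#' @export
facility_context <- function(pue = get_pue("global-average"),
                             ci = get_carbon_intensity("global"),
                             region = NULL, facility = NULL) {
  region_label <- if (is.null(region)) "custom" else canonical_key(region)
  facility_label <- if (is.null(facility)) "custom" else canonical_key(facility)
  if (!is.null(region)) ci <- get_carbon_intensity(region)
  if (!is.null(facility)) pue <- get_pue(facility)
  if (!is.numeric(pue) || pue < 1) gc_stop("'pue' must be >= 1", "validation")
  if (!is.numeric(ci) || ci < 0) gc_stop("'ci' must be >= 0", "validation")
  structure(
    list(pue = as.numeric(pue), ci = as.numeric(ci),
         region = region_label, facility = facility_label),
    class = "facility_context"
  )
}

# Active power terms in W: processors and memory.
processor_power_w <- function(resources) {
  sum(vapply(resources$processors,
             function(p) p$cores * p$power_per_core * p$usage, numeric(1)))
}

memory_power_w <- function(resources) {
  m <- resources$memory
  if (!m$known) 0 else m$size_gb * m$power_per_gb
}

#' Energy consumption of a job
#'
#' Splits the energy draw into a compute term (cores) and a memory term,
#' both inflated by the facility's PUE and converted from Wh to kWh.
#'
#' @param resources A [task_resources()] object.
#' @param facility A [facility_context()] object.
#' @return An `energy_breakdown` with `compute_kwh`, `memory_kwh`,
#'   `total_kwh` and `memory_fraction` (the share of total energy drawn
#'   by memory; 0 when the total is zero).
#' @export
compute_energy <- function(resources, facility) {
  if (!inherits(resources, "task_resources")) {
    gc_stop("'resources' must be a task_resources object", "validation")
  }
  if (!inherits(facility, "facility_context")) {
    gc_stop("'facility' must be a facility_context object", "validation")
  }
  to_kwh <- facility$pue * gc_constants("kwh_conversion")
  compute_kwh <- resources$duration * processor_power_w(resources) * to_kwh
  memory_kwh <- resources$duration * memory_power_w(resources) * to_kwh
  total <- compute_kwh + memory_kwh
  structure(
    list(compute_kwh = compute_kwh, memory_kwh = memory_kwh, total_kwh = total,
         memory_fraction = if (total > 0) memory_kwh / total else 0),
    class = "energy_breakdown"
  )
}

#' Carbon footprint of a job
#'
#' Multiplies the job's energy by the grid carbon intensity and attaches
#' contextual equivalents (tree-months of sequestration, km driven in an
#' average European car).
#'
#' @inheritParams compute_energy
#' @return A `footprint` object: `kg_co2e`, the `energy` breakdown, an
#'   `equivalents` list (see [contextualize()]) and a `memory_excluded`
#'   flag set when memory was unreported and therefore not counted.
#' @examples
#' res <- task_resources("300,000 h", processor_allocation(1, 12),
#'                       memory_allocation(8), duration_kind = "core-hours")
#' compute_footprint(res, facility_context())
#' @export
compute_footprint <- function(resources, facility) {
  energy <- compute_energy(resources, facility)
  kg <- energy$total_kwh * facility$ci
  structure(
    list(kg_co2e = kg, energy = energy, equivalents = contextualize(kg),
         facility = facility, memory_excluded = !resources$memory$known),
    class = "footprint"
  )
}

#' Share of a job's energy drawn by memory
#'
#' The fraction `f = nm*Pm / (sum nc*Pc*uc + nm*Pm)`. It is a property of
#' the power terms only: running time, PUE and carbon intensity cancel.
#'
#' @param resources A [task_resources()] object.
#' @return A fraction in `[0, 1]`.
#' @export
memory_energy_fraction <- function(resources) {
  if (!inherits(resources, "task_resources")) {
    gc_stop("'resources' must be a task_resources object", "validation")
  }
  cpu_w <- processor_power_w(resources)
  mem_w <- memory_power_w(resources)
  if (cpu_w + mem_w <= 0) {
    gc_stop("memory energy fraction is undefined when all power terms are zero",
            "validation")
  }
  mem_w / (cpu_w + mem_w)
}

#' Contextual equivalents of a carbon footprint
#'
#' Converts kgCO2e into quantities with everyday meaning: km driven in an
#' average European car (0.175 kgCO2e/km) and months of carbon
#' sequestration by a mature tree (0.917 kgCO2e/month; a tree-year is 12
#' tree-months).
#'
#' @param kg_co2e Carbon footprint in kgCO2e, >= 0 (vectorised).
#' @return A list (or tibble for vector input) with `tree_months`,
#'   `tree_years` and `car_km`, unrounded.
#' @examples
#' contextualize(3564.87)
#' @export
contextualize <- function(kg_co2e) {
  if (!is.numeric(kg_co2e) || any(is.na(kg_co2e)) || any(kg_co2e < 0)) {
    gc_stop("'kg_co2e' must be non-negative", "validation")
  }
  tm <- kg_co2e / gc_constants("tree_month_sequestration")
  out <- tibble::tibble(
    tree_months = tm,
    tree_years = tm / 12,
    car_km = kg_co2e / gc_constants("car_emission_factor")
  )
  if (length(kg_co2e) == 1) as.list(out) else out
}

#' @export
print.footprint <- function(x, ...) {
  cat(sprintf("Carbon footprint: %s kgCO2e\n", format_kg(x$kg_co2e)))
  cat(sprintf("  energy: %.4g kWh (compute %.4g, memory %.4g; memory share %.1f%%)\n",
              x$energy$total_kwh, x$energy$compute_kwh, x$energy$memory_kwh,
              100 * x$energy$memory_fraction))
  cat(sprintf("  context: PUE %.3g, CI %.3g kgCO2e/kWh\n",
              x$facility$pue, x$facility$ci))
  cat(sprintf("  equivalents: %s tree-months (%s tree-years), %s car-km\n",
              format_quantity(x$equivalents$tree_months),
              format_quantity(x$equivalents$tree_years),
              format_quantity(x$equivalents$car_km)))
  if (x$memory_excluded) {
    cat("  note: memory allocation unreported; memory energy excluded\n")
  }
  invisible(x)
}

#' @export
print.energy_breakdown <- function(x, ...) {
  cat(sprintf("Energy: %.6g kWh (compute %.6g + memory %.6g; memory share %.2f%%)\n",
              x$total_kwh, x$compute_kwh, x$memory_kwh, 100 * x$memory_fraction))
  invisible(x)
}
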