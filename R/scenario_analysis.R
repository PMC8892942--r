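# Decision analyses: memory over-allocation, parallelization trade-off,
# CPU-vs-GPU break-even, and facility/location comparison.

#' Footprint increase from over-allocating memory
#'
#' Reserving `x` extra multiples of the required memory (allocated =
#' `(1 + x) *` required) inflates a job's footprint by `100 * f * x`
#' percent, where `f` is the job's baseline memory energy fraction (see
#' [memory_energy_fraction()]). The shortcut is exact: recomputing the
#' full model with the inflated allocation gives the same percentage.
#'
#' @param f Baseline memory energy fraction, in `[0, 1)`.
#' @param xs Over-allocation factors, each >= 0 (0 = no extra memory,
#'   5 = five times the requirement reserved on top of it).
#' @return A tibble with `overallocation` and `increase_pct`.
#' @examples
#' memory_overallocation_curve(0.06, 0:5)  # MEGAHIT-like: +30% at x = 5
#' @export
memory_overallocation_curve <- function(f, xs) {
  if (!is.numeric(f) || length(f) != 1 || f < 0 || f >= 1) {
    gc_stop("'f' must be a memory energy fraction in [0, 1)", "validation")
  }
  if (!is.numeric(xs) || any(xs < 0)) {
    gc_stop("over-allocation factors must be >= 0", "validation")
  }
  tibble::tibble(overallocation = as.numeric(xs), increase_pct = 100 * f * xs)
}

#' Running-time versus footprint trade-off of parallelization
#'
#' Given measured runtimes at several core counts, computes each
#' configuration's footprint, its speedup over the baseline (smallest
#' core count present, ideally 1) and the percent change in footprint
#' relative to that baseline. With perfect scaling and no memory the
#' footprint is flat in `n`; sublinear speedups make parallel runs
#' strictly dirtier, while memory amortisation pulls the other way.
#'
#' @param series Data frame with columns `n_cores` (strictly increasing
#'   positive integers) and `runtime_hours` (> 0).
#' @param per_core_power Power per core in W.
#' @param memory A [memory_allocation()]; defaults to none.
#' @param facility A [facility_context()].
#' @param usage Core usage factor applied to every configuration.
#' @return A tibble with `n_cores`, `runtime_hours`, `kg_co2e`,
#'   `speedup` and `footprint_change_pct` (vs the baseline row).
#' @export
parallelization_tradeoff <- function(series,
                                     per_core_power = gc_constants("default_core_power"),
                                     memory = memory_allocation(0),
                                     facility = facility_context(),
                                     usage = gc_constants("default_usage_factor")) {
  if (!all(c("n_cores", "runtime_hours") %in% names(series)) || nrow(series) == 0) {
    gc_stop("'series' needs non-empty columns 'n_cores' and 'runtime_hours'",
            "validation")
  }
  if (any(series$runtime_hours <= 0)) {
    gc_stop("all runtimes must be > 0", "validation")
  }
  if (any(diff(series$n_cores) <= 0)) {
    gc_stop("'n_cores' must be strictly increasing", "validation")
  }
  if (series$n_cores[1] != 1) {
    warning("no single-core observation; using n = ", series$n_cores[1],
            " cores as baseline")
  }
  kg <- vapply(seq_len(nrow(series)), function(i) {
    res <- task_resources(series$runtime_hours[i],
                          processor_allocation(series$n_cores[i], per_core_power,
                                               usage = usage),
                          memory)
    compute_footprint(res, facility)$kg_co2e
  }, numeric(1))
  tibble::tibble(
    n_cores = as.integer(series$n_cores),
    runtime_hours = as.numeric(series$runtime_hours),
    kg_co2e = kg,
    speedup = series$runtime_hours[1] / series$runtime_hours,
    footprint_change_pct = percent_change(kg[1], kg)
  )
}

#' Break-even speedup for switching from CPU to GPU
#'
#' Returns the factor by which a job must run faster on the GPU for the
#' two configurations to emit equally: with footprints equal,
#' `t_cpu / t_gpu = (P_gpu + m) / (P_cpu + m)` where `m` is the memory
#' power term (`nm * Pm`), charged identically on both sides. The default
#' ignores memory, matching the simple power-draw-ratio approximation;
#' pass `memory` to include it (the required speedup then shrinks toward
#' 1 as memory grows, since memory dominates both sides).
#'
#' @param cpu_total_power Total CPU power in W (all cores), > 0.
#' @param gpu_total_power Total GPU power in W, > 0.
#' @param memory Optional [memory_allocation()] present on both sides.
#' @return Required speedup ratio `t_cpu / t_gpu` (>= for GPU to win).
#' @examples
#' gpu_cpu_breakeven(120, 300)  # Xeon E5-2683 (16 cores) vs Tesla V100: 2.5
#' @export
gpu_cpu_breakeven <- function(cpu_total_power, gpu_total_power, memory = NULL) {
  if (!is.numeric(cpu_total_power) || cpu_total_power <= 0 ||
      !is.numeric(gpu_total_power) || gpu_total_power <= 0) {
    gc_stop("processor powers must be > 0", "validation")
  }
  m <- 0
  if (!is.null(memory)) {
    if (!inherits(memory, "memory_allocation")) {
      gc_stop("'memory' must be a memory_allocation object", "validation")
    }
    m <- if (memory$known) memory$size_gb * memory$power_per_gb else 0
  }
  (gpu_total_power + m) / (cpu_total_power + m)
}

#' Compare a job's footprint across facilities and regions
#'
#' Rescales a baseline footprint to other locations using the identity
#' `C = e * PUE * CI`, where `e` (the pre-PUE energy) is invariant to
#' where the job runs. Percent reductions therefore depend only on the
#' `PUE * CI` products, never on the baseline's absolute scale.
#'
#' @param baseline_kg Baseline footprint in kgCO2e, > 0.
#' @param baseline_facility [facility_context()] the baseline was
#'   computed under (must have `pue * ci > 0`).
#' @param options Data frame with columns `label`, `pue`, `ci`, or a
#'   named list of [facility_context()] objects.
#' @return A tibble with `label`, `pue`, `ci`, `kg_co2e`,
#'   `change_vs_baseline_pct` and `change_vs_worst_pct` (negative values
#'   are reductions).
#' @examples
#' compare_locations(470, facility_context(),
#'                   data.frame(label = c("australia-local", "uk-google-cloud"),
#'                              pue = c(1.67, 1.11), ci = c(0.88, 0.253)))
#' @export
compare_locations <- function(baseline_kg, baseline_facility, options) {
  if (!is.numeric(baseline_kg) || baseline_kg <= 0) {
    gc_stop("'baseline_kg' must be > 0", "validation")
  }
  if (!inherits(baseline_facility, "facility_context") ||
      baseline_facility$pue * baseline_facility$ci <= 0) {
    gc_stop("baseline facility must have pue * ci > 0", "validation")
  }
  if (is.list(options) && !is.data.frame(options) &&
      all(vapply(options, inherits, logical(1), "facility_context"))) {
    options <- tibble::tibble(
      label = if (!is.null(names(options))) names(options)
              else paste0("option-", seq_along(options)),
      pue = vapply(options, `[[`, numeric(1), "pue"),
      ci = vapply(options, `[[`, numeric(1), "ci")
    )
  }
  if (!all(c("label", "pue", "ci") %in% names(options)) || nrow(options) == 0) {
    gc_stop("'options' needs non-empty columns 'label', 'pue', 'ci'", "validation")
  }
  e <- baseline_kg / (baseline_facility$pue * baseline_facility$ci)
  kg <- unname(e * as.numeric(options$pue) * as.numeric(options$ci))
  tibble::tibble(
    label = as.character(options$label),
    pue = as.numeric(options$pue),
    ci = as.numeric(options$ci),
    kg_co2e = kg,
    change_vs_baseline_pct = percent_change(baseline_kg, kg),
    change_vs_worst_pct = percent_change(max(kg), kg)
  )
}
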