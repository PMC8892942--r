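# Synthetic task descriptors and scaling series with known ground truth,
# so every analysis stage is testable without external downloads.

#' Default sampling ranges for synthetic tasks
#'
#' The defaults span the ranges observed across the shipped benchmark
#' catalog and reference tables: runtimes from seconds to hundreds of
#' thousands of core-hours, memory from 0.05 to 262 GB, per-core powers
#' of 8-20 W, PUE 1.1-1.7 and carbon intensities from the Swiss to the
#' Australian grid. Runtime, memory and CI span several orders of
#' magnitude and are sampled log-uniformly; cores, power, usage and PUE
#' uniformly.
#'
#' @return A named list of `c(low, high)` bounds.
#' @export
default_task_ranges <- function() {
  list(
    runtime_hours = c(0.002, 4e5),
    cores = c(1, 64),
    power_per_core = c(8, 20),
    memory_gb = c(0.05, 262),
    usage = c(1, 1),
    pue = c(1.1, 1.7),
    ci = c(0.012, 0.88)
  )
}

#' Specification for the synthetic task generator
#'
#' @param seed Integer seed; generation is deterministic given the seed
#'   (Mersenne-Twister, R's default RNG).
#' @param n Number of tasks to generate, >= 0.
#' @param ranges Named list of `c(low, high)` bounds; see
#'   [default_task_ranges()]. Partial lists override the defaults.
#' @return A `generator_spec` object.
#' @export
generator_spec <- function(seed, n, ranges = list()) {
  if (!is.numeric(seed) || length(seed) != 1 || is.na(seed)) {
    gc_stop("'seed' must be a single integer", "validation")
  }
  if (!is.numeric(n) || length(n) != 1 || is.na(n) || n < 0 || n != round(n)) {
    gc_stop("'n' must be a single integer >= 0", "validation")
  }
  full <- utils::modifyList(default_task_ranges(), ranges)
  for (nm in names(full)) {
    r <- full[[nm]]
    if (length(r) != 2 || any(!is.finite(r)) || any(r <= 0) || r[1] > r[2]) {
      gc_stop(sprintf("range '%s' must be positive finite bounds with low <= high", nm),
              "validation")
    }
  }
  structure(list(seed = as.integer(seed), n = as.integer(n), ranges = full),
            class = "generator_spec")
}

runif_log <- function(n, low, high) exp(stats::runif(n, log(low), log(high)))

#' Generate synthetic task descriptors
#'
#' Draws `n` task/facility pairs with every field inside its configured
#' range. Sampling does not disturb the caller's RNG state.
#'
#' @param spec A [generator_spec()].
#' @return A tibble with one row per task: `task_id`, `runtime_hours`,
#'   `cores`, `power_per_core`, `usage`, `memory_gb`, `pue`, `ci`. Use
#'   [synthetic_task()] to turn a row into model inputs, or
#'   [synthetic_catalog()] to emit the catalog format.
#' @export
generate_tasks <- function(spec) {
  if (!inherits(spec, "generator_spec")) {
    gc_stop("'spec' must come from generator_spec()", "validation")
  }
  n <- spec$n
  r <- spec$ranges
  draw <- function() {
    tibble::tibble(
      task_id = sprintf("synthetic-%04d", seq_len(n)),
      runtime_hours = runif_log(n, r$runtime_hours[1], r$runtime_hours[2]),
      cores = as.integer(floor(stats::runif(n, r$cores[1], r$cores[2] + 1))),
      power_per_core = stats::runif(n, r$power_per_core[1], r$power_per_core[2]),
      usage = stats::runif(n, r$usage[1], r$usage[2]),
      memory_gb = runif_log(n, r$memory_gb[1], r$memory_gb[2]),
      pue = stats::runif(n, r$pue[1], r$pue[2]),
      ci = runif_log(n, r$ci[1], r$ci[2])
    )
  }
  if (n == 0) {
    out <- draw()[0, ]
  } else {
    out <- with_preserved_seed(spec$seed, draw())
    out$cores <- pmin(out$cores, as.integer(r$cores[2]))
  }
  out
}

with_preserved_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed, kind = "Mersenne-Twister")
  expr
}

#' Model inputs for one generated task
#'
#' @param row A single row of [generate_tasks()] output.
#' @return A list with `resources` ([task_resources()]) and `facility`
#'   ([facility_context()]).
#' @export
synthetic_task <- function(row) {
  if (nrow(row) != 1) gc_stop("'row' must be a single task row", "validation")
  list(
    resources = task_resources(
      row$runtime_hours,
      processor_allocation(row$cores, row$power_per_core, usage = row$usage),
      memory_allocation(row$memory_gb)
    ),
    facility = facility_context(pue = row$pue, ci = row$ci)
  )
}

#' Express generated tasks in the catalog schema
#'
#' Builds catalog rows whose printed footprints are the model's own
#' outputs, with full hardware fields (`hardware_provenance =
#' "synthetic"`). Writing with [write_catalog()] and reloading
#' reproduces the footprints.
#'
#' @param tasks Output of [generate_tasks()].
#' @return A catalog tibble.
#' @export
synthetic_catalog <- function(tasks) {
  n <- nrow(tasks)
  kg <- numeric(n)
  for (i in seq_len(n)) {
    st <- synthetic_task(tasks[i, ])
    kg[i] <- compute_footprint(st$resources, st$facility)$kg_co2e
  }
  eq <- contextualize(if (n == 1) kg else kg)
  eq <- tibble::as_tibble(eq)
  tibble::tibble(
    task_group = "synthetic",
    tool = tasks$task_id,
    version = "",
    experiment = "synthetic task",
    runtime = sprintf("%.15g h", tasks$runtime_hours),
    runtime_max = "",
    runtime_kind = "wall-clock",
    memory_gb = tasks$memory_gb,
    memory_gb_max = NA_real_,
    memory_known = TRUE,
    cores = as.numeric(tasks$cores),
    power_per_core = tasks$power_per_core * tasks$usage,
    pue = tasks$pue,
    ci = tasks$ci,
    printed_kg = kg,
    printed_kg_max = NA_real_,
    printed_tree_months = eq$tree_months,
    printed_tree_months_max = NA_real_,
    printed_km = eq$car_km,
    printed_km_max = NA_real_,
    printed_increase_pct = NA_real_,
    scaling = "",
    hardware_provenance = "synthetic"
  )
}

#' Generate a synthetic footprint-versus-size series
#'
#' Points follow `kg = base_kg * (size / reference)^exponent` under the
#' given scaling law, optionally perturbed by multiplicative log-normal
#' noise (footprints are positive and span decades, so noise is relative,
#' not additive).
#'
#' @param model A [scaling_model()].
#' @param base_kg Footprint at the model's reference size, > 0.
#' @param sizes Positive sizes at which to evaluate.
#' @param noise_sd Standard deviation of the log-normal noise on the log
#'   scale; 0 gives the exact law.
#' @param seed Integer seed (only used when `noise_sd > 0`).
#' @return A tibble with `size` and `kg_co2e`.
#' @export
generate_scaling_series <- function(model, base_kg, sizes, noise_sd = 0,
                                    seed = 1) {
  if (!inherits(model, "scaling_model")) {
    gc_stop("'model' must be a scaling_model object", "validation")
  }
  if (!is.numeric(base_kg) || base_kg <= 0) gc_stop("'base_kg' must be > 0", "validation")
  if (!is.numeric(sizes) || length(sizes) == 0 || any(sizes <= 0)) {
    gc_stop("'sizes' must be positive", "validation")
  }
  if (!is.numeric(noise_sd) || noise_sd < 0) gc_stop("'noise_sd' must be >= 0", "validation")
  kg <- extrapolate_footprint(base_kg, model, sizes)
  if (noise_sd > 0) {
    noise <- with_preserved_seed(seed, stats::rnorm(length(sizes), 0, noise_sd))
    kg <- kg * exp(noise)
  }
  tibble::tibble(size = as.numeric(sizes), kg_co2e = kg)
}
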