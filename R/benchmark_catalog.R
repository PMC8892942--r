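# The benchmark catalog: a CSV of published bioinformatic workload
# benchmarks (task, tool, runtime, memory, printed footprint and
# contextual equivalents), with validation, reproduction of rows whose
# hardware is fully specified, and rebuilding of the relative
# increase-versus-best-tool column.

catalog_columns <- c(
  "task_group", "tool", "version", "experiment", "runtime", "runtime_max",
  "runtime_kind", "memory_gb", "memory_gb_max", "memory_known", "cores",
  "power_per_core", "pue", "ci", "printed_kg", "printed_kg_max",
  "printed_tree_months", "printed_tree_months_max", "printed_km",
  "printed_km_max", "printed_increase_pct", "scaling", "hardware_provenance"
)

catalog_numeric_cols <- c(
  "memory_gb", "memory_gb_max", "cores", "power_per_core", "pue", "ci",
  "printed_kg", "printed_kg_max", "printed_tree_months",
  "printed_tree_months_max", "printed_km", "printed_km_max",
  "printed_increase_pct"
)

#' Path to the bundled benchmark catalog
#' @return File path of the shipped catalog CSV.
#' @export
catalog_path <- function() {
  system.file("extdata", "benchmark_catalog.csv", package = "greencompute")
}

#' Load and validate a benchmark catalog
#'
#' The catalog is a CSV with a schema-version comment line
#' (`# greencompute catalog v1`) followed by a fixed column set. Range
#' entries (footprints reported as min-max) populate the `*_max`
#' columns. Rows whose hardware is fully stated in the primary record
#' carry `hardware_provenance = "primary"` and can be reproduced; rows
#' whose hardware lives in supplementary records ship with empty
#' hardware fields that users may fill in.
#'
#' @param path Catalog CSV; defaults to the bundled transcription.
#' @return A tibble of validated entries with an extra `runtime_hours`
#'   column (parsed from the runtime text).
#' @export
load_catalog <- function(path = catalog_path()) {
  if (!file.exists(path)) {
    gc_stop(sprintf("catalog file not found: '%s'", path), "lookup")
  }
  first <- readLines(path, n = 1)
  if (!grepl("^# greencompute catalog v[0-9]+$", first)) {
    gc_stop("catalog file lacks the '# greencompute catalog v<N>' header line",
            "validation")
  }
  raw <- utils::read.csv(path, comment.char = "#", colClasses = "character",
                         check.names = FALSE)
  if (nrow(raw) == 0) gc_stop("catalog contains no rows", "validation")
  missing <- setdiff(catalog_columns, names(raw))
  if (length(missing) > 0) {
    gc_stop(sprintf("catalog is missing columns: %s",
                    paste(missing, collapse = ", ")), "validation")
  }
  cat_tbl <- tibble::as_tibble(raw[, catalog_columns])
  for (col in catalog_numeric_cols) {
    vals <- suppressWarnings(as.numeric(cat_tbl[[col]]))
    bad <- which(nzchar(cat_tbl[[col]]) & is.na(vals))
    if (length(bad) > 0) {
      gc_stop(sprintf("row %d: column '%s' value '%s' is not numeric",
                      bad[1], col, cat_tbl[[col]][bad[1]]), "validation")
    }
    cat_tbl[[col]] <- vals
  }
  cat_tbl$memory_known <- tolower(cat_tbl$memory_known) %in% c("true", "t", "1", "yes")

  cat_tbl$runtime_hours <- NA_real_
  for (i in seq_len(nrow(cat_tbl))) {
    row <- cat_tbl[i, ]
    hours <- tryCatch(parse_duration(row$runtime), error = function(e) {
      gc_stop(sprintf("row %d (%s): unparseable runtime '%s'",
                      i, row$tool, row$runtime), "validation")
    })
    if (hours <= 0) {
      gc_stop(sprintf("row %d (%s): runtime must be positive, got '%s'",
                      i, row$tool, row$runtime), "validation")
    }
    cat_tbl$runtime_hours[i] <- hours
    if (!row$runtime_kind %in% c("wall-clock", "core-hours")) {
      gc_stop(sprintf("row %d (%s): runtime_kind must be wall-clock or core-hours",
                      i, row$tool), "validation")
    }
    for (col in c("memory_gb", "printed_kg", "printed_tree_months", "printed_km")) {
      v <- row[[col]]
      if (!is.na(v) && v < 0) {
        gc_stop(sprintf("row %d (%s): negative %s", i, row$tool, col), "validation")
      }
    }
    if (is.na(row$printed_kg)) {
      gc_stop(sprintf("row %d (%s): missing printed_kg", i, row$tool), "validation")
    }
    if (!row$hardware_provenance %in% c("primary", "supplementary", "absent", "synthetic")) {
      gc_stop(sprintf("row %d (%s): unknown hardware_provenance '%s'",
                      i, row$tool, row$hardware_provenance), "validation")
    }
    if (row$hardware_provenance == "primary" &&
        (is.na(row$cores) || is.na(row$power_per_core))) {
      gc_stop(sprintf("row %d (%s): primary hardware rows need cores and power_per_core",
                      i, row$tool), "validation")
    }
    if (nzchar(row$scaling)) parse_scaling(row$scaling)  # validates syntax
  }
  class(cat_tbl) <- c("benchmark_catalog", class(cat_tbl))
  cat_tbl
}

#' Write a catalog to CSV
#'
#' Emits the schema-version header line and the fixed column set, so the
#' file round-trips through [load_catalog()].
#'
#' @param catalog A catalog tibble.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_catalog <- function(catalog, path) {
  out <- as.data.frame(catalog)[, catalog_columns]
  out$memory_known <- ifelse(out$memory_known, "true", "false")
  for (col in catalog_numeric_cols) {
    out[[col]] <- ifelse(is.na(out[[col]]), "",
                         formatC(out[[col]], format = "g", digits = 15))
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# greencompute catalog v1", con)
  utils::write.csv(out, con, row.names = FALSE, quote = which(
    catalog_columns %in% c("task_group", "tool", "version", "experiment",
                           "runtime", "runtime_max", "scaling")))
  invisible(path)
}

entry_to_task <- function(entry) {
  procs <- processor_allocation(
    cores = entry$cores,
    power_per_core = entry$power_per_core,
    usage = gc_constants("default_usage_factor")
  )
  mem <- if (entry$memory_known && !is.na(entry$memory_gb)) {
    memory_allocation(entry$memory_gb)
  } else {
    memory_allocation(0, known = FALSE)
  }
  task_resources(entry$runtime_hours, procs, mem,
                 duration_kind = entry$runtime_kind)
}

#' Recompute catalog footprints and compare with the printed values
#'
#' Rows are reproducible only when their hardware fields (`cores`,
#' `power_per_core`) are populated; other rows are reported with
#' `reproducible = FALSE`, never an error. Computation uses the row's
#' own PUE and CI.
#'
#' @param catalog A catalog tibble from [load_catalog()], or a subset of
#'   its rows.
#' @return A tibble with `task_group`, `tool`, `printed_kg`,
#'   `computed_kg`, `deviation` (relative, computed vs printed) and
#'   `reproducible`.
#' @export
reproduce_catalog <- function(catalog = load_catalog()) {
  n <- nrow(catalog)
  computed <- rep(NA_real_, n)
  ok <- rep(FALSE, n)
  for (i in seq_len(n)) {
    entry <- catalog[i, ]
    if (is.na(entry$cores) || is.na(entry$power_per_core) ||
        !is.na(entry$printed_kg_max)) {
      next
    }
    fac <- facility_context(pue = entry$pue, ci = entry$ci)
    computed[i] <- compute_footprint(entry_to_task(entry), fac)$kg_co2e
    ok[i] <- TRUE
  }
  tibble::tibble(
    task_group = catalog$task_group,
    tool = catalog$tool,
    version = catalog$version,
    printed_kg = catalog$printed_kg,
    computed_kg = computed,
    deviation = (computed - catalog$printed_kg) / catalog$printed_kg,
    reproducible = ok
  )
}

#' Recompute one catalog entry
#'
#' @param entry A single catalog row.
#' @return One row of the [reproduce_catalog()] report.
#' @export
reproduce_entry <- function(entry) {
  if (nrow(entry) != 1) gc_stop("'entry' must be a single catalog row", "validation")
  reproduce_catalog(entry)
}

#' Rebuild the increase-versus-best-tool column
#'
#' Within each task group, the tool with the lowest printed footprint is
#' the baseline (increase `NA`, displayed as an em dash) and every other
#' row gets `percent_change(baseline, row)`. Rebuilt values are compared
#' against the printed column where present: because the printed
#' percentages were derived from unrounded internal footprints while the
#' rebuild starts from the rounded printed ones, they can differ; rows
#' outside the tolerance are flagged in `matches_printed`, never
#' silently dropped. Range entries (min-max footprints) are excluded.
#'
#' @param catalog A catalog tibble.
#' @param tolerance_pp Absolute tolerance in percentage points.
#' @param tolerance_rel Relative tolerance on large percentages. A row
#'   matches when the discrepancy is within either tolerance.
#' @return A tibble with `task_group`, `tool`, `printed_kg`,
#'   `rebuilt_increase_pct`, `printed_increase_pct`, `is_baseline`,
#'   `matches_printed`.
#' @export
rebuild_increase_columns <- function(catalog = load_catalog(),
                                     tolerance_pp = 2, tolerance_rel = 0.02) {
  cat_tbl <- catalog[is.na(catalog$printed_kg_max), ]
  if (nrow(cat_tbl) == 0) gc_stop("no non-range rows to rebuild", "validation")
  if (any(tapply(cat_tbl$printed_kg, cat_tbl$task_group, max) <= 0)) {
    gc_stop("a task group contains only zero footprints", "validation")
  }
  groups <- split(seq_len(nrow(cat_tbl)), cat_tbl$task_group)
  rebuilt <- rep(NA_real_, nrow(cat_tbl))
  baseline <- rep(FALSE, nrow(cat_tbl))
  for (idx in groups) {
    b <- idx[which.min(cat_tbl$printed_kg[idx])]
    baseline[b] <- TRUE
    others <- setdiff(idx, b)
    rebuilt[others] <- percent_change(cat_tbl$printed_kg[b],
                                      cat_tbl$printed_kg[others])
  }
  printed <- cat_tbl$printed_increase_pct
  diff_pp <- abs(rebuilt - printed)
  matches <- ifelse(is.na(printed) | is.na(rebuilt), NA,
                    diff_pp <= pmax(tolerance_pp, tolerance_rel * abs(printed)))
  tibble::tibble(
    task_group = cat_tbl$task_group,
    tool = cat_tbl$tool,
    version = cat_tbl$version,
    printed_kg = cat_tbl$printed_kg,
    rebuilt_increase_pct = rebuilt,
    printed_increase_pct = printed,
    is_baseline = baseline,
    matches_printed = matches
  )
}
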