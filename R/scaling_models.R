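# Per-unit normalisation of footprints and extrapolation across input
# sizes using stated runtime scaling laws (linear in reads/variants,
# power laws in loci or sample size).

#' Declare a scaling law
#'
#' @param kind `"linear"` or `"power-law"`.
#' @param exponent Scaling exponent, > 0. Forced to 1 for linear laws.
#' @param unit Unit of the size axis (`"reads"`, `"million variants"`,
#'   `"Gb"`, `"samples"`, `"loci"`, ...). Bookkeeping only; sizes passed
#'   to [extrapolate_footprint()] must be in this unit.
#' @param reference_size Size at which a known footprint was measured, > 0.
#' @return A `scaling_model` object.
#' @examples
#' scaling_model("power-law", exponent = 1.5, unit = "samples",
#'               reference_size = 5e5)
#' @export
scaling_model <- function(kind = c("linear", "power-law"), exponent = 1,
                          unit = "units", reference_size = 1) {
  kind <- match.arg(kind)
  if (kind == "linear") exponent <- 1
  if (!is.numeric(exponent) || exponent <= 0) {
    gc_stop("'exponent' must be > 0", "validation")
  }
  if (!is.numeric(reference_size) || reference_size <= 0) {
    gc_stop("'reference_size' must be > 0", "validation")
  }
  structure(
    list(kind = kind, exponent = as.numeric(exponent), unit = as.character(unit),
         reference_size = as.numeric(reference_size)),
    class = "scaling_model"
  )
}

#' Parse a scaling declaration string
#'
#' Catalog rows declare scaling laws compactly: `"linear:reads"` or
#' `"power:1.5:samples"`.
#'
#' @param text Declaration string.
#' @param reference_size Reference size attached to the parsed model.
#' @return A [scaling_model()], or `NULL` for empty/missing text.
#' @export
parse_scaling <- function(text, reference_size = 1) {
  if (length(text) != 1 || is.na(text) || !nzchar(trimws(text))) return(NULL)
  parts <- strsplit(trimws(text), ":", fixed = TRUE)[[1]]
  if (parts[1] == "linear" && length(parts) == 2) {
    scaling_model("linear", unit = parts[2], reference_size = reference_size)
  } else if (parts[1] == "power" && length(parts) == 3) {
    scaling_model("power-law", exponent = as.numeric(parts[2]), unit = parts[3],
                  reference_size = reference_size)
  } else {
    gc_stop(sprintf("cannot parse scaling declaration '%s'", text), "parse")
  }
}

#' Footprint per unit of work
#'
#' @param kg_co2e Footprint in kgCO2e, >= 0.
#' @param size Amount of work it covered, > 0, in `unit`.
#' @param unit Unit label carried into the result (use scaled units such
#'   as `"million variants"` to avoid 1e6 bookkeeping mistakes).
#' @return A tibble with `per_unit_kg` and `unit`.
#' @examples
#' per_unit_footprint(4.70, 93, "million variants")  # 0.0505 kg per M variants
#' @export
per_unit_footprint <- function(kg_co2e, size, unit = "units") {
  if (!is.numeric(kg_co2e) || any(kg_co2e < 0)) {
    gc_stop("'kg_co2e' must be >= 0", "validation")
  }
  if (!is.numeric(size) || any(size <= 0)) {
    gc_stop("'size' must be > 0", "validation")
  }
  tibble::tibble(per_unit_kg = kg_co2e / size, unit = paste("per", unit))
}

#' Extrapolate a footprint to a different input size
#'
#' Applies `C' = C * (target_size / reference_size)^exponent`, i.e. the
#' footprint follows the task's runtime scaling law.
#'
#' @param kg_co2e Footprint at the model's reference size, >= 0.
#' @param model A [scaling_model()].
#' @param target_size Size to extrapolate to, > 0, in the model's unit.
#' @return Extrapolated footprint in kgCO2e.
#' @examples
#' m <- scaling_model("power-law", 1.5, "samples", reference_size = 5e5)
#' extrapolate_footprint(4.70, m, 1.25e5)  # quarter the samples: 0.25^1.5
#' @export
extrapolate_footprint <- function(kg_co2e, model, target_size) {
  if (!inherits(model, "scaling_model")) {
    gc_stop("'model' must be a scaling_model object", "validation")
  }
  if (!is.numeric(kg_co2e) || any(kg_co2e < 0)) {
    gc_stop("'kg_co2e' must be >= 0", "validation")
  }
  if (!is.numeric(target_size) || any(target_size <= 0)) {
    gc_stop("'target_size' must be > 0", "validation")
  }
  kg_co2e * (target_size / model$reference_size)^model$exponent
}

#' Mean per-tool ratio of per-unit footprints between two conditions
#'
#' For each tool present in both groups, forms the ratio of its per-unit
#' footprint in group A over group B, then averages the per-tool ratios
#' arithmetically (not the ratio of group means). Used, e.g., to compare
#' long-read versus short-read assembly cost per million reads.
#'
#' @param group_a,group_b Data frames with columns `tool`, `kg_co2e`,
#'   `size` (> 0). Both must contain the same tool set.
#' @return List with the overall `mean_ratio` and a tibble of `per_tool`
#'   ratios.
#' @export
mean_per_tool_ratio <- function(group_a, group_b) {
  for (g in list(group_a, group_b)) {
    if (!all(c("tool", "kg_co2e", "size") %in% names(g))) {
      gc_stop("groups need columns 'tool', 'kg_co2e', 'size'", "validation")
    }
    if (any(g$size <= 0)) gc_stop("all sizes must be > 0", "validation")
  }
  if (!setequal(group_a$tool, group_b$tool) ||
      anyDuplicated(group_a$tool) || anyDuplicated(group_b$tool)) {
    gc_stop("groups must contain the same tools, once each", "validation")
  }
  b <- group_b[match(group_a$tool, group_b$tool), ]
  per_tool <- tibble::tibble(
    tool = group_a$tool,
    ratio = (group_a$kg_co2e / group_a$size) / (b$kg_co2e / b$size)
  )
  list(mean_ratio = mean(per_tool$ratio), per_tool = per_tool)
}

#' Signed percentage change relative to a reference
#'
#' @param reference Reference value, > 0.
#' @param other Value compared against the reference (vectorised).
#' @return `100 * (other - reference) / reference`.
#' @examples
#' percent_change(4.70, 17.29)  # +267.9
#' @export
percent_change <- function(reference, other) {
  if (!is.numeric(reference) || any(reference <= 0)) {
    gc_stop("'reference' must be > 0", "validation")
  }
  100 * (other - reference) / reference
}

#' Fit a scaling exponent from (size, footprint) observations
#'
#' Ordinary least squares on the log-log scale; under the model
#' `C = k * size^alpha` the slope estimates alpha.
#'
#' @param sizes,kg_co2e Positive numeric vectors of equal length >= 2.
#' @return List with `exponent`, its `std_error` and the intercept `log_k`.
#' @export
fit_scaling_exponent <- function(sizes, kg_co2e) {
  if (length(sizes) != length(kg_co2e) || length(sizes) < 2) {
    gc_stop("need at least two (size, kg) pairs of equal length", "validation")
  }
  if (any(sizes <= 0) || any(kg_co2e <= 0)) {
    gc_stop("sizes and footprints must be > 0 for a log-log fit", "validation")
  }
  fit <- stats::lm(log(kg_co2e) ~ log(sizes))
  # summary.lm warns on noise-free series (a perfect fit); that is the
  # expected case for exact generated laws, not a problem
  coefs <- suppressWarnings(summary(fit))$coefficients
  list(exponent = unname(coefs[2, 1]),
       std_error = unname(coefs[2, 2]),
       log_k = unname(coefs[1, 1]))
}
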