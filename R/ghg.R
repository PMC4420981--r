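#' Dietary greenhouse-gas emissions of a diet
#'
#' Multiplies per-group consumption (g/day) by life-cycle GHG intensity
#' (kgCO2e/g) for the requested variant and sums. Emissions are linear in
#' the diet, so convex combinations of diets yield the same combination of
#' their emissions.
#'
#' @param x Diet vector (g/day) in food-table row order, or `NULL` to use
#'   the table's baseline `consumption_g`.
#' @param food_table Food table rows for one sex (filter with `sex` if needed).
#' @param variant `"low"`, `"central"` or `"high"` intensity variant.
#' @param sex Optional sex label to filter a multi-sex table.
#' @return A list with class `emissions_result`: `total` (kgCO2e/day),
#'   `by_group` (named vector) and `variant`.
#' @export
diet_emissions <- function(x = NULL, food_table, variant = "central",
                           sex = NULL) {
  tb <- filter_sex(food_table, sex)
  g <- tb[[paste0("ghg_", variant)]]
  if (is.null(g)) abort(paste0("unknown GHG variant `", variant, "`."))
  x <- x %||% tb$consumption_g
  if (length(x) != nrow(tb)) abort("`x` does not match the food table rows.")
  if (any(x < 0)) abort("diet vector must be non-negative.")
  by_group <- setNames(x * g, tb$group_id)
  structure(list(total = sum(by_group), by_group = by_group,
                 variant = variant),
            class = "emissions_result")
}

#' Achieved fractional GHG reduction between two diets
#'
#' `1 - scenario/baseline` on total emissions; negative when the scenario
#' emits more. Both results must be computed under the same intensity
#' variant.
#'
#' @param baseline,scenario `emissions_result` objects from
#'   [diet_emissions()].
#' @return A single fraction.
#' @export
achieved_reduction <- function(baseline, scenario) {
  stopifnot(inherits(baseline, "emissions_result"),
            inherits(scenario, "emissions_result"))
  if (!identical(baseline$variant, scenario$variant))
    abort("baseline and scenario use different GHG intensity variants.")
  if (baseline$total <= 0) abort("baseline emissions must be positive.")
  1 - scenario$total / baseline$total
}

#' @export
print.emissions_result <- function(x, ...) {
  cat("<emissions_result> total ", format(x$total, digits = 4),
      " kgCO2e/day (", x$variant, " variant, ", length(x$by_group),
      " groups)\n", sep = "")
  invisible(x)
}
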