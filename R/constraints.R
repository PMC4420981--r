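#' Nutrient constraint sets
#'
#' A `nutrient_constraints` object holds per-nutrient daily-intake bounds
#' plus two structural equalities: total energy fixed at its baseline value
#' and the liquid fraction of diet mass fixed at baseline. Bounds can be in
#' absolute units (the unit of the corresponding per-gram composition column
#' times g/day) or as a fraction of total energy (`unit = "pct_energy"`,
#' which needs `kcal_per_g` to convert the nutrient's grams to kcal).
#'
#' @param nutrients A tibble with columns `nutrient`, `unit` (`"absolute"` or
#'   `"pct_energy"`), `lower`, `upper` (use `NA` for absent bounds) and
#'   `kcal_per_g` (`NA` unless `unit == "pct_energy"`).
#' @param energy_equality Keep total energy at its baseline value.
#' @param liquid_equality Keep the liquid share of diet mass at baseline.
#' @param energy_nutrient Name of the composition column holding energy
#'   density (kcal/g).
#' @return A list with class `nutrient_constraints`.
#' @export
nutrient_constraints <- function(nutrients,
                                 energy_equality = TRUE,
                                 liquid_equality = TRUE,
                                 energy_nutrient = "energy_kcal") {
  nutrients <- tibble::as_tibble(nutrients)
  need <- c("nutrient", "unit", "lower", "upper")
  miss <- setdiff(need, names(nutrients))
  if (length(miss)) abort(paste("constraint table is missing columns:",
                                paste(miss, collapse = ", ")))
  if (!"kcal_per_g" %in% names(nutrients)) nutrients$kcal_per_g <- NA_real_
  bad <- !is.na(nutrients$lower) & !is.na(nutrients$upper) &
    nutrients$lower > nutrients$upper
  if (any(bad)) abort("lower bound exceeds upper bound for some nutrient.")
  if (any(nutrients$unit == "pct_energy" & is.na(nutrients$kcal_per_g)))
    abort("`kcal_per_g` is required for pct_energy constraints.")
  structure(list(nutrients = nutrients,
                 energy_equality = isTRUE(energy_equality),
                 liquid_equality = isTRUE(liquid_equality),
                 energy_nutrient = energy_nutrient),
            class = "nutrient_constraints")
}

#' Default nutrition-recommendation constraint set
#'
#' An editable default inspired by population intake goals of the kind
#' issued by the WHO: energy shares of total fat <= 30% and saturated fat
#' <= 10% and free sugars <= 10%; fibre >= 25 g/day; sodium <= 2000 mg/day;
#' combined fruit and vegetables >= 400 g/day (expressed through the
#' `fruitveg_g` indicator column of the food table). These are configurable
#' defaults, not an authoritative transcription of any guideline document.
#'
#' @return A [nutrient_constraints()] object.
#' @export
#' @examples
#' cons <- who_constraints()
#' cons$nutrients
who_constraints <- function() {
  nutrient_constraints(tibble::tribble(
    ~nutrient,       ~unit,         ~lower, ~upper, ~kcal_per_g,
    "fat_g",         "pct_energy",  NA,     0.30,   9,
    "satfat_g",      "pct_energy",  NA,     0.10,   9,
    "free_sugar_g",  "pct_energy",  NA,     0.10,   4,
    "fibre_g",       "absolute",    25,     NA,     NA,
    "sodium_mg",     "absolute",    NA,     2000,   NA,
    "fruitveg_g",    "absolute",    400,    NA,     NA
  ))
}

#' Read / write a constraint set as YAML
#'
#' @param path File path.
#' @return `read_constraints()` returns a [nutrient_constraints()] object;
#'   `write_constraints()` invisibly returns `path`.
#' @export
read_constraints <- function(path) {
  y <- yaml::read_yaml(path)
  nut <- purrr::map(y$nutrients, function(r) {
    tibble::tibble(nutrient = r$nutrient,
                   unit = r$unit %||% "absolute",
                   lower = as.numeric(r$lower %||% NA),
                   upper = as.numeric(r$upper %||% NA),
                   kcal_per_g = as.numeric(r$kcal_per_g %||% NA))
  })
  nutrient_constraints(dplyr::bind_rows(nut),
                       energy_equality = y$energy_equality %||% TRUE,
                       liquid_equality = y$liquid_equality %||% TRUE,
                       energy_nutrient = y$energy_nutrient %||% "energy_kcal")
}

#' @rdname read_constraints
#' @param cons A [nutrient_constraints()] object.
#' @export
write_constraints <- function(cons, path) {
  stopifnot(inherits(cons, "nutrient_constraints"))
  rows <- purrr::pmap(cons$nutrients, function(nutrient, unit, lower, upper,
                                               kcal_per_g, ...) {
    r <- list(nutrient = nutrient, unit = unit)
    if (!is.na(lower)) r$lower <- lower
    if (!is.na(upper)) r$upper <- upper
    if (!is.na(kcal_per_g)) r$kcal_per_g <- kcal_per_g
    r
  })
  yaml::write_yaml(list(nutrients = rows,
                        energy_equality = cons$energy_equality,
                        liquid_equality = cons$liquid_equality,
                        energy_nutrient = cons$energy_nutrient), path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
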