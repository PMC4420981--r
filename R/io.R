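#' Read / write pipeline tables as CSV
#'
#' Plain-CSV persistence for the food-group and population tables with
#' light validation on read. Column layouts match the generators:
#' see [generate_food_table()] and [generate_population_table()].
#'
#' @param path File path.
#' @return Readers return validated tibbles; writers invisibly return
#'   `path`.
#' @export
read_food_table <- function(path) {
  tb <- readr::read_csv(path, show_col_types = FALSE)
  need <- c("sex", "group_id", "exposure", "liquid", "consumption_g",
            "ghg_central", "elasticity", "share")
  miss <- setdiff(need, names(tb))
  if (length(miss)) abort(paste("food table is missing columns:",
                                paste(miss, collapse = ", ")))
  if (any(tb$consumption_g <= 0))
    abort("baseline consumption must be strictly positive.")
  tb
}

#' @rdname read_food_table
#' @param food_table A food-group tibble.
#' @export
write_food_table <- function(food_table, path) {
  readr::write_csv(food_table, path)
  invisible(path)
}

#' @rdname read_food_table
#' @export
read_population_table <- function(path) {
  tb <- readr::read_csv(path, show_col_types = FALSE)
  need <- c("sex", "age", "population", "all_cause")
  miss <- setdiff(need, names(tb))
  if (length(miss)) abort(paste("population table is missing columns:",
                                paste(miss, collapse = ", ")))
  if (any(tb$all_cause < 0) || any(tb$all_cause > 1))
    abort("all-cause mortality rates must lie in [0, 1].")
  tb
}

#' @rdname read_food_table
#' @param pop A population tibble.
#' @export
write_population_table <- function(pop, path) {
  readr::write_csv(pop, path)
  invisible(path)
}
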