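#' Run the full scenario sweep over a ladder of GHG targets
#'
#' For each target (with `NA` meaning "no GHG target": nutrition-only
#' optimisation whose incidental emission reduction is reported) and each
#' sex: optimise the diet, compute achieved emissions reduction, derive
#' exposure changes, convert them to per-disease hazard multipliers and
#' project YLL averted and life-expectancy change. Failures at any stage
#' are recorded against their target, never silently dropped.
#'
#' @param food_table Per-sex food table (see [generate_food_table()]).
#' @param cons A [nutrient_constraints()] object.
#' @param erfs ERF tibble (see [generate_erf_table()]).
#' @param pop Population table (see [generate_population_table()]).
#' @param targets Fractional GHG reduction targets; `NA` for the no-target
#'   scenario. Default `c(NA, 0.1, 0.2, 0.3, 0.4, 0.5, 0.6)`.
#' @param variant GHG intensity variant used in optimisation and accounting.
#' @param rr_which RR estimate used for multipliers (`"central"`, `"low"`,
#'   `"high"`; see [scale_rr()]).
#' @param mask_exposures Exposure tags whose health effects are ignored
#'   (structural sensitivity).
#' @param horizons YLL accumulation horizons in years.
#' @param lags Named list of [lag_function()]s; defaults to
#'   [default_lags()] on the ERF diseases.
#' @param ... Passed to [optimise_diet()].
#' @return A `diet_sweep` object; `tidy()` gives the per-target summary,
#'   `autoplot()` plots YLL and the deviation index against the target.
#' @export
run_sweep <- function(food_table, cons, erfs, pop,
                      targets = c(NA, 0.1, 0.2, 0.3, 0.4, 0.5, 0.6),
                      variant = "central", rr_which = "central",
                      mask_exposures = character(0),
                      horizons = c(20, 30), lags = NULL, ...) {
  validate_erf_table(erfs)
  lags <- lags %||% default_lags(unique(erfs$disease))
  sexes <- unique(food_table$sex)
  targets <- targets[order(targets, na.last = FALSE)]

  rows <- purrr::map(targets, function(tg) {
    tg_val <- if (is.na(tg)) NULL else tg
    res <- tryCatch({
      scen <- purrr::map(setNames(sexes, sexes), function(sx) {
        optimise_diet(food_table, cons, ghg_target = tg_val, sex = sx,
                      variant = variant, ...)
      })
      deltas <- purrr::map(scen, deltas_from_scenario) |> dplyr::bind_rows()
      mult <- purrr::map(scen, function(s) {
        hazard_multipliers(deltas_from_scenario(s), erfs, which = rr_which,
                           mask_exposures = mask_exposures)
      }) |> dplyr::bind_rows()
      impact <- project_yll(pop, mult, lags, horizons = horizons)
      list(target = tg, scenarios = scen, deltas = deltas,
           multipliers = mult, impact = impact,
           achieved = mean(purrr::map_dbl(scen, "achieved")),
           objective = mean(purrr::map_dbl(scen, "objective")),
           error = NA_character_)
    }, error = function(e) {
      list(target = tg, scenarios = NULL, deltas = NULL, multipliers = NULL,
           impact = NULL, achieved = NA_real_, objective = NA_real_,
           error = conditionMessage(e))
    })
    res
  })

  summary <- purrr::map(rows, function(r) {
    base <- tibble::tibble(target = r$target, achieved = r$achieved,
                           objective = r$objective, error = r$error)
    if (!is.null(r$impact)) dplyr::bind_cols(base, glance(r$impact)) else base
  }) |> dplyr::bind_rows()

  impacts <- purrr::map(rows, function(r) {
    if (is.null(r$impact)) return(NULL)
    dplyr::mutate(r$impact$yll, target = r$target, .before = 1)
  }) |> dplyr::bind_rows()

  deltas <- purrr::map(rows, function(r) {
    if (is.null(r$deltas)) return(NULL)
    dplyr::mutate(r$deltas, target = r$target, .before = 1)
  }) |> dplyr::bind_rows()

  structure(list(rows = rows, summary = summary, impacts = impacts,
                 deltas = deltas, targets = targets, horizons = horizons,
                 variant = variant, rr_which = rr_which,
                 mask_exposures = mask_exposures),
            class = "diet_sweep")
}

#' @export
print.diet_sweep <- function(x, ...) {
  cat("<diet_sweep> ", length(x$targets), " targets (",
      paste(ifelse(is.na(x$targets), "none",
                   paste0(100 * x$targets, "%")), collapse = ", "),
      ")\n", sep = "")
  print(x$summary)
  invisible(x)
}

#' Tidy a scenario sweep
#'
#' @param x A `diet_sweep` from [run_sweep()].
#' @param ... Unused.
#' @return The per-target summary tibble: achieved reduction, deviation
#'   index (mean optimiser objective across sexes), total YLL averted per
#'   horizon, life-expectancy change per sex, and any recorded error.
#' @method tidy diet_sweep
#' @export
tidy.diet_sweep <- function(x, ...) x$summary

#' One-row summary of a scenario sweep
#'
#' @inheritParams tidy.diet_sweep
#' @return A one-row tibble: number of targets, number converged, and the
#'   incidental (no-target) achieved reduction when that scenario is present.
#' @method glance diet_sweep
#' @export
glance.diet_sweep <- function(x, ...) {
  tibble::tibble(
    n_targets = length(x$targets),
    n_converged = sum(is.na(x$summary$error)),
    incidental_reduction = if (any(is.na(x$targets)))
      x$summary$achieved[is.na(x$summary$target)][1] else NA_real_
  )
}

#' Parameter sensitivity analysis at a single GHG target
#'
#' Reruns the full pipeline three times at one target: a low-impact run
#' (low GHG intensity variant with the CI bound of every RR nearest 1), the
#' central run, and a high-impact run (high intensity variant with the far
#' CI bound). Total YLL averted is ordered low <= central <= high when the
#' CIs are informative.
#'
#' @inheritParams run_sweep
#' @param target Single fractional reduction target (default 0.2).
#' @return A list with class `sensitivity_result`: the three `diet_sweep`
#'   rows and a `summary` tibble of total YLL per run and horizon.
#' @export
run_parameter_sensitivity <- function(food_table, cons, erfs, pop,
                                      target = 0.2, horizons = c(20, 30),
                                      lags = NULL, ...) {
  for (v in c("ghg_low", "ghg_high"))
    if (!v %in% names(food_table))
      abort(paste0("food table lacks the `", v, "` intensity variant."))
  runs <- list(
    low = run_sweep(food_table, cons, erfs, pop, targets = target,
                    variant = "low", rr_which = "low", horizons = horizons,
                    lags = lags, ...),
    central = run_sweep(food_table, cons, erfs, pop, targets = target,
                        variant = "central", rr_which = "central",
                        horizons = horizons, lags = lags, ...),
    high = run_sweep(food_table, cons, erfs, pop, targets = target,
                     variant = "high", rr_which = "high", horizons = horizons,
                     lags = lags, ...)
  )
  summary <- purrr::imap(runs, function(sw, nm) {
    dplyr::filter(sw$impacts, .data$disease == "total") |>
      dplyr::mutate(run = nm, .before = 1) |>
      dplyr::select("run", "horizon", "yll")
  }) |> dplyr::bind_rows()
  structure(list(runs = runs, summary = summary, target = target),
            class = "sensitivity_result")
}

#' @export
print.sensitivity_result <- function(x, ...) {
  cat("<sensitivity_result> target ", 100 * x$target, "%\n", sep = "")
  print(tidyr::pivot_wider(x$summary, names_from = "run",
                           values_from = "yll"))
  invisible(x)
}

#' Structural sensitivity: fruit-only and vegetable-only effects
#'
#' Repeats the sweep counting health effects of (i) fruit but not
#' vegetables and (ii) vegetables but not fruit, by masking the other
#' exposure's ERFs. Meat effects are retained in both variants.
#'
#' @inheritParams run_sweep
#' @return A named list of `diet_sweep` objects: `full`, `fruit_only`,
#'   `vegetable_only`.
#' @export
run_structural_sensitivity <- function(food_table, cons, erfs, pop,
                                       targets = c(NA, 0.1, 0.2, 0.3, 0.4,
                                                   0.5, 0.6), ...) {
  list(
    full = run_sweep(food_table, cons, erfs, pop, targets = targets, ...),
    fruit_only = run_sweep(food_table, cons, erfs, pop, targets = targets,
                           mask_exposures = "vegetable", ...),
    vegetable_only = run_sweep(food_table, cons, erfs, pop, targets = targets,
                               mask_exposures = "fruit", ...)
  )
}
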