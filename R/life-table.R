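## Life-table survival convention: a cohort entering a one-year interval with
## mortality rate m (deaths per person-year) has survival probability
## s = (2 - m) / (2 + m) and contributes (entry + exit)/2 person-years --
## deaths occur on average halfway through the interval. For a constant
## hazard this makes cohort life expectancy exactly 1/m (with the geometric
## open-ended top interval), which anchors the closed-form checks.

surv_prob <- function(m, dt = 1) {
  x <- m * dt
  (2 - x) / (2 + x)
}

## Extract one sex's schedules from a population table.
pop_schedules <- function(pop, sex, diseases) {
  tb <- dplyr::filter(tibble::as_tibble(pop), .data$sex == .env$sex) |>
    dplyr::arrange(.data$age)
  if (nrow(tb) == 0) abort(paste0("population table has no rows for sex `",
                                  sex, "`."))
  miss <- setdiff(diseases, names(tb))
  if (length(miss)) abort(paste("population table lacks cause columns:",
                                paste(miss, collapse = ", ")))
  list(ages = tb$age, n0 = tb$population, m = tb$all_cause,
       md = as.matrix(tb[, diseases, drop = FALSE]))
}

#' Scenario-modified all-cause hazard at a given time
#'
#' Applies lagged per-disease hazard multipliers to the cause-specific
#' components of all-cause mortality:
#' `m'(a, t) = m(a) + sum_d m_d(a) * f_d(t) * (v_d - 1)`,
#' where `v_d` is the full-effect multiplier and `f_d` the lag weight (the
#' lag interpolates linearly on the rate scale between no effect and full
#' effect). Negative modified hazards are clipped to zero with a warning.
#'
#' @param pop Population table (see [generate_population_table()]).
#' @param multipliers Tibble with `disease`, `value` (and optionally `sex`)
#'   from [hazard_multipliers()].
#' @param lags Named list of [lag_function()]s (one per disease), e.g.
#'   [default_lags()].
#' @param t Years since the dietary change was adopted.
#' @param sex Sex label selecting rows of `pop`.
#' @return Numeric vector of modified all-cause rates by single year of age.
#' @export
modified_hazard <- function(pop, multipliers, lags, t, sex) {
  ds <- pop_schedules(pop, sex, multipliers$disease)
  v <- multipliers$value
  f <- purrr::map_dbl(multipliers$disease, ~ lag_weight(lags[[.x]], t))
  m2 <- ds$m + drop(ds$md %*% (f * (v - 1)))
  if (any(m2 < 0)) {
    warn(paste0("modified hazard clipped at 0 for ", sum(m2 < 0),
                " age(s) at t = ", t, "."))
    m2 <- pmax(m2, 0)
  }
  m2
}

## Project a closed population (no births) for `horizon` years and return
## person-years lived in each year. `hazard_fn(t_mid)` gives the per-age
## all-cause rate for the year centred at t_mid.
project_person_years <- function(n0, hazard_fn, horizon) {
  n <- n0
  A <- length(n0)
  py <- numeric(horizon)
  for (k in seq_len(horizon)) {
    m <- pmin(hazard_fn(k - 0.5), 1.999)
    s <- surv_prob(m)
    py[k] <- sum(n * (1 + s) / 2)
    surv <- n * s
    n <- c(0, surv[-A])
    n[A] <- n[A] + surv[A]          # open-ended top age interval
  }
  py
}

## Hazard closure for one sex under a multiplier set with lags.
scenario_hazard_fn <- function(ds, multipliers, lags) {
  v <- multipliers$value
  md <- ds$md[, multipliers$disease, drop = FALSE]
  function(t) {
    f <- purrr::map_dbl(multipliers$disease, ~ lag_weight(lags[[.x]], t))
    pmax(ds$m + drop(md %*% (f * (v - 1))), 0)
  }
}

#' Project years of life lost averted under a diet scenario
#'
#' Projects the current closed population (no future births) year by year
#' under baseline and scenario hazards and accumulates the difference in
#' person-years lived up to each horizon. Positive values are person-years
#' gained (YLL averted). The headline total per horizon comes from the
#' joint scenario (all diseases modified together); per-disease rows are
#' attributions obtained by switching on one disease's multiplier at a
#' time, so they sum only approximately to the joint total (interaction
#' terms are small). Life-expectancy change at birth per sex (in months) is
#' included via [life_expectancy_change()].
#'
#' @param pop Population table covering the sexes in `multipliers`.
#' @param multipliers Tibble `disease`, `sex`, `value` (one row per disease
#'   and sex) from [hazard_multipliers()].
#' @param lags Named list of [lag_function()]s per disease.
#' @param horizons Projection horizons in years (default `c(20, 30)`).
#' @param by_disease Compute one-at-a-time per-disease attributions.
#' @param include_le Also compute life-expectancy change at birth per sex.
#' @return An `impact_result`: `yll` tibble (`disease`, `horizon`, `yll`,
#'   with `disease == "total"` for the joint run), `le_months` tibble, and
#'   the horizons used.
#' @export
project_yll <- function(pop, multipliers, lags, horizons = c(20, 30),
                        by_disease = TRUE, include_le = TRUE) {
  if (any(horizons < 1)) abort("horizons must be at least 1 year.")
  if (!"sex" %in% names(multipliers) || all(is.na(multipliers$sex))) {
    multipliers$sex <- NULL
    multipliers <- tidyr::crossing(multipliers, sex = unique(pop$sex))
  }
  sexes <- unique(multipliers$sex)
  hmax <- max(horizons)
  diseases <- unique(multipliers$disease)

  run_delta <- function(keep) {
    ## person-years gained per year, summed over sexes, for a scenario in
    ## which only `keep` diseases carry their multiplier
    total <- numeric(hmax)
    for (sx in sexes) {
      mult <- dplyr::filter(multipliers, .data$sex == sx)
      ds <- pop_schedules(pop, sx, mult$disease)
      mk <- dplyr::mutate(mult,
                          value = ifelse(.data$disease %in% keep,
                                         .data$value, 1))
      base_py <- project_person_years(ds$n0, function(t) ds$m, hmax)
      scen_py <- project_person_years(ds$n0,
                                      scenario_hazard_fn(ds, mk, lags), hmax)
      total <- total + (scen_py - base_py)
    }
    total
  }

  joint <- run_delta(diseases)
  yll <- tibble::tibble(disease = "total",
                        horizon = horizons,
                        yll = purrr::map_dbl(horizons,
                                             ~ sum(joint[seq_len(.x)])))
  if (by_disease) {
    per <- purrr::map(diseases, function(d) {
      py <- run_delta(d)
      tibble::tibble(disease = d, horizon = horizons,
                     yll = purrr::map_dbl(horizons, ~ sum(py[seq_len(.x)])))
    })
    yll <- dplyr::bind_rows(yll, per)
  }
  le <- if (include_le) {
    tibble::tibble(sex = sexes,
                   months = purrr::map_dbl(sexes, function(sx) {
                     life_expectancy_change(pop,
                                            dplyr::filter(multipliers,
                                                          .data$sex == sx),
                                            lags, sx)
                   }))
  } else {
    tibble::tibble(sex = character(0), months = numeric(0))
  }
  structure(list(yll = yll, le_months = le, horizons = horizons),
            class = "impact_result")
}

#' Change in cohort life expectancy at birth
#'
#' Follows a birth cohort under scenario hazards -- time-varying through the
#' lag functions as the cohort ages (time since adoption equals age), held
#' at full effect thereafter -- and under baseline hazards, and returns the
#' difference in life expectancy at birth in months. Survivors beyond the
#' oldest tabulated age accrue an open-ended geometric tail at the closing
#' rate.
#'
#' @inheritParams project_yll
#' @param sex Sex label.
#' @return Months of life expectancy gained (negative if lost).
#' @export
life_expectancy_change <- function(pop, multipliers, lags, sex) {
  mult <- multipliers
  if ("sex" %in% names(mult) && !all(is.na(mult$sex)))
    mult <- dplyr::filter(mult, .data$sex == .env$sex)
  ds <- pop_schedules(pop, sex, mult$disease)
  hz <- scenario_hazard_fn(ds, mult, lags)
  e_base <- cohort_e0(ds$m)
  A <- length(ds$m)
  m_scen <- purrr::map_dbl(seq_len(A), function(j) hz(j - 0.5)[j])
  e_scen <- cohort_e0(m_scen)
  (e_scen - e_base) * 12
}

## e0 for a per-year hazard vector under the package survival convention,
## with a geometric open-ended tail at the final rate.
cohort_e0 <- function(m, dt = 1) {
  s <- surv_prob(pmin(m, 1.999 / dt), dt)
  l <- 1
  e <- 0
  for (j in seq_along(m)) {
    e <- e + dt * l * (1 + s[j]) / 2
    l <- l * s[j]
  }
  s_end <- s[length(s)]
  if (s_end < 1) e <- e + dt * l * (1 + s_end) / (2 * (1 - s_end))
  e
}

#' Cohort life expectancy for an arbitrary hazard schedule
#'
#' Utility used for closed-form checks of the life-table engine: computes
#' life expectancy for a hazard given as a function of age (or a constant),
#' on a grid of step `dt` years up to `max_age`, with the same half-interval
#' survival convention as the projection engine. For a constant hazard `m`
#' the result equals `1/m` up to floating-point error, independent of `dt`.
#'
#' @param hazard A function of age returning a rate, or a single constant
#'   rate.
#' @param dt Time step in years.
#' @param max_age Oldest age on the grid (the tail beyond it is closed
#'   geometrically at the final rate).
#' @return Life expectancy at birth in years.
#' @export
cohort_life_expectancy <- function(hazard, dt = 1, max_age = 110) {
  hz <- if (is.function(hazard)) hazard else function(a) rep_len(hazard, length(a))
  mids <- seq(dt / 2, max_age, by = dt)
  cohort_e0(hz(mids), dt)
}

#' @export
print.impact_result <- function(x, ...) {
  tot <- dplyr::filter(x$yll, .data$disease == "total")
  cat("<impact_result>\n")
  for (i in seq_len(nrow(tot)))
    cat(sprintf("  YLL averted over %d years: %s\n", tot$horizon[i],
                format(round(tot$yll[i]), big.mark = ",")))
  for (i in seq_len(nrow(x$le_months)))
    cat(sprintf("  life expectancy at birth (%s): %+.1f months\n",
                x$le_months$sex[i], x$le_months$months[i]))
  invisible(x)
}

#' Tidy an impact result into per-disease rows
#'
#' @param x An `impact_result` from [project_yll()].
#' @param ... Unused.
#' @return The long tibble of YLL averted by disease (including the joint
#'   `"total"` rows) and horizon.
#' @method tidy impact_result
#' @export
tidy.impact_result <- function(x, ...) x$yll

#' One-row summary of an impact result
#'
#' @inheritParams tidy.impact_result
#' @return A one-row tibble with total YLL per horizon (`yll_<h>`) and
#'   life-expectancy change per sex (`le_months_<sex>`).
#' @method glance impact_result
#' @export
glance.impact_result <- function(x, ...) {
  tot <- dplyr::filter(x$yll, .data$disease == "total")
  out <- tibble::as_tibble(setNames(as.list(tot$yll),
                                    paste0("yll_", tot$horizon)))
  if (nrow(x$le_months))
    out <- dplyr::bind_cols(out,
                            tibble::as_tibble(setNames(
                              as.list(x$le_months$months),
                              paste0("le_months_", x$le_months$sex))))
  out
}
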