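#' Welfare weights for dietary change
#'
#' Builds per-group weights expressing how costly (in welfare terms) it is
#' to move a food group away from its current consumption: groups with a
#' large expenditure share and low price responsiveness are the hardest to
#' change. The default functional form is `w_i = s_i / |e_i|`, normalised to
#' mean 1; the normalisation only rescales the objective and does not move
#' its minimiser.
#'
#' @param elasticities Own-price elasticities, all strictly negative.
#' @param shares Expenditure shares, all strictly positive.
#' @return A numeric vector of positive weights with mean 1.
#' @export
#' @examples
#' build_weights(c(-0.5, -1), c(0.5, 0.5))  # c(4/3, 2/3)
build_weights <- function(elasticities, shares) {
  if (length(elasticities) != length(shares))
    abort("`elasticities` and `shares` must have the same length.")
  if (any(elasticities == 0)) abort("zero elasticity: weight undefined.")
  if (any(elasticities > 0)) abort("elasticities must be negative.")
  if (any(shares <= 0)) abort("shares must be strictly positive.")
  w <- shares / abs(elasticities)
  w / mean(w)
}

#' Deviation objective for diet optimisation
#'
#' The welfare-weighted sum of squared percentage deviations from the
#' baseline diet: `sum_i w_i * (100 * (x_i - c_i) / c_i)^2`. Zero exactly
#' when the candidate diet equals the baseline.
#'
#' @param x Candidate diet (g/day per group).
#' @param baseline Baseline diet (g/day per group), strictly positive.
#' @param weights Per-group weights, e.g. from [build_weights()].
#' @return A non-negative scalar.
#' @export
diet_objective <- function(x, baseline, weights = rep(1, length(baseline))) {
  if (any(baseline <= 0)) abort("baseline consumption must be strictly positive.")
  if (length(x) != length(baseline) || length(weights) != length(baseline))
    abort("`x`, `baseline` and `weights` must be conformable.")
  sum(weights * (100 * (x - baseline) / baseline)^2)
}

## Build the linear constraint system A x (>=|=) b for one sex.
## Returns Ain/bin (rows: a . x >= b), Aeq/beq and row labels.
build_constraint_system <- function(tb, cons, ghg_target = NULL,
                                    variant = "central") {
  c0 <- tb$consumption_g
  n <- length(c0)
  energy <- tb[[cons$energy_nutrient]]
  if (is.null(energy)) abort(paste0("food table lacks the energy column `",
                                    cons$energy_nutrient, "`."))
  Ain <- NULL; bin <- numeric(0); in_lab <- character(0); in_type <- character(0)
  add_in <- function(a, b, lab, type) {
    Ain <<- rbind(Ain, a); bin <<- c(bin, b)
    in_lab <<- c(in_lab, lab); in_type <<- c(in_type, type)
  }
  for (i in seq_len(nrow(cons$nutrients))) {
    r <- cons$nutrients[i, ]
    v <- tb[[r$nutrient]]
    if (is.null(v)) abort(paste0("food table lacks nutrient column `",
                                 r$nutrient, "`."))
    if (r$unit == "pct_energy") {
      if (!is.na(r$lower))
        add_in(v * r$kcal_per_g - r$lower * energy, 0,
               paste0(r$nutrient, "_lower"), "lower")
      if (!is.na(r$upper))
        add_in(-(v * r$kcal_per_g - r$upper * energy), 0,
               paste0(r$nutrient, "_upper"), "upper")
    } else {
      if (!is.na(r$lower))
        add_in(v, r$lower, paste0(r$nutrient, "_lower"), "lower")
      if (!is.na(r$upper))
        add_in(-v, -r$upper, paste0(r$nutrient, "_upper"), "upper")
    }
  }
  Aeq <- NULL; beq <- numeric(0); eq_lab <- character(0)
  if (cons$energy_equality) {
    Aeq <- rbind(Aeq, energy); beq <- c(beq, sum(energy * c0))
    eq_lab <- c(eq_lab, "energy_equality")
  }
  if (cons$liquid_equality) {
    p <- sum(c0[tb$liquid]) / sum(c0)
    Aeq <- rbind(Aeq, as.numeric(tb$liquid) - p); beq <- c(beq, 0)
    eq_lab <- c(eq_lab, "liquid_proportion_equality")
  }
  if (!is.null(ghg_target) && !is.na(ghg_target)) {
    g <- tb[[paste0("ghg_", variant)]]
    if (is.null(g)) abort(paste0("unknown GHG variant `", variant, "`."))
    add_in(-g, -(1 - ghg_target) * sum(g * c0), "ghg_target", "ghg")
  }
  list(Ain = Ain, bin = bin, in_lab = in_lab, in_type = in_type,
       Aeq = Aeq, beq = beq, eq_lab = eq_lab)
}

#' Evaluate constraint slacks for a candidate diet
#'
#' Reports, for every nutrient bound, the energy and liquid-proportion
#' equalities, the GHG inequality (when a target is given) and
#' non-negativity, the attained value, the bound, the signed slack
#' (non-negative means satisfied) and whether the constraint holds within a
#' relative tolerance. A pure reporting operation: it never errors on a
#' violated constraint.
#'
#' @param x Candidate diet for one sex (g/day, in food-table row order).
#' @param food_table Food table filtered (or filterable via `sex`) to one sex.
#' @param cons A [nutrient_constraints()] object.
#' @param ghg_target Fractional reduction target in (0, 1), or `NULL`.
#' @param sex Sex label used to filter `food_table` if it has several.
#' @param variant GHG intensity variant: `"low"`, `"central"`, `"high"`.
#' @param tol Relative tolerance for the `ok` flag (default 1e-6).
#' @return A tibble with one row per constraint.
#' @export
evaluate_constraints <- function(x, food_table, cons, ghg_target = NULL,
                                 sex = NULL, variant = "central", tol = 1e-6) {
  tb <- filter_sex(food_table, sex)
  if (length(x) != nrow(tb)) abort("`x` does not match the food table rows.")
  sys <- build_constraint_system(tb, cons, ghg_target, variant)
  rows <- list()
  if (!is.null(sys$Ain)) {
    val <- unname(drop(sys$Ain %*% x))
    scale <- pmax(1, abs(sys$bin), apply(abs(sys$Ain) * abs(x)[col(sys$Ain)], 1, max))
    rows$ineq <- tibble::tibble(constraint = sys$in_lab, type = sys$in_type,
                                value = val, bound = sys$bin,
                                slack = val - sys$bin,
                                rel_violation = pmax(0, sys$bin - val) / scale)
  }
  if (!is.null(sys$Aeq)) {
    val <- unname(drop(sys$Aeq %*% x))
    scale <- pmax(1, abs(sys$beq), apply(abs(sys$Aeq) * abs(x)[col(sys$Aeq)], 1, max))
    rows$eq <- tibble::tibble(constraint = sys$eq_lab, type = "equality",
                              value = val, bound = sys$beq,
                              slack = val - sys$beq,
                              rel_violation = abs(val - sys$beq) / scale)
  }
  rows$nn <- tibble::tibble(constraint = "non_negativity", type = "bound",
                            value = min(x), bound = 0, slack = min(x),
                            rel_violation = pmax(0, -min(x)))
  out <- dplyr::bind_rows(rows)
  out$ok <- out$rel_violation <= tol
  out
}

#' Optimise a diet against nutrient constraints and a GHG target
#'
#' Finds, for one sex, the diet closest to the baseline (in welfare-weighted
#' squared percentage deviation, see [diet_objective()]) among diets that
#' satisfy the nutrient constraint set, hold total energy and the liquid
#' share of diet mass at baseline, keep every group non-negative, and - when
#' a target is given - reduce diet-wide GHG emissions by at least the target
#' fraction. The GHG condition is an inequality, so the achieved reduction
#' can exceed the target. With no target the achieved reduction is still
#' computed and reported (the "incidental" reduction of a diet optimised on
#' nutrition alone).
#'
#' The problem is a convex diagonal quadratic with linear constraints; it is
#' solved in percentage-deviation coordinates by an augmented-Lagrangian
#' method with analytic gradients, from `n_starts` deterministic starting
#' points (baseline plus fixed perturbations); the best feasible solution is
#' returned.
#'
#' @inheritParams evaluate_constraints
#' @param weights Optional per-group weights; defaults to
#'   [build_weights()] on the table's elasticities and shares.
#' @param n_starts Number of deterministic starts (default 8).
#' @param ctol Solver feasibility tolerance (default 1e-9 on unit-normalised
#'   constraint rows).
#' @return A `diet_scenario` object; see [tidy.diet_scenario()].
#' @export
optimise_diet <- function(food_table, cons, ghg_target = NULL, sex = NULL,
                          variant = "central", weights = NULL,
                          n_starts = 8L, ctol = 1e-9, tol = 1e-6) {
  tb <- filter_sex(food_table, sex)
  sx <- if ("sex" %in% names(tb)) unique(tb$sex) else sex
  c0 <- tb$consumption_g
  if (any(c0 <= 0)) abort("baseline consumption must be strictly positive.")
  n <- length(c0)
  w <- weights %||% build_weights(tb$elasticity, tb$share)
  sys <- build_constraint_system(tb, cons, ghg_target, variant)

  ## solve in percentage-deviation coordinates z = 100 (x - c0) / c0:
  ## objective sum(w z^2) is perfectly conditioned; constraints stay linear.
  to_x <- function(z) c0 * (1 + z / 100)
  fn <- function(z) sum(w * z^2)
  gr <- function(z) 2 * w * z
  tr <- function(A, b) if (is.null(A)) list(A = NULL, b = numeric(0)) else
    list(A = A * rep(c0 / 100, each = nrow(A)), b = b - drop(A %*% c0))
  IN <- tr(sys$Ain, sys$bin); EQ <- tr(sys$Aeq, sys$beq)

  best <- NULL
  for (j in seq_len(n_starts)) {
    z0 <- if (j == 1) numeric(n) else
      100 * ((0.5 + ((seq_len(n) * j) %% 8) / 7) - 1)   # fixed perturbations
    fit <- auglag_solve(z0, fn, gr, Aeq = EQ$A, beq = EQ$b,
                        Ain = IN$A, bin = IN$b,
                        lower = rep(-100, n), upper = rep(Inf, n), ctol = ctol)
    if (is.null(best)) {
      best <- fit
    } else {
      feas_fit <- fit$violation <= 10 * ctol
      feas_best <- best$violation <= 10 * ctol
      if ((feas_fit && !feas_best) ||
          (feas_fit == feas_best && feas_fit && fit$value < best$value) ||
          (!feas_fit && !feas_best && fit$violation < best$violation))
        best <- fit
    }
  }
  x <- pmax(to_x(best$par), 0)
  report <- evaluate_constraints(x, tb, cons, ghg_target, variant = variant,
                                 tol = tol)
  if (any(!report$ok)) {
    worst <- report$constraint[which.max(report$rel_violation)]
    abort(paste0("optimisation did not reach a feasible diet",
                 if (!is.null(sx)) paste0(" for sex `", sx, "`"),
                 "; most violated constraint: `", worst, "` (relative ",
                 "violation ", signif(max(report$rel_violation), 3),
                 "). The constraint set may be infeasible."))
  }
  g <- tb[[paste0("ghg_", variant)]]
  structure(
    list(sex = sx, target = ghg_target, variant = variant,
         group_id = tb$group_id, exposure = tb$exposure,
         baseline = setNames(c0, tb$group_id), x = setNames(x, tb$group_id),
         weights = w,
         achieved = 1 - sum(g * x) / sum(g * c0),
         objective = diet_objective(x, c0, w),
         constraint_report = report, converged = TRUE),
    class = "diet_scenario"
  )
}

filter_sex <- function(food_table, sex) {
  tb <- tibble::as_tibble(food_table)
  if (!is.null(sex)) tb <- dplyr::filter(tb, .data$sex == .env$sex)
  if ("sex" %in% names(tb) && length(unique(tb$sex)) > 1)
    abort("food table contains several sexes; supply `sex = `.")
  if (nrow(tb) == 0) abort("no food-table rows for the requested sex.")
  tb
}

#' @export
print.diet_scenario <- function(x, ...) {
  cat("<diet_scenario>", if (!is.null(x$sex)) paste0(" sex: ", x$sex), "\n",
      sep = "")
  cat("  GHG target: ",
      if (is.null(x$target)) "none" else sprintf("%.0f%%", 100 * x$target),
      "; achieved: ", sprintf("%.1f%%", 100 * x$achieved), "\n", sep = "")
  cat("  objective (deviation index): ", format(x$objective, digits = 5),
      "; converged: ", x$converged, "\n", sep = "")
  invisible(x)
}

#' Tidy a diet scenario into per-group rows
#'
#' @param x A `diet_scenario` from [optimise_diet()].
#' @param ... Unused.
#' @return A tibble with baseline and optimised consumption per food group,
#'   absolute and percentage change.
#' @method tidy diet_scenario
#' @export
tidy.diet_scenario <- function(x, ...) {
  tibble::tibble(sex = x$sex %||% NA_character_,
                 group_id = x$group_id, exposure = x$exposure,
                 baseline_g = unname(x$baseline), optimised_g = unname(x$x),
                 change_g = unname(x$x - x$baseline),
                 pct_change = 100 * unname(x$x - x$baseline) / unname(x$baseline))
}

#' One-row summary of a diet scenario
#'
#' @inheritParams tidy.diet_scenario
#' @return A one-row tibble: target, achieved reduction, objective value,
#'   convergence flag and the largest relative constraint violation.
#' @method glance diet_scenario
#' @export
glance.diet_scenario <- function(x, ...) {
  tibble::tibble(sex = x$sex %||% NA_character_,
                 target = x$target %||% NA_real_,
                 achieved = x$achieved, objective = x$objective,
                 converged = x$converged,
                 max_rel_violation = max(x$constraint_report$rel_violation))
}
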