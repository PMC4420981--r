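## Shared fixtures, cached per test session (the full sweep is the most
## expensive object and several files inspect it).

.fixture_cache <- new.env(parent = emptyenv())

default_fixture <- function() {
  if (is.null(.fixture_cache$fx)) {
    cfg <- synth_config(seed = 1)
    .fixture_cache$fx <- list(
      cfg = cfg,
      food = generate_food_table(cfg),
      pop = generate_population_table(cfg),
      erfs = generate_erf_table(cfg),
      cons = who_constraints()
    )
  }
  .fixture_cache$fx
}

default_sweep <- function() {
  if (is.null(.fixture_cache$sw)) {
    fx <- default_fixture()
    .fixture_cache$sw <- run_sweep(fx$food, fx$cons, fx$erfs, fx$pop)
  }
  .fixture_cache$sw
}

## Minimal food tables for hand-sized optimisation problems. Extra nutrient
## columns are passed as named vectors of per-gram values.
tiny_food_table <- function(consumption, energy = rep(1, length(consumption)),
                            ghg = rep(1, length(consumption)),
                            elasticity = rep(-1, length(consumption)),
                            share = rep(1 / length(consumption),
                                        length(consumption)),
                            liquid = rep(FALSE, length(consumption)),
                            exposure = rep("other", length(consumption)),
                            ...) {
  n <- length(consumption)
  tb <- tibble::tibble(
    group_id = paste0("food", seq_len(n)), exposure = exposure,
    liquid = liquid, consumption_g = consumption,
    ghg_low = 0.8 * ghg, ghg_central = ghg, ghg_high = 1.3 * ghg,
    elasticity = elasticity, share = share, energy_kcal = energy
  )
  extra <- list(...)
  for (nm in names(extra)) tb[[nm]] <- extra[[nm]]
  tb
}

no_constraints <- function() {
  nutrient_constraints(
    tibble::tibble(nutrient = character(0), unit = character(0),
                   lower = numeric(0), upper = numeric(0),
                   kcal_per_g = numeric(0)),
    energy_equality = FALSE, liquid_equality = FALSE
  )
}

## Dense grid-search oracles with iterative refinement: independent of the
## package solver, they only need a feasibility predicate and an objective.
## Each round lays `n` points per free coordinate across the current box and
## shrinks the box around the incumbent, so the final precision is far below
## the comparison tolerance.
oracle_grid_1d <- function(lo, hi, objective, feasible, n = 200, rounds = 5) {
  best <- NA
  for (r in seq_len(rounds)) {
    xs <- seq(lo, hi, length.out = n)
    ok <- vapply(xs, feasible, logical(1))
    if (!any(ok)) stop("oracle: no feasible grid point")
    vals <- vapply(xs[ok], objective, numeric(1))
    best <- xs[ok][which.min(vals)]
    step <- (hi - lo) / (n - 1)
    lo <- max(lo, best - 3 * step)
    hi <- min(hi, best + 3 * step)
  }
  best
}

oracle_grid_2d <- function(lo, hi, objective, feasible, n = 200, rounds = 6) {
  best <- c(NA, NA)
  for (r in seq_len(rounds)) {
    g1 <- seq(lo[1], hi[1], length.out = n)
    g2 <- seq(lo[2], hi[2], length.out = n)
    grid <- expand.grid(x1 = g1, x2 = g2)
    ok <- mapply(function(a, b) feasible(c(a, b)), grid$x1, grid$x2)
    if (!any(ok)) stop("oracle: no feasible grid point")
    sub <- grid[ok, ]
    vals <- mapply(function(a, b) objective(c(a, b)), sub$x1, sub$x2)
    best <- as.numeric(sub[which.min(vals), ])
    step <- (hi - lo) / (n - 1)
    lo <- pmax(lo, best - 3 * step)
    hi <- pmin(hi, best + 3 * step)
  }
  best
}

expect_coords_close <- function(x, ref, rel = 0.005) {
  expect_true(all(abs(x - ref) / pmax(abs(ref), 1) <= rel),
              label = paste0("coordinates (", paste(signif(x, 6),
                                                    collapse = ", "),
                             ") vs oracle (", paste(signif(ref, 6),
                                                    collapse = ", "), ")"))
}
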