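test_that("welfare weights follow share / |elasticity|, normalised to mean 1", {
  expect_equal(build_weights(c(-1, -1, -1), c(1, 1, 1) / 3), rep(1, 3))
  expect_equal(build_weights(c(-0.5, -1.0), c(0.5, 0.5)), c(4 / 3, 2 / 3))
  ## monotone: growing a group's share raises its weight relative to others
  w1 <- build_weights(c(-1, -1), c(0.5, 0.5))
  w2 <- build_weights(c(-1, -1), c(2 / 3, 1 / 3))
  expect_gt(w2[1] / w2[2], w1[1] / w1[2])
  expect_error(build_weights(c(0, -1), c(0.5, 0.5)), "zero elasticity")
  expect_error(build_weights(c(-1, -1), c(0, 1)), "positive")
})

test_that("deviation objective matches its closed form", {
  c0 <- c(100, 200)
  expect_equal(diet_objective(c0, c0), 0)
  expect_equal(diet_objective(110, 100, 1), 100)              # (10%)^2
  expect_equal(diet_objective(c(110, 160), c0, c(2, 1)), 600) # 2*100 + 1*400
  expect_error(diet_objective(c(1, 1), c(0, 1)), "strictly positive")
})

test_that("constraint report slacks are exact at the baseline diet", {
  fx <- default_fixture()
  tb <- dplyr::filter(fx$food, sex == "male")
  c0 <- tb$consumption_g
  rep0 <- evaluate_constraints(c0, tb, fx$cons)
  eq <- dplyr::filter(rep0, type == "equality")
  expect_equal(eq$slack, rep(0, nrow(eq)), tolerance = 1e-12)

  ## with a 10% target the baseline diet violates the GHG row by exactly
  ## 10% of baseline emissions
  rep1 <- evaluate_constraints(c0, tb, fx$cons, ghg_target = 0.1)
  ghg_row <- dplyr::filter(rep1, constraint == "ghg_target")
  base_em <- diet_emissions(NULL, tb)$total
  expect_equal(ghg_row$slack, -0.1 * base_em, tolerance = 1e-9)
  expect_false(ghg_row$ok)
})

test_that("unconstrained optimisation returns the baseline diet", {
  tb <- tiny_food_table(c(100, 250, 60))
  sc <- optimise_diet(tb, no_constraints())
  expect_equal(unname(sc$x), tb$consumption_g, tolerance = 1e-6)
  expect_lt(sc$objective, 1e-8)
})

test_that("a GHG target is met as an inequality (achieved >= target)", {
  fx <- default_fixture()
  sc <- optimise_diet(fx$food, fx$cons, ghg_target = 0.2, sex = "male")
  expect_true(sc$converged)
  expect_gte(sc$achieved, 0.2 - 1e-6)
  expect_true(all(sc$x >= 0))
  expect_true(all(sc$constraint_report$ok))
})

test_that("solution is invariant to group reordering and weight rescaling", {
  fx <- default_fixture()
  tb <- dplyr::filter(fx$food, sex == "female")
  sc1 <- optimise_diet(tb, fx$cons, ghg_target = 0.3)
  perm <- rev(seq_len(nrow(tb)))
  sc2 <- optimise_diet(tb[perm, ], fx$cons, ghg_target = 0.3)
  expect_equal(sc2$x[names(sc1$x)], sc1$x, tolerance = 1e-4)

  w <- build_weights(tb$elasticity, tb$share)
  sc3 <- optimise_diet(tb, fx$cons, ghg_target = 0.3, weights = 7.3 * w)
  expect_equal(sc3$x, sc1$x, tolerance = 1e-4)
  expect_equal(sc3$objective, 7.3 * sc1$objective, tolerance = 1e-6)
})

test_that("multi-start solutions of the convex problem agree", {
  fx <- default_fixture()
  tb <- dplyr::filter(fx$food, sex == "male")
  sc1 <- optimise_diet(tb, fx$cons, ghg_target = 0.4, n_starts = 1)
  sc8 <- optimise_diet(tb, fx$cons, ghg_target = 0.4, n_starts = 8)
  expect_equal(sc1$x, sc8$x, tolerance = 1e-4)
  expect_equal(sc1$objective, sc8$objective, tolerance = 1e-6)
})

test_that("an infeasible constraint set raises a named error", {
  ## fib >= 1000 is unreachable once total mass is capped at 150 g
  tb <- tiny_food_table(c(100, 100), fib = c(0.01, 0.02))
  cons2 <- nutrient_constraints(
    tibble::tibble(nutrient = c("fib", "mass"), unit = "absolute",
                   lower = c(1000, NA), upper = c(NA, 150),
                   kcal_per_g = c(NA, NA)),
    energy_equality = FALSE, liquid_equality = FALSE
  )
  tb$mass <- c(1, 1)
  expect_error(optimise_diet(tb, cons2), "most violated")
})

test_that("scenario tidiers expose per-group changes and a summary row", {
  fx <- default_fixture()
  sc <- optimise_diet(fx$food, fx$cons, ghg_target = 0.2, sex = "male")
  td <- tidy(sc)
  expect_equal(nrow(td), 42L)
  expect_equal(td$optimised_g - td$baseline_g, td$change_g)
  gl <- glance(sc)
  expect_equal(gl$target, 0.2)
  expect_true(gl$converged)
  expect_lte(gl$max_rel_violation, 1e-6)
})
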