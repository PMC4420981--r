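## A one-age population table for hand enumeration.
toy_pop <- function(n = 1000, m = 0.1, md = 0.05, sex = "male") {
  tibble::tibble(sex = sex, age = 0, population = n, all_cause = m, d1 = md)
}

test_that("null multipliers leave hazards, YLL and life expectancy unchanged", {
  fx <- default_fixture()
  mult <- tibble::tibble(disease = fx$cfg$disease_names, sex = "male",
                         value = 1)
  lags <- default_lags(fx$cfg$disease_names)
  mh <- modified_hazard(fx$pop, mult, lags, t = 15, sex = "male")
  expect_identical(mh, fx$pop$all_cause[fx$pop$sex == "male"])

  both <- dplyr::bind_rows(mult, dplyr::mutate(mult, sex = "female"))
  imp <- project_yll(fx$pop, both, lags)
  expect_true(all(imp$yll$yll == 0))
  expect_true(all(imp$le_months$months == 0))
})

test_that("modified hazard applies lagged multipliers on the rate scale", {
  pop <- toy_pop(m = 0.1, md = 0.04)
  lags <- list(d1 = lag_function("instant"))
  mult <- tibble::tibble(disease = "d1", sex = "male", value = 0.5)
  ## f = 1, M = 0.5, m_d = 0.4 m  ->  m' = 0.8 m
  expect_equal(modified_hazard(pop, mult, lags, t = 5, sex = "male"), 0.08)
  ## at t = 0 every lag weight is 0
  expect_equal(modified_hazard(pop, mult, lags, t = 0, sex = "male"), 0.1)
  ## a hazard pushed below zero is clipped with a warning
  bad <- tibble::tibble(sex = "male", age = 0, population = 1,
                        all_cause = 0.1, d1 = 0.3)  # inconsistent on purpose
  expect_warning(
    out <- modified_hazard(bad, mult, lags, t = 5, sex = "male"),
    "clipped")
  expect_equal(out, 0)
  expect_error(modified_hazard(pop, dplyr::mutate(mult, disease = "d9"),
                               lags, t = 1, sex = "male"), "cause columns")
})

test_that("two-year toy projection matches explicit hand enumeration", {
  n <- 1000; m <- 0.1; md <- 0.05; M <- 0.5
  pop <- toy_pop(n, m, md)
  mult <- tibble::tibble(disease = "d1", sex = "male", value = M)
  lags <- list(d1 = lag_function("instant"))
  imp <- project_yll(pop, mult, lags, horizons = c(1, 2),
                     by_disease = FALSE, include_le = FALSE)

  ## oracle: explicit enumeration under the package survival convention
  ## s = (2 - m)/(2 + m), person-years = n (1 + s)/2 each year
  m_scen <- m + md * (M - 1)
  sb <- (2 - m) / (2 + m)
  ss <- (2 - m_scen) / (2 + m_scen)
  py_base <- c(n * (1 + sb) / 2, n * sb * (1 + sb) / 2)
  py_scen <- c(n * (1 + ss) / 2, n * ss * (1 + ss) / 2)
  expected <- cumsum(py_scen - py_base)
  got <- dplyr::filter(imp$yll, disease == "total") |> dplyr::arrange(horizon)
  expect_equal(got$yll, expected, tolerance = 1e-12)
})

test_that("YLL is linear in population size and monotone in the horizon", {
  fx <- default_fixture()
  mult <- tidyr::crossing(disease = fx$cfg$disease_names,
                          sex = fx$cfg$sexes) |>
    dplyr::mutate(value = 0.9)
  lags <- default_lags(fx$cfg$disease_names)
  imp1 <- project_yll(fx$pop, mult, lags, horizons = c(10, 20, 30),
                      by_disease = FALSE, include_le = FALSE)
  pop2 <- dplyr::mutate(fx$pop, population = 2 * population)
  imp2 <- project_yll(pop2, mult, lags, horizons = c(10, 20, 30),
                      by_disease = FALSE, include_le = FALSE)
  expect_equal(imp2$yll$yll, 2 * imp1$yll$yll, tolerance = 1e-12)
  tot <- dplyr::arrange(dplyr::filter(imp1$yll, disease == "total"), horizon)
  expect_true(all(tot$yll > 0))
  expect_true(all(diff(tot$yll) > 0))
})

test_that("per-disease attributions nearly sum to the joint total", {
  sw <- default_sweep()
  imp <- sw$rows[[1]]$impact   # no-GHG-target scenario
  for (h in sw$horizons) {
    tot <- imp$yll$yll[imp$yll$disease == "total" & imp$yll$horizon == h]
    parts <- sum(imp$yll$yll[imp$yll$disease != "total" &
                               imp$yll$horizon == h])
    expect_lt(abs(parts - tot) / tot, 0.05)
  }
})

test_that("constant-hazard life expectancy matches the 1/m closed form", {
  m <- 0.2
  for (dt in c(1, 0.5, 0.25)) {
    e <- cohort_life_expectancy(m, dt = dt, max_age = 400)
    expect_equal(e, 1 / m, tolerance = 1e-10)
  }
  ## discretisation error never grows as the step shrinks
  errs <- sapply(c(1, 0.5, 0.25), function(dt)
    abs(cohort_life_expectancy(function(a) 0.05 + 0.002 * a, dt = dt,
                               max_age = 300) -
          cohort_life_expectancy(function(a) 0.05 + 0.002 * a, dt = 0.01,
                                 max_age = 300)))
  expect_true(all(diff(errs) <= 0))
  expect_lte(errs[2], errs[1] / 2 + 1e-12)
})

test_that("a permanent uniform multiplier reproduces exponential survival", {
  m <- 0.08; M <- 0.7
  ages <- 0:100
  pop <- tibble::tibble(sex = "male", age = ages, population = 1000,
                        all_cause = m, d1 = m)  # one cause carries it all
  mult <- tibble::tibble(disease = "d1", sex = "male", value = M)
  lags <- list(d1 = lag_function("instant"))
  gain <- life_expectancy_change(pop, mult, lags, sex = "male")
  expect_equal(gain, (1 / (m * M) - 1 / m) * 12, tolerance = 1e-9)
})

test_that("protective multipliers yield strictly positive life-expectancy gain", {
  fx <- default_fixture()
  mult <- tibble::tibble(disease = "coronary_heart_disease", sex = "female",
                         value = 0.8)
  lags <- default_lags("coronary_heart_disease")
  gain <- life_expectancy_change(fx$pop, mult, lags, sex = "female")
  expect_gt(gain, 0)
})
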