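test_that("food-table generator is seed-deterministic and well-formed", {
  cfg <- synth_config(seed = 7)
  a <- generate_food_table(cfg)
  b <- generate_food_table(cfg)
  expect_identical(a, b)

  fx <- default_fixture()
  food <- fx$food
  for (sx in fx$cfg$sexes) {
    tb <- dplyr::filter(food, sex == sx)
    expect_equal(nrow(tb), 42L)
    expect_true(all(tb$consumption_g > 0))
    expect_true(all(tb$ghg_central > 0))
    expect_true(all(tb$ghg_low <= tb$ghg_central & tb$ghg_central <= tb$ghg_high))
    expect_true(all(tb$elasticity > -2 & tb$elasticity < -0.05))
    expect_true(all(tb$share > 0))
    expect_equal(sum(tb$share), 1, tolerance = 1e-12)
    for (tag in c("fruit", "vegetable", "red_meat", "processed_meat"))
      expect_true(any(tb$exposure == tag))
    expect_true(any(tb$liquid))
    nut <- tb[, fx$cfg$nutrient_names]
    expect_true(all(as.matrix(nut) >= 0))
  }
})

test_that("too few groups for the mandatory exposure tags is an error", {
  expect_error(generate_food_table(synth_config(n_food_groups = 4)),
               "at least one")
  expect_error(synth_config(n_food_groups = 1), "at least 2")
})

test_that("non-default group counts still carry every exposure tag", {
  for (n in c(5, 12, 60)) {
    tb <- generate_food_table(synth_config(n_food_groups = n, seed = 3))
    one_sex <- dplyr::filter(tb, sex == "male")
    expect_equal(nrow(one_sex), n)
    for (tag in c("fruit", "vegetable", "red_meat", "processed_meat"))
      expect_true(any(one_sex$exposure == tag))
    expect_equal(sum(one_sex$share), 1, tolerance = 1e-12)
  }
})

test_that("population table satisfies its structural invariants", {
  fx <- default_fixture()
  pop <- fx$pop
  expect_setequal(unique(pop$sex), fx$cfg$sexes)
  for (sx in fx$cfg$sexes) {
    tb <- dplyr::arrange(dplyr::filter(pop, sex == sx), age)
    expect_equal(tb$age, 0:fx$cfg$max_age)
    expect_true(all(tb$population >= 0))
    expect_true(all(tb$all_cause > 0 & tb$all_cause <= 1))
    expect_equal(tb$all_cause[nrow(tb)], 1)  # closing the table
    cause_sum <- rowSums(tb[, fx$cfg$disease_names])
    expect_true(all(cause_sum <= tb$all_cause + 1e-12))
    ## roughly Gompertz: mortality rises by orders of magnitude over adulthood
    expect_gt(tb$all_cause[81], 20 * tb$all_cause[41])
  }
  expect_identical(generate_population_table(fx$cfg),
                   generate_population_table(fx$cfg))
})

test_that("published ERF table has the 17 documented pathways", {
  erfs <- generate_erf_table(synth_config())
  expect_equal(nrow(erfs), 17L)
  fruit_chd <- dplyr::filter(erfs, exposure == "fruit",
                             disease == "coronary_heart_disease")
  expect_equal(fruit_chd$rr, 0.93)
  expect_equal(fruit_chd$increment_g, 80)
  pm_t2d <- dplyr::filter(erfs, exposure == "processed_meat",
                          disease == "type2_diabetes")
  expect_equal(pm_t2d$rr, 1.51)
  expect_equal(pm_t2d$increment_g, 100)
  ## lung cancer is a fruit-only pathway
  expect_equal(unique(erfs$exposure[erfs$disease == "lung_cancer"]), "fruit")
  expect_true(all(erfs$rr_low <= erfs$rr & erfs$rr <= erfs$rr_high))
})

test_that("ERF fixture round-trips through the CSV writer/reader unchanged", {
  erfs <- generate_erf_table(synth_config())
  path <- withr::local_tempfile(fileext = ".csv")
  write_erf_table(erfs, path)
  expect_equal(read_erf_table(path), erfs)
})

test_that("random ERF mode is structurally valid and deterministic", {
  cfg <- synth_config(seed = 11)
  a <- generate_erf_table(cfg, use_published = FALSE)
  expect_identical(a, generate_erf_table(cfg, use_published = FALSE))
  expect_true(all(a$rr >= 0.5 & a$rr <= 1.6))
  expect_true(all(a$rr_low <= a$rr & a$rr <= a$rr_high))
  expect_true(all(a$increment_g > 0))
})

test_that("the default synthetic problem admits a feasible diet", {
  fx <- default_fixture()
  sc <- optimise_diet(fx$food, fx$cons, sex = "female")
  expect_true(sc$converged)
  expect_true(all(sc$constraint_report$ok))
})
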