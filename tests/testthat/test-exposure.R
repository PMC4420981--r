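fruit_chd <- list(rr = 0.93, rr_low = 0.89, rr_high = 0.96, increment_g = 80)

test_that("log-linear RR scaling hits the reference increment exactly", {
  expect_equal(scale_rr(fruit_chd, 80), 0.93)
  expect_equal(scale_rr(fruit_chd, 0), 1)
  fruit_stroke <- list(rr = 0.89, rr_low = 0.85, rr_high = 0.93,
                       increment_g = 80)
  expect_equal(scale_rr(fruit_stroke, 160), 0.89^2)
  expect_equal(scale_rr(fruit_chd, -80), 1 / 0.93, tolerance = 1e-14)
  expect_error(scale_rr(list(rr = -1, increment_g = 80), 10), "positive")
})

test_that("RR scaling is multiplicative over intake increments", {
  erfs <- generate_erf_table(synth_config())
  withr::with_seed(5, {
    for (i in 1:40) {
      row <- as.list(erfs[sample(nrow(erfs), 1), ])
      a <- runif(1, -200, 200)
      b <- runif(1, -200, 200)
      expect_equal(scale_rr(row, a + b),
                   scale_rr(row, a) * scale_rr(row, b),
                   tolerance = 1e-12)
    }
  })
})

test_that("effect direction follows RR and the sign of the change", {
  protective <- list(rr = 0.8, rr_low = 0.7, rr_high = 0.9, increment_g = 100)
  harmful <- list(rr = 1.3, rr_low = 1.1, rr_high = 1.5, increment_g = 100)
  expect_lt(scale_rr(protective, 50), 1)
  expect_gt(scale_rr(protective, -50), 1)
  expect_lt(scale_rr(harmful, -50), 1)
  expect_gt(scale_rr(harmful, 50), 1)
})

test_that("CI-based impact bounds pick near-1 (low) and far (high) bounds", {
  ## CI spanning 1: low-impact bound is the one nearer 1 on the log scale
  veg_stroke <- list(rr = 0.97, rr_low = 0.92, rr_high = 1.02,
                     increment_g = 80)
  expect_equal(scale_rr(veg_stroke, 80, which = "low"), 1.02)
  expect_equal(scale_rr(veg_stroke, 80, which = "high"), 0.92)
  expect_equal(scale_rr(fruit_chd, 80, which = "low"), 0.96)
  expect_equal(scale_rr(fruit_chd, 80, which = "high"), 0.89)
})

test_that("multipliers combine multiplicatively and commute", {
  expect_equal(combine_multipliers(numeric(0))$value, 1)
  expect_equal(combine_multipliers(c(0.93, 0.89))$value, 0.8277)
  expect_equal(combine_multipliers(c(0.89, 0.93))$value,
               combine_multipliers(c(0.93, 0.89))$value)
  expect_error(combine_multipliers(c(1, -0.5)), "positive")
})

test_that("exposure deltas sum tagged groups and ignore `other`", {
  fx <- default_fixture()
  sc <- optimise_diet(fx$food, fx$cons, sex = "male")
  dd <- deltas_from_scenario(sc)
  td <- tidy(sc)
  for (tag in c("fruit", "vegetable", "red_meat", "processed_meat")) {
    expect_equal(dd$delta_g[dd$exposure == tag],
                 sum(td$change_g[td$exposure == tag]))
  }
  expect_false("other" %in% dd$exposure)

  ## identity scenario: all deltas zero
  sc0 <- optimise_diet(dplyr::filter(fx$food, sex == "male"),
                       no_constraints())
  expect_equal(deltas_from_scenario(sc0)$delta_g,
               rep(0, 4), tolerance = 1e-4)
})

test_that("hazard multipliers combine ERFs within disease, honouring masks", {
  erfs <- generate_erf_table(synth_config())
  deltas <- tibble::tibble(sex = "male",
                           exposure = c("fruit", "vegetable", "red_meat",
                                        "processed_meat"),
                           delta_g = c(80, 80, -100, 0))
  hm <- hazard_multipliers(deltas, erfs)
  ## CHD: fruit 0.93 * vegetable 0.89 (processed-meat delta is 0)
  expect_equal(hm$value[hm$disease == "coronary_heart_disease"],
               0.93 * 0.89)
  ## stroke: fruit 0.89 * vegetable 0.97 * red meat 1.21^-1
  expect_equal(hm$value[hm$disease == "stroke"], 0.89 * 0.97 / 1.21)
  ## masking an exposure with zero delta changes nothing
  hm2 <- hazard_multipliers(deltas, erfs, mask_exposures = "processed_meat")
  expect_equal(hm2$value, hm$value)
  ## masking fruit removes the lung-cancer pathway entirely
  hm3 <- hazard_multipliers(deltas, erfs, mask_exposures = "fruit")
  expect_equal(hm3$value[hm3$disease == "lung_cancer"], 1)
  ## per-disease products of single-exposure runs reconstruct the joint one
  fr <- hazard_multipliers(deltas, erfs,
                           mask_exposures = c("vegetable", "red_meat",
                                              "processed_meat"))
  vg <- hazard_multipliers(deltas, erfs,
                           mask_exposures = c("fruit", "red_meat",
                                              "processed_meat"))
  mt <- hazard_multipliers(deltas, erfs, mask_exposures = c("fruit",
                                                            "vegetable"))
  expect_equal(fr$value * vg$value * mt$value, hm$value, tolerance = 1e-12)
})
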