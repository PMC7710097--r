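# Clinical scores: unit conversions, carry-forward imputation, daily and
# summed modified scores, the day-3 score, the composite risk score,
# regeneration and outcome labels.

test_that("unit converters are exact inverses", {
  x <- c(0, 0.1, 10, 19, 250)
  expect_equal(bilirubin_mgdl_to_umol(bilirubin_umol_to_mgdl(x)), x)
  expect_equal(creatinine_mgdl_to_umol(creatinine_umol_to_mgdl(x)), x)
  expect_equal(bilirubin_umol_to_mgdl(17.1), 1)
  expect_equal(creatinine_umol_to_mgdl(88.4), 1)
})

test_that("carry-forward imputation fills gaps from the previous day", {
  b <- bloods_df(c(1.1, 1.2), c(10, 12), c(70, 75), days = 1:2)
  out <- impute_carry_forward(b)
  expect_equal(out$bilirubin_umol_l, c(10, 12, 12, 12, 12))
  expect_equal(out$inr, c(1.1, 1.2, 1.2, 1.2, 1.2))
  expect_equal(out$imputed, c(FALSE, FALSE, TRUE, TRUE, TRUE))

  complete <- bloods_df(rep(1.1, 5), 10:14, rep(70, 5))
  out2 <- impute_carry_forward(complete)
  expect_false(any(out2$imputed))
  expect_equal(out2$bilirubin_umol_l, 10:14)

  only1 <- bloods_df(1.3, 20, 90, days = 1)
  out3 <- impute_carry_forward(only1)
  expect_equal(out3$creatinine_umol_l, rep(90, 5))
  expect_equal(sum(out3$imputed), 4)

  # interior gap as an NA row
  gap <- bloods_df(c(1, NA, 1.4), c(10, NA, 9), c(70, NA, 71), days = c(1, 3, 5))
  out4 <- impute_carry_forward(gap)
  expect_equal(out4$inr, c(1, 1, 1, 1, 1.4))
  expect_true(all(out4$imputed[c(2, 3, 4)]))
  expect_false(out4$imputed[5])
})

test_that("missing day 1 errors unless the pre-op fallback is enabled", {
  b <- bloods_df(1.2, 10, 70, days = 2)
  expect_error(impute_carry_forward(b), "day 1")
  pre <- bloods_df(1.0, 8, 65, days = 1)[, -1]
  out <- impute_carry_forward(b, preop = pre, allow_preop = TRUE)
  expect_equal(out$inr, c(1.0, 1.2, 1.2, 1.2, 1.2))
  expect_true(out$imputed_inr[1])
  expect_error(impute_carry_forward(bloods_df(1, 1, 1, days = 0)), "1..5")
})

test_that("daily modified score applies the published weights", {
  expect_equal(modified_hp_daily(0, 0, 0), 0)
  expect_equal(modified_hp_daily(1, 1, 1), 108.0)
  expect_equal(modified_hp_daily(1.2, bilirubin_umol_to_mgdl(10), 0.9),
               2.5 * 1.2 + 10 + 88.4 * 0.9, tolerance = 1e-12)
  expect_lt(abs(modified_hp_daily(1.2, 0.585, 0.9) - 92.56), 0.011)
  expect_error(modified_hp_daily(-0.1, 1, 1), "non-negative")
  # linearity per analyte
  expect_equal(modified_hp_daily(2, 0, 0), 2 * modified_hp_daily(1, 0, 0))
  expect_equal(modified_hp_daily(0, 3, 0), 3 * modified_hp_daily(0, 1, 0))
})

test_that("five-day sum composes with imputation", {
  expect_equal(modified_hp_sum(rep(108, 5)), 540)
  expect_equal(modified_hp_sum(c(100, 110, 120, 110, 100)), 540)
  expect_error(modified_hp_sum(c(100, 110)), "complete")
  b <- bloods_df(c(1, 1.1), c(17.1, 34.2), c(88.4, 88.4), days = 1:2)
  ser <- impute_carry_forward(b)
  manual <- modified_hp_daily(ser$inr,
                              bilirubin_umol_to_mgdl(ser$bilirubin_umol_l),
                              creatinine_umol_to_mgdl(ser$creatinine_umol_l))
  expect_equal(modified_hp_sum(ser), sum(manual))
  expect_error(modified_hp_sum(bloods_df(c(1, NA, 1, 1, 1), 1, 1)),
               "incomplete")
})

test_that("day-3 score needs an explicit Clavien-Dindo weight", {
  expect_error(hp_weights(), "Clavien-Dindo weight")
  expect_error(hp_day3(1, 1, 1, 2), "weights")
  w <- hp_weights(clavien = 2)
  expect_equal(hp_day3(0, 0, 0, 0, w)$score, 0)
  # zero Clavien weight reduces to the daily blood score
  w0 <- hp_weights(clavien = 0)
  expect_equal(hp_day3(1.2, 0.5, 0.8, 3, w0)$score,
               modified_hp_daily(1.2, 0.5, 0.8))
  expect_true(hp_day3(1, 0.1, 0.05, 0, w0, flag_threshold = 9)$score < 9)
  r <- hp_day3(2, 0.2, 0.03, 0, w0)        # score 11.072 > 9
  expect_true(r$flagged)
  expect_false(hp_day3(0, 0.5, 0.005, 0, w0)$flagged)   # 8.992 <= 9
  expect_error(hp_day3(1, 1, 1, 6, w), "0..5")
})

test_that("composite risk score matches the closed form and is monotone", {
  expect_equal(hepatica_score(80, 722.5), 0.4823, tolerance = 1e-4)
  zero <- hepatica_coefficients(0, 0, 0)
  expect_equal(hepatica_score(37, 950, zero), 1)
  expect_error(hepatica_score(0, 700), "flr_percent")
  expect_error(hepatica_score(80, -5), "ct1_ms")
  flr <- seq(20, 100, by = 5)
  expect_true(all(diff(hepatica_score(flr, 722.5)) > 0))
  ct1 <- seq(600, 1000, by = 20)
  expect_true(all(diff(hepatica_score(80, ct1)) < 0))
  expect_true(all(hepatica_score(runif(50, 1, 100), runif(50, 400, 1200)) > 0))
})

test_that("regeneration scores implement both definitions", {
  expect_equal(regeneration_score(1500, 1500), 1)
  expect_equal(regeneration_score(1500, 1450, 500, "resected_relative"), 0.9)
  expect_equal(regeneration_score(1200, 1000), 1.2)
  expect_error(regeneration_score(1500, 1450, mode = "resected_relative"),
               "resected_volume_ml")
  expect_error(regeneration_score(1500, 1450, 1600, "resected_relative"),
               "cannot exceed")
  expect_error(regeneration_score(-1, 5), "positive")
})

test_that("outcome labels: strict threshold and upper-quartile rules", {
  expect_identical(outcome_label(c(10, 22, 22.0001, 40)),
                   c(FALSE, FALSE, TRUE, TRUE))
  # P75 of {10,20,30,40} by linear interpolation is 37.5: only 40 flagged
  expect_identical(outcome_label(c(10, 20, 30, 40), "upper_quartile"),
                   c(FALSE, FALSE, FALSE, TRUE))
  expect_identical(outcome_label(rep(15, 6), "upper_quartile"),
                   rep(FALSE, 6))
  expect_error(outcome_label(c(1, 2, 3), "upper_quartile"), "4 patients")
})
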