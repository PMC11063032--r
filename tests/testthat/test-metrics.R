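test_that("mean germination time and rate follow the weighted-day formula", {
  # all 10 seeds on day 2
  expect_equal(mean_germination_time(make_tc(c(0, 10))), 2)
  # daily increments 5, 3, 2 on days 1..3
  tc <- make_tc(c(5, 8, 10))
  expect_equal(mean_germination_time(tc), 1.7)
  expect_equal(mean_germination_rate(tc), 1 / 1.7)
  # increments 1, 1 on days 1 and 3
  expect_equal(mean_germination_time(make_tc(c(1, 2), days = c(1, 3), n = 10)),
               2)
  # zero germination is an explicit undefined, which the rate propagates
  mgt <- mean_germination_time(make_tc(c(0, 0, 0)))
  expect_true(is_undefined(mgt))
  expect_equal(undefined_reason(mgt), "no_germination")
  expect_true(is_undefined(mean_germination_rate(make_tc(c(0, 0, 0)))))
})

test_that("germination energy sums percentage increments over day numbers", {
  expect_equal(germination_energy(make_tc(5, days = 1)), 50)
  expect_equal(germination_energy(make_tc(c(4, 7))), 40 / 1 + 30 / 2)
  expect_equal(germination_energy(make_tc(c(0, 0))), 0)
})

test_that("germination rate index supports both published forms", {
  expect_equal(germination_rate_index(make_tc(5, days = 1)), 50)
  tc <- make_tc(c(4, 7))
  expect_equal(germination_rate_index(tc, "standard"), 55)
  expect_equal(germination_rate_index(tc, "as_printed"), 35)
  expect_error(germination_rate_index(tc, "bogus"),
               class = "seedhtt_config_error")
})

test_that("germination index weights days 10 down to 1", {
  expect_equal(germination_index(make_tc(10, days = 1)), 100)
  expect_equal(germination_index(make_tc(c(2, 5))), 10 * 2 + 9 * 3)
  expect_equal(germination_index(make_tc(c(0, 0))), 0)
  # germination after day 10 gets weight zero, with a warning
  late <- make_tc(c(2, 2, 3), days = c(1, 10, 12))
  expect_warning(gi <- germination_index(late), "day 10")
  expect_equal(gi, 10 * 2 + 1 * 0 + 0 * 1)
})

test_that("Timson index sums carried-forward cumulative percentages", {
  expect_equal(timson_index(make_tc(10, days = 1)), 1000)
  expect_equal(timson_index(make_tc(c(5, 10)), window_days = 2), 150)
  expect_equal(timson_index(make_tc(c(0, 0))), 0)
  expect_error(timson_index(make_tc(c(0, 5)), window_days = 0),
               class = "seedhtt_invalid_input")
})

test_that("coefficient of velocity is 100 over MGT", {
  expect_equal(coefficient_velocity(make_tc(c(0, 10))), 50)
  expect_equal(coefficient_velocity(make_tc(c(5, 8, 10))), 100 / 1.7)
  expect_equal(coefficient_velocity(make_tc(10, days = 1)), 100)
  expect_true(is_undefined(coefficient_velocity(make_tc(c(0, 0)))))
})

test_that("T50 interpolates to half the final germinated count", {
  expect_equal(time_to_50(make_tc(c(0, 10))), 1.5)
  expect_equal(time_to_50(make_tc(c(5, 10))), 1)
  t50 <- time_to_50(make_tc(c(0, 4)))
  expect_true(is_undefined(t50))
  expect_equal(undefined_reason(t50), "final_fraction_below_half")
})

test_that("vigor indices scale seedling measures by germination percent", {
  tc <- make_tc(c(4, 8))  # 80% final germination
  sm <- seedling_measures(3, 2, 0.02)
  svi <- seed_vigor_indices(tc, sm)
  expect_equal(svi$svi_length, 400)
  expect_equal(svi$svi_weight, 0.02 * 80)
  expect_equal(seed_vigor_indices(make_tc(c(2, 5)), sm)$svi_weight, 1)
  none <- seed_vigor_indices(make_tc(c(0, 0)), sm)
  expect_equal(none$svi_length, 0)
  expect_equal(none$svi_weight, 0)
  expect_error(seedling_measures(-1, 2, 0.1),
               class = "seedhtt_invalid_input")
})

test_that("indices ignore observations appended after saturation", {
  tc <- make_tc(c(2, 7, 9))
  tc_ext <- make_tc(c(2, 7, 9, 9, 9), days = 1:5)
  for (f in list(mean_germination_time, germination_energy,
                 germination_rate_index, germination_index, timson_index,
                 coefficient_velocity, time_to_50, germination_percent)) {
    expect_equal(f(tc_ext), f(tc))
  }
})

test_that("per-dish indices do not depend on other dishes", {
  set.seed(42)
  for (i in 1:20) {
    counts <- cumsum(sample(0:3, 8, replace = TRUE))
    counts <- pmin(counts, 10)
    tc <- make_tc(counts, days = 1:8)
    rep1 <- index_report(tc)
    rep2 <- index_report(tc)  # identical dish replicated: same report
    expect_identical(rep1, rep2)
    if (counts[8] > 0) {
      mgt <- mean_germination_time(tc)
      expect_equal(mean_germination_rate(tc) * mgt, 1, tolerance = 1e-12)
      expect_equal(coefficient_velocity(tc),
                   100 * mean_germination_rate(tc), tolerance = 1e-12)
      expect_lte(germination_index(tc), 10 * tc$n_seeds)
      expect_lte(timson_index(tc, 10), 100 * 10)
    }
  }
})

test_that("index_report collects undefined reasons in the notes column", {
  rep0 <- index_report(make_tc(c(0, 0, 0)))
  expect_true(is.na(rep0$MGT_d))
  expect_match(rep0$notes, "MGT:no_germination")
  expect_match(rep0$notes, "T50:final_fraction_below_half")
  expect_equal(rep0$GI, 0)
  rep1 <- index_report(make_tc(c(5, 8, 10)), seedling_measures(3, 2, 0.02))
  expect_equal(rep1$notes, "")
  expect_equal(rep1$SVI_length, 500)
  expect_equal(rep1$germination_percent, 100)
})

test_that("non-integer observation days are floored with a warning", {
  tc <- germination_time_course(c(1.5, 2.5), c(5, 10), 10)
  expect_warning(mgt <- mean_germination_time(tc), "floored")
  expect_equal(mgt, (5 * 1 + 5 * 2) / 10)
})
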