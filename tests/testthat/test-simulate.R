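test_that("the same root seed reproduces the identical study", {
  cfg <- simulation_config(rng_seed = 7L)
  a <- simulate_study(cfg)
  b <- simulate_study(cfg)
  expect_identical(
    lapply(a$courses, `[[`, "cumulative_counts"),
    lapply(b$courses, `[[`, "cumulative_counts")
  )
  # per-dish substreams make grid subsets reproducible
  d <- simulate_dish(cfg, 25, -0.6, 2)
  expect_identical(d$cumulative_counts,
                   a$courses[["T25_psi-0.6_r2"]]$cumulative_counts)
  # and the global RNG stream is left untouched
  set.seed(99); before <- rnorm(3)
  set.seed(99); invisible(simulate_study(cfg)); after <- rnorm(3)
  expect_identical(before, after)
})

test_that("the default design yields the full grid of dishes", {
  st <- simulate_study(simulation_config())
  expect_length(st$courses, 4 * 5 * 3)
  expect_s3_class(st$courses[[1]], "germination_time_course")
  expect_identical(st$truth, simulation_config()$true_params)
})

test_that("a degenerate population germinates as one step at the shared tg", {
  p <- htt_params(thetaHTT = 408, Tb = 10, psib50 = -1.5,
                  sigma_psib = 1e-9, kT = 0, To = 1e6)
  cfg <- simulation_config(
    true_params = p, temperatures = 20, water_potentials = 0,
    n_replicates = 1, n_seeds_per_dish = 10,
    observation_times_h = c(24, 27.2001, 48)
  )
  d <- simulate_dish(cfg, 20, 0)
  # tg = 408 / ((0 - (-1.5)) * (20 - 10)) = 27.2 h for every seed
  expect_equal(d$cumulative_counts, c(0, 10, 10))
})

test_that("binomial sampling converges to the closed-form CDF", {
  p <- table3_params()
  for (mode in c("none", "binomial")) {
    cfg <- simulation_config(
      true_params = p, temperatures = c(15, 25), water_potentials = c(0, -0.6),
      n_replicates = 1, n_seeds_per_dish = 1e5, noise_mode = mode,
      rng_seed = 11L
    )
    assign(mode, simulate_study(cfg))
  }
  for (nm in names(none$courses)) {
    dev <- max(abs(cumulative_fraction(none$courses[[nm]]) -
                     cumulative_fraction(binomial$courses[[nm]])))
    expect_lte(dev, 0.01)
  }
  # at psi = psib50 (sub-optimal T) half the population germinates
  cfg <- simulation_config(true_params = p, temperatures = 15,
                           water_potentials = -0.87, n_replicates = 1,
                           n_seeds_per_dish = 1e5,
                           observation_times_h = c(24, 1e6), rng_seed = 3L)
  d <- simulate_dish(cfg, 15, -0.87)
  expect_equal(cumulative_fraction(d)[2], 0.5, tolerance = 0.01)
})

test_that("expected germination is ordered by water potential", {
  st <- noiseless_study(n_seeds = 1000)
  final <- vapply(st$courses, function(tc) rev(cumulative_fraction(tc))[1],
                  numeric(1))
  psis <- vapply(st$courses, `[[`, numeric(1), "water_potential")
  temps <- vapply(st$courses, `[[`, numeric(1), "temperature")
  for (tt in unique(temps)) {
    ord <- order(psis[temps == tt])
    expect_true(all(diff(final[temps == tt][ord]) >= 0))
  }
})

test_that("temperatures at or below Tb give all-zero dishes with a warning", {
  cfg <- simulation_config(temperatures = c(15, 20))
  expect_warning(d <- simulate_dish(cfg, 6.8, 0), "Tb")
  expect_equal(sum(d$cumulative_counts), 0)
})

test_that("configuration invariants are enforced", {
  expect_error(simulation_config(n_replicates = 0),
               class = "seedhtt_config_error")
  expect_error(simulation_config(water_potentials = c(0, 0.3)),
               class = "seedhtt_config_error")
  expect_error(simulation_config(observation_times_h = c(48, 24)),
               class = "seedhtt_config_error")
  expect_error(simulation_config(temperatures = numeric(0)),
               class = "seedhtt_config_error")
  expect_error(recovery_experiment(simulation_config(), n_repeats = 0),
               class = "seedhtt_config_error")
})

test_that("recovery reports compare estimates against the simulated truth", {
  cfg <- simulation_config(n_seeds_per_dish = 5000, n_replicates = 1,
                           noise_mode = "none")
  rec <- recovery_experiment(cfg, n_repeats = 1, fit = "htt")
  expect_equal(rec$n_failed, 0L)
  expect_equal(nrow(rec$estimates), 1L)
  expect_true(all(rec$summary$mean_abs_rel_error <= 0.01))
  rec_ht <- recovery_experiment(cfg, n_repeats = 1, fit = "hydrotime",
                                temperature = 20)
  expect_lt(rel_err(rec_ht$estimates$thetaH, 56.43), 0.01)
})
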