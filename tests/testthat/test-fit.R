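# Dish whose median germination time is exactly tg_h (hours): the 50%
# fraction falls on an observation.
step_course <- function(tg_h, temperature, psi = 0, n = 10) {
  germination_time_course(
    c(tg_h / 2, tg_h, tg_h * 2), c(0, n / 2, n), n,
    temperature = temperature, water_potential = psi,
    replicate_id = sprintf("T%g", temperature), units = "hours"
  )
}

test_that("thermal fit recovers both branches exactly from noiseless rates", {
  # sub-optimal line: GR = (T - 10)/300; supra: GR = (45 - T)/400;
  # the lines intersect at T = 25, which sits on the grid.
  courses <- c(
    lapply(c(15, 20, 25), function(tt) step_course(300 / (tt - 10), tt)),
    lapply(c(30, 35), function(tt) step_course(400 / (45 - tt), tt))
  )
  fit <- fit_thermal(courses)
  expect_equal(fit$Tb, 10, tolerance = 1e-6)
  expect_equal(fit$Tc, 45, tolerance = 1e-6)
  expect_equal(fit$To, 25, tolerance = 1e-6)
  expect_equal(fit$thetaT1, 300, tolerance = 1e-6)
  expect_equal(fit$thetaT2, 400, tolerance = 1e-6)
  expect_equal(fit$diagnostics$r_squared_sub, 1, tolerance = 1e-9)
})

test_that("thermal fit handles sub-optimal-only data and tiny inputs", {
  sub_only <- lapply(c(10, 15, 20), function(tt) {
    step_course(300 / (tt - 6.8), tt)
  })
  expect_warning(fit <- fit_thermal(sub_only), "supra")
  expect_equal(fit$Tb, 6.8, tolerance = 1e-6)
  expect_equal(fit$thetaT1, 300, tolerance = 1e-6)
  expect_true(is.na(fit$Tc))
  expect_error(fit_thermal(list(step_course(30, 20))),
               class = "seedhtt_fit_error")
  # rates decreasing with temperature on the cold branch cannot be thermal
  bad <- lapply(c(12, 16, 20), function(tt) step_course(10 * tt, tt))
  expect_error(fit_thermal(bad), class = "seedhtt_fit_error")
})

test_that("hydrotime probit fit recovers known population parameters", {
  courses <- hydrotime_fixture(56.43, -0.87, 0.20)
  fit <- fit_hydrotime_probit(courses)
  expect_lt(rel_err(fit$theta_h, 56.43), 0.01)
  expect_lt(rel_err(fit$psib50, -0.87), 0.01)
  expect_lt(rel_err(fit$sigma_psib, 0.20), 0.01)
  expect_gte(fit$diagnostics$r_squared, 0.999)
})

test_that("hydrotime fit flags data with no water-potential signal", {
  flat <- lapply(c(0, -0.3, -0.6), function(psi) {
    make_tc(c(5, 5, 5), temperature = 20, water_potential = psi,
            replicate_id = sprintf("psi%g", psi))
  })
  expect_warning(fit <- fit_hydrotime_probit(flat), "sigma_psib")
  expect_true(fit$degenerate)
  expect_true(is.infinite(fit$sigma_psib))
  # all fractions at the boundaries leave nothing to regress
  allout <- lapply(c(0, -0.3, -0.6), function(psi) {
    make_tc(c(0, 10, 10), temperature = 20, water_potential = psi)
  })
  expect_error(fit_hydrotime_probit(allout), class = "seedhtt_fit_error")
  expect_error(
    fit_hydrotime_probit(hydrotime_fixture(50, -1, 0.2, psis = c(0, -0.3))),
    class = "seedhtt_fit_error"
  )
})

test_that("joint HTT fit recovers the generating parameters from a noiseless grid", {
  truth <- table3_params()
  fit <- fit_htt(noiseless_study())
  expect_lt(rel_err(fit$params$thetaHTT, truth$thetaHTT), 0.01)
  expect_lt(rel_err(fit$params$Tb, truth$Tb), 0.01)
  expect_lt(rel_err(fit$params$psib50, truth$psib50), 0.01)
  expect_lt(rel_err(fit$params$sigma_psib, truth$sigma_psib), 0.01)
  expect_lt(rel_err(fit$params$kT, truth$kT), 0.01)
  expect_gte(fit$diagnostics$r_squared, 0.999)
  expect_equal(fit$params$To, 20)
  expect_equal(fit$theta_h, fit$params$thetaHTT / (20 - fit$params$Tb))
})

test_that("kT is recovered as ~0 when the truth has no supra-optimal shift", {
  p <- htt_params(thetaHTT = 600, Tb = 8, psib50 = -0.9, sigma_psib = 0.2,
                  kT = 0, To = 20)
  st <- noiseless_study(params = p)
  fit <- fit_htt(st, To = 20)
  expect_lte(fit$params$kT, 0.005)
})

test_that("kT is fixed at zero when no supra-optimal temperatures exist", {
  p <- table3_params()
  cfg <- simulation_config(true_params = p, temperatures = c(12, 16, 20),
                           n_replicates = 1, n_seeds_per_dish = 2000,
                           noise_mode = "none")
  expect_warning(fit <- fit_htt(simulate_study(cfg)), "kT fixed at 0")
  expect_equal(fit$params$kT, 0)
})

test_that("grid-scan theta_h matches an independent brute-force scan", {
  courses <- hydrotime_fixture(40, -1, 0.25)
  fit <- fit_hydrotime_probit(courses)
  pts <- fit$points
  z <- qnorm(pts$g)
  scan <- seq(0.3 * 40, 3 * 40, length.out = 1200)
  r2 <- vapply(scan, function(th) {
    x <- pts$psi - th / pts$t_h
    suppressWarnings(cor(x, z)^2)
  }, numeric(1))
  expect_lte(abs(fit$theta_h - scan[which.max(r2)]), diff(scan[1:2]))
})

test_that("the time-constant grid applies the threshold relations per cell", {
  tg_tab <- data.frame(temperature = 20, psi = 0, tg_h = 27.2)
  row <- table1_grid(tg_table = tg_tab, Tb = 10, Tc = 45, psib = -1.5)
  expect_equal(nrow(row), 1L)
  expect_equal(row$tt_sub, 272)
  expect_equal(row$tt_supra, 680)
  expect_equal(row$theta_htt, 408)
  expect_equal(row$theta_h, 40.8)
  expect_equal(row$gr, 1 / 27.2)
  # psi at the base potential: hydro cells undefined
  dry <- table1_grid(
    tg_table = data.frame(temperature = 20, psi = -1.5, tg_h = 30),
    Tb = 10, Tc = 45, psib = -1.5
  )
  expect_true(is.na(dry$theta_h))
  expect_true(is.na(dry$theta_htt))
  expect_false(is.na(dry$tt_sub))
  # missing tg propagates as undefined markers, row retained
  miss <- table1_grid(
    tg_table = data.frame(temperature = c(20, 25), psi = 0,
                          tg_h = c(27.2, NA)),
    Tb = 10, Tc = 45, psib = -1.5
  )
  expect_equal(nrow(miss), 2L)
  expect_true(all(is.na(unlist(miss[miss$temperature == 25,
                                    c("tt_sub", "theta_htt", "gr")]))))
})
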