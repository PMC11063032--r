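#' Simulation configuration
#'
#' Defines a dish-level germination experiment generated from the
#' hydrothermal-time population model. Defaults reproduce the standard
#' design for sunflower: 4 temperatures (15, 20, 25, 30 degC) x 5 water
#' potentials (0 to -1.2 MPa in 0.3 MPa steps of PEG-6000 osmoticum) x 3
#' replicate dishes of 10 seeds, counted daily for 10 days, with population
#' parameters psib50 = -0.87 MPa, sigma_psib = 0.20 MPa, Tb = 6.8 degC,
#' To = 20 degC, kT = 0.104 MPa/degC and thetaHTT = 56.43 * (20 - 6.8)
#' MPa-degC-h.
#'
#' @param true_params An [htt_params()] object.
#' @param temperatures Incubation temperatures, degC.
#' @param water_potentials Water potentials, MPa (<= 0).
#' @param n_replicates Replicate dishes per treatment (>= 1).
#' @param n_seeds_per_dish Seeds per dish (>= 1).
#' @param observation_times_h Strictly increasing observation times, hours.
#' @param rng_seed Integer root seed; per-dish substreams are derived
#'   deterministically from (seed, T, psi, replicate) so that any grid
#'   subset is reproducible.
#' @param noise_mode `"binomial"` (each seed draws its own base water
#'   potential) or `"none"` (expected counts from the closed-form CDF,
#'   rounded).
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(
    true_params = htt_params(thetaHTT = 56.43 * (20 - 6.8), Tb = 6.8,
                             psib50 = -0.87, sigma_psib = 0.20,
                             kT = 0.104, To = 20),
    temperatures = c(15, 20, 25, 30),
    water_potentials = c(0, -0.3, -0.6, -0.9, -1.2),
    n_replicates = 3,
    n_seeds_per_dish = 10,
    observation_times_h = seq(24, 240, by = 24),
    rng_seed = 1L,
    noise_mode = c("binomial", "none")) {
  noise_mode <- match.arg(noise_mode)
  if (!inherits(true_params, "htt_params")) {
    abort_config("`true_params` must be an `htt_params` object.")
  }
  if (length(temperatures) < 1L || length(water_potentials) < 1L) {
    abort_config("the treatment grid must be non-empty.")
  }
  if (any(water_potentials > 0)) {
    abort_config("`water_potentials` must be <= 0 MPa.")
  }
  if (n_replicates < 1L || n_replicates %% 1 != 0) {
    abort_config("`n_replicates` must be a positive integer.")
  }
  if (n_seeds_per_dish < 1L || n_seeds_per_dish %% 1 != 0) {
    abort_config("`n_seeds_per_dish` must be a positive integer.")
  }
  if (length(observation_times_h) < 1L || any(observation_times_h <= 0) ||
      (length(observation_times_h) > 1L &&
       any(diff(observation_times_h) <= 0))) {
    abort_config("`observation_times_h` must be positive and strictly increasing.")
  }
  structure(
    list(
      true_params = true_params,
      temperatures = temperatures,
      water_potentials = water_potentials,
      n_replicates = as.integer(n_replicates),
      n_seeds_per_dish = as.integer(n_seeds_per_dish),
      observation_times_h = observation_times_h,
      rng_seed = as.integer(rng_seed),
      noise_mode = noise_mode
    ),
    class = "simulation_config"
  )
}

# Deterministic per-dish substream seed from (root, T, psi, replicate):
# a rolling polynomial hash of the treatment key mixed with the root seed,
# kept below 2^31.
dish_seed <- function(root, temperature, psi, replicate) {
  key <- sprintf("%.6g|%.6g|%s", temperature, psi, as.character(replicate))
  m <- 2147483629
  h <- 0
  for (ch in utf8ToInt(key)) h <- (h * 131 + ch) %% m
  as.integer((h + (as.numeric(root) %% m) * 48271) %% m)
}

with_preserved_rng <- function(code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  force(code)
}

#' Simulate one dish
#'
#' Each seed draws a base water potential
#' `psib ~ N(psib50 + kT * max(0, T - To), sigma_psib)`. A seed with
#' `psi > psib` germinates at `tg = thetaHTT / ((psi - psib)(T - Tb))`
#' hours; seeds with `psi <= psib` never germinate. Cumulative counts are
#' recorded at the configured observation times. With
#' `noise_mode = "none"` the expected counts (rounded) from the closed-form
#' normal CDF are returned instead.
#'
#' @param config A [simulation_config()].
#' @param temperature,psi Treatment, degC and MPa.
#' @param replicate Replicate index or label (selects the RNG substream).
#' @return A [germination_time_course()].
#' @export
simulate_dish <- function(config, temperature, psi, replicate = 1L) {
  if (!inherits(config, "simulation_config")) {
    abort_config("`config` must be a `simulation_config`.")
  }
  p <- config$true_params
  n <- config$n_seeds_per_dish
  t_h <- config$observation_times_h
  rep_id <- sprintf("T%g_psi%g_r%s", temperature, psi,
                    as.character(replicate))
  if (temperature <= p$Tb) {
    warning("temperature at or below Tb: dish never germinates",
            call. = FALSE)
    counts <- rep(0L, length(t_h))
  } else if (config$noise_mode == "none") {
    counts <- round(n * predict_time_course(p, temperature, psi, t_h))
  } else {
    counts <- with_preserved_rng({
      set.seed(dish_seed(config$rng_seed, temperature, psi, replicate))
      mu <- p$psib50 + p$kT * max(0, temperature - p$To)
      psib <- rnorm(n, mu, p$sigma_psib)
      tg <- ifelse(psi > psib,
                   p$thetaHTT / ((psi - psib) * (temperature - p$Tb)),
                   Inf)
      vapply(t_h, function(t) sum(tg <= t), numeric(1))
    })
  }
  germination_time_course(
    t_h, counts, n,
    temperature = temperature, water_potential = psi,
    replicate_id = rep_id, units = "hours"
  )
}

#' Simulate a full study
#'
#' Generates the whole temperature x water potential x replicate grid,
#' reproducibly from the config's root seed, and keeps the generating
#' parameters as a truth record for recovery scoring.
#'
#' @param config A [simulation_config()].
#' @return An object of class `germination_study`: a named list of
#'   [germination_time_course()] objects (`courses`), the `truth`
#'   parameters, and the `config`.
#' @export
simulate_study <- function(config) {
  if (!inherits(config, "simulation_config")) {
    abort_config("`config` must be a `simulation_config`.")
  }
  courses <- list()
  for (temp in config$temperatures) {
    for (psi in config$water_potentials) {
      for (r in seq_len(config$n_replicates)) {
        tc <- simulate_dish(config, temp, psi, r)
        courses[[tc$replicate_id]] <- tc
      }
    }
  }
  structure(
    list(courses = courses, truth = config$true_params, config = config),
    class = "germination_study"
  )
}

#' @export
print.germination_study <- function(x, ...) {
  cat(sprintf("<germination_study> %d dishes\n", length(x$courses)))
  if (!is.null(x$truth)) cat("  (simulated; truth record attached)\n")
  invisible(x)
}

# Accept either a germination_study or a bare list of time courses.
study_courses <- function(x) {
  if (inherits(x, "germination_study")) return(x$courses)
  if (is_time_course(x)) return(list(x))
  if (is.list(x)) return(x)
  abort_invalid("expected a germination_study or a list of time courses.")
}

#' Parameter-recovery experiment
#'
#' Simulates `n_repeats` studies from the configured truth, fits the
#' requested model to each, and reports per-parameter recovery (bias, RMSE,
#' mean absolute relative error). Fit failures are counted, not raised.
#'
#' @param config A [simulation_config()].
#' @param n_repeats Number of Monte-Carlo repeats (>= 1).
#' @param fit `"htt"` (joint fit across the grid) or `"hydrotime"` (single
#'   temperature, requires `temperature`).
#' @param temperature Temperature at which to fit when `fit = "hydrotime"`.
#' @return An object of class `recovery_report` with `estimates` (one row
#'   per successful repeat), `summary` (per-parameter recovery) and
#'   `n_failed`.
#' @export
recovery_experiment <- function(config, n_repeats = 50,
                                fit = c("htt", "hydrotime"),
                                temperature = NULL) {
  fit <- match.arg(fit)
  if (!inherits(config, "simulation_config")) {
    abort_config("`config` must be a `simulation_config`.")
  }
  if (n_repeats < 1L || n_repeats %% 1 != 0) {
    abort_config("`n_repeats` must be a positive integer.")
  }
  truth <- config$true_params
  est <- vector("list", n_repeats)
  n_failed <- 0L
  for (i in seq_len(n_repeats)) {
    cfg_i <- config
    cfg_i$rng_seed <- as.integer(
      (as.numeric(config$rng_seed) + 104729 * i) %% 2147483647
    )
    study <- simulate_study(cfg_i)
    res <- tryCatch({
      if (fit == "htt") {
        f <- fit_htt(study)
        data.frame(
          repeat_i = i,
          thetaHTT = f$params$thetaHTT, Tb = f$params$Tb,
          psib50 = f$params$psib50, sigma_psib = f$params$sigma_psib,
          kT = f$params$kT, r_squared = f$diagnostics$r_squared
        )
      } else {
        if (is.null(temperature)) {
          abort_config("`temperature` is required for hydrotime recovery.")
        }
        cs <- Filter(function(tc) tc$temperature == temperature,
                     study$courses)
        f <- fit_hydrotime_probit(cs)
        data.frame(
          repeat_i = i,
          thetaH = f$theta_h, psib50 = f$psib50,
          sigma_psib = f$sigma_psib, r_squared = f$diagnostics$r_squared
        )
      }
    }, error = function(e) NULL)
    if (is.null(res)) n_failed <- n_failed + 1L else est[[i]] <- res
  }
  estimates <- do.call(rbind, est)
  truth_vec <- c(
    thetaHTT = truth$thetaHTT, Tb = truth$Tb, psib50 = truth$psib50,
    sigma_psib = truth$sigma_psib, kT = truth$kT,
    thetaH = truth$thetaHTT / (truth$To - truth$Tb)
  )
  params <- intersect(names(truth_vec), names(estimates))
  summ <- do.call(rbind, lapply(params, function(pn) {
    e <- estimates[[pn]]
    tv <- truth_vec[[pn]]
    data.frame(
      parameter = pn, truth = tv, mean_estimate = mean(e),
      bias = mean(e) - tv, rmse = sqrt(mean((e - tv)^2)),
      mean_abs_rel_error = if (tv != 0) mean(abs(e - tv) / abs(tv)) else
        mean(abs(e))
    )
  }))
  structure(
    list(estimates = estimates, summary = summ, n_failed = n_failed,
         truth = truth, fit = fit),
    class = "recovery_report"
  )
}

#' @export
print.recovery_report <- function(x, ...) {
  cat(sprintf("<recovery_report> fit = %s, %d successful repeats, %d failed\n",
              x$fit, nrow(x$estimates), x$n_failed))
  print(x$summary, row.names = FALSE, digits = 4)
  invisible(x)
}
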