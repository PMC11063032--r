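# Shared fixtures, all built in code.

# Published grid of thermal/hydro/hydrothermal time constants for sunflower
# germination across 4 temperatures x 5 water potentials (hours units),
# shipped as a plain-text reference.
ref_grid <- function() {
  read.csv(system.file("extdata", "sunflower_reference_grid.csv",
                       package = "seedhtt"))
}

# Published population parameters for sunflower: psib50 = -0.87 MPa,
# sigma_psib = 0.20 MPa, thetaH = 56.43 MPa.h at To = 20 degC, Tb = 6.8 degC,
# kT = 0.104 MPa/degC; thetaHTT = thetaH * (To - Tb).
table3_params <- function() {
  htt_params(thetaHTT = 56.43 * (20 - 6.8), Tb = 6.8, psib50 = -0.87,
             sigma_psib = 0.20, kT = 0.104, To = 20)
}

# Dish with daily counts (days 1, 2, ...).
make_tc <- function(counts, days = seq_along(counts), n = 10, ...) {
  germination_time_course(days, counts, n, ...)
}

# High-resolution deterministic study at the published parameters.
noiseless_study <- function(n_seeds = 5000, params = table3_params()) {
  simulate_study(simulation_config(
    true_params = params, n_replicates = 1, n_seeds_per_dish = n_seeds,
    noise_mode = "none"
  ))
}

# Noiseless single-temperature hydrotime fixture (kT = 0).
hydrotime_fixture <- function(theta_h, psib50, sigma, temperature = 20,
                              Tb = 10, n_seeds = 2000,
                              psis = c(0, -0.3, -0.6, -0.9, -1.2)) {
  p <- htt_params(thetaHTT = theta_h * (temperature - Tb), Tb = Tb,
                  psib50 = psib50, sigma_psib = sigma, kT = 0, To = 1e6)
  cfg <- simulation_config(
    true_params = p, temperatures = temperature, water_potentials = psis,
    n_replicates = 1, n_seeds_per_dish = n_seeds, noise_mode = "none"
  )
  simulate_study(cfg)$courses
}

rel_err <- function(est, truth) abs(est - truth) / abs(truth)
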