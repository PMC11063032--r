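#' Sub-optimal thermal time
#'
#' `TTsub = (T - Tb) * tg`: degree-hours accumulated above the base
#' temperature over the germination time of a seed fraction.
#'
#' @param temperature Incubation temperature T, degC (must exceed `Tb`).
#' @param Tb Base temperature, degC.
#' @param tg Germination time of the fraction, hours (> 0).
#' @return Thermal time in degC-hours.
#' @export
tt_sub <- function(temperature, Tb, tg) {
  if (any(tg <= 0)) abort_domain("`tg` must be positive.")
  if (any(temperature <= Tb)) {
    abort_domain("sub-optimal thermal time requires T > Tb.")
  }
  (temperature - Tb) * tg
}

#' Supra-optimal thermal time
#'
#' `TTsupra = (Tc - T) * tg`: degree-hours below the ceiling temperature.
#'
#' @param temperature Incubation temperature T, degC (must be below `Tc`).
#' @param Tc Ceiling temperature, degC.
#' @inheritParams tt_sub
#' @return Thermal time in degC-hours.
#' @export
tt_supra <- function(temperature, Tc, tg) {
  if (any(tg <= 0)) abort_domain("`tg` must be positive.")
  if (any(temperature >= Tc)) {
    abort_domain("supra-optimal thermal time requires T < Tc.")
  }
  (Tc - temperature) * tg
}

#' Thermal-time germination rate
#'
#' `GR = 1/tg = (T - Tb) / thetaT1`: at sub-optimal temperatures the
#' germination rate of a fraction is linear in temperature, with slope
#' `1/thetaT1` and x-intercept `Tb`.
#'
#' @inheritParams tt_sub
#' @param thetaT1 Sub-optimal thermal time constant, degC-hours (> 0).
#' @return Germination rate in 1/h (0 at `T = Tb`).
#' @export
gr_thermal <- function(temperature, Tb, thetaT1) {
  if (any(thetaT1 <= 0)) abort_domain("`thetaT1` must be positive.")
  pmax(0, temperature - Tb) / thetaT1
}

#' Hydrotime constant for a seed fraction
#'
#' `thetaH(g) = (psi - psi_b(g)) * tg`: MPa-hours accumulated above the
#' fraction's base water potential.
#'
#' @param psi Ambient water potential, MPa.
#' @param psib Base water potential of the fraction, MPa (must be below
#'   `psi`).
#' @inheritParams tt_sub
#' @return Hydrotime in MPa-hours.
#' @export
hydrotime_theta <- function(psi, psib, tg) {
  if (any(tg <= 0)) abort_domain("`tg` must be positive.")
  if (any(psi <= psib)) {
    abort_domain("hydrotime requires psi > psib (the fraction germinates).")
  }
  (psi - psib) * tg
}

#' Hydrotime germination rate
#'
#' `GR(g) = 1/tg = (psi - psib) / thetaH`, zero when `psi <= psib` (that
#' seed fraction never germinates).
#'
#' @inheritParams hydrotime_theta
#' @param thetaH Hydrotime constant, MPa-hours (> 0).
#' @return Germination rate in 1/h.
#' @export
gr_hydro <- function(psi, psib, thetaH) {
  if (any(thetaH <= 0)) abort_domain("`thetaH` must be positive.")
  pmax(0, psi - psib) / thetaH
}

#' Hydrothermal time for a seed fraction
#'
#' `thetaHTT = (psi - psib) * (T - Tb) * tg`, the joint suprathreshold
#' water-potential x temperature x time accumulation. (Both factors are
#' taken as positive magnitudes above their thresholds.)
#'
#' @inheritParams hydrotime_theta
#' @inheritParams tt_sub
#' @return Hydrothermal time in MPa-degC-hours.
#' @export
theta_htt <- function(psi, psib, temperature, Tb, tg) {
  if (any(tg <= 0)) abort_domain("`tg` must be positive.")
  if (any(psi <= psib)) abort_domain("hydrothermal time requires psi > psib.")
  if (any(temperature <= Tb)) {
    abort_domain("hydrothermal time requires T > Tb.")
  }
  (psi - psib) * (temperature - Tb) * tg
}

#' Hydrothermal-time model parameters
#'
#' The population model: each seed's base water potential is normally
#' distributed with median `psib50` and spread `sigma_psib`; above the
#' optimum temperature `To` the median shifts upward at `kT` MPa per degC.
#' A seed (fraction `g`) germinates when it accumulates `thetaHTT`
#' MPa-degC-hours above its thresholds.
#'
#' @param thetaHTT Hydrothermal time constant, MPa-degC-hours (> 0).
#' @param Tb Base temperature, degC.
#' @param psib50 Median base water potential, MPa (< 0).
#' @param sigma_psib Standard deviation of the base water potential, MPa
#'   (> 0).
#' @param kT Supra-optimal shift rate of `psib50`, MPa/degC (>= 0).
#' @param To Optimum temperature, degC (> `Tb`).
#' @return An object of class `htt_params`.
#' @export
htt_params <- function(thetaHTT, Tb, psib50, sigma_psib, kT = 0, To = Inf) {
  if (thetaHTT <= 0) abort_invalid("`thetaHTT` must be positive.")
  if (sigma_psib <= 0) abort_invalid("`sigma_psib` must be positive.")
  if (psib50 >= 0) abort_invalid("`psib50` must be negative.")
  if (kT < 0) abort_invalid("`kT` must be non-negative.")
  if (To <= Tb) abort_invalid("`To` must exceed `Tb`.")
  structure(
    list(thetaHTT = thetaHTT, Tb = Tb, psib50 = psib50,
         sigma_psib = sigma_psib, kT = kT, To = To),
    class = "htt_params"
  )
}

#' @export
print.htt_params <- function(x, ...) {
  cat("<htt_params>\n")
  cat(sprintf("  thetaHTT   %.4g MPa.degC.h\n", x$thetaHTT))
  cat(sprintf("  Tb         %.4g degC\n", x$Tb))
  cat(sprintf("  psib50     %.4g MPa\n", x$psib50))
  cat(sprintf("  sigma_psib %.4g MPa\n", x$sigma_psib))
  cat(sprintf("  kT         %.4g MPa/degC\n", x$kT))
  cat(sprintf("  To         %.4g degC\n", x$To))
  invisible(x)
}

# Effective water potential: above To the base-water-potential median
# shifts up by kT per degC, equivalently the ambient psi is reduced.
psi_effective <- function(psi, temperature, kT, To) {
  psi - kT * pmax(0, temperature - To)
}

#' Predict a cumulative germination time course
#'
#' Inverts the hydrothermal-time population model for the germinated
#' fraction at each time:
#' `g(t) = Phi((psi_eff - thetaHTT / ((T - Tb) t) - psib50) / sigma_psib)`
#' with `psi_eff = psi - kT * max(0, T - To)` and `Phi` the standard normal
#' CDF. Non-decreasing in `t`, with asymptote
#' `Phi((psi_eff - psib50) / sigma_psib)`.
#'
#' @param params An [htt_params()] object.
#' @param temperature Incubation temperature, degC.
#' @param psi Water potential, MPa.
#' @param times_h Times at which to evaluate, hours.
#' @return Vector of predicted cumulative germinated fractions.
#' @export
predict_time_course <- function(params, temperature, psi, times_h) {
  if (!inherits(params, "htt_params")) {
    abort_invalid("`params` must be an `htt_params` object.")
  }
  if (temperature <= params$Tb) {
    warning("temperature at or below Tb: predicting zero germination",
            call. = FALSE)
    return(rep(0, length(times_h)))
  }
  psi_eff <- psi_effective(psi, temperature, params$kT, params$To)
  accum <- params$thetaHTT / ((temperature - params$Tb) * times_h)
  pnorm((psi_eff - accum - params$psib50) / params$sigma_psib)
}
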