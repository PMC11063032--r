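# Build the (temperature, psi, t_h, g) observation table used by the
# probit fits. Replicate dishes sharing a (T, psi, time) cell are pooled
# (counts and seeds summed). Boundary fractions (0 or 1) carry no probit
# information; by default they are excluded, alternatively adjusted by
# 0.5/(2n) into the open interval.
probit_points <- function(courses, boundary = c("exclude", "adjust")) {
  boundary <- match.arg(boundary)
  courses <- lapply(study_courses(courses), assert_time_course)
  rows <- lapply(courses, function(tc) {
    data.frame(
      temperature = tc$temperature,
      psi = tc$water_potential,
      t_h = times_hours(tc),
      count = tc$cumulative_counts,
      n = tc$n_seeds
    )
  })
  df <- do.call(rbind, rows)
  pooled <- aggregate(df[c("count", "n")],
                      by = df[c("temperature", "psi", "t_h")], FUN = sum)
  g <- pooled$count / pooled$n
  if (boundary == "adjust") {
    adj <- 0.5 / (2 * pooled$n)
    g[g <= 0] <- adj[g <= 0]
    g[g >= 1] <- (1 - adj)[g >= 1]
  }
  keep <- g > 0 & g < 1
  out <- pooled[keep, c("temperature", "psi", "t_h")]
  out$g <- g[keep]
  out[order(out$temperature, out$psi, out$t_h), , drop = FALSE]
}

probit_r_squared <- function(x, z) {
  if (length(x) < 3L || var(x) < 1e-14 || var(z) < 1e-14) return(0)
  fit <- lm(z ~ x)
  summary(fit)$r.squared
}

fit_diagnostics <- function(fit, n) {
  s <- summary(fit)
  fstat <- if (is.null(s$fstatistic)) NA_real_ else unname(s$fstatistic[1L])
  pval <- if (is.null(s$fstatistic)) NA_real_ else
    unname(stats::pf(s$fstatistic[1L], s$fstatistic[2L], s$fstatistic[3L],
                     lower.tail = FALSE))
  list(
    r_squared = s$r.squared,
    F_statistic = fstat,
    standard_error = s$sigma,
    significance = pval,
    n = n
  )
}

#' Fit the hydrotime model at one temperature (repeated probit regression)
#'
#' For each candidate hydrotime constant `thetaH`, the probit-transformed
#' germinated fractions are regressed on
#' `x = psi - thetaH / tg` over all (water potential, time) observations;
#' the `thetaH` maximizing R-squared is selected by a log-spaced grid scan
#' followed by golden-section refinement. The final probit line gives
#' `psib50` (the `x` at probit 0) and `sigma_psib = 1/slope`.
#'
#' @param courses Time courses at a single temperature spanning >= 3 water
#'   potentials (a `germination_study` restricted to one temperature also
#'   works).
#' @param boundary Handling of fractions 0/1: `"exclude"` (default) or
#'   `"adjust"` (shift by `0.5/(2n)`).
#' @param grid_n Number of grid candidates for `thetaH` (default 500).
#' @param grid_span Multiplicative span of the grid around the initial
#'   moment-based guess (default 10, i.e. 0.1x to 10x).
#' @return An object of class `hydrotime_fit`: `theta_h` (MPa-h), `psib50`
#'   (MPa), `sigma_psib` (MPa), `temperature`, `diagnostics` (R-squared, F,
#'   SE, significance, n) and the observation table.
#' @export
fit_hydrotime_probit <- function(courses, boundary = c("exclude", "adjust"),
                                 grid_n = 500, grid_span = 10) {
  boundary <- match.arg(boundary)
  courses <- study_courses(courses)
  temps <- unique(vapply(courses, `[[`, numeric(1), "temperature"))
  if (length(temps) != 1L) {
    abort_invalid("hydrotime fit expects courses at a single temperature.")
  }
  psis <- unique(vapply(courses, `[[`, numeric(1), "water_potential"))
  if (length(psis) < 3L) {
    abort_fit("hydrotime fit needs >= 3 water potentials.")
  }
  pts <- probit_points(courses, boundary)
  if (nrow(pts) < 3L) {
    abort_fit("no probit-transformable data (all fractions 0 or 1).")
  }
  z <- qnorm(pts$g)

  theta0 <- hydrotime_theta_init(courses, pts)
  grid <- exp(seq(log(theta0 / grid_span), log(theta0 * grid_span),
                  length.out = grid_n))
  r2 <- vapply(grid, function(th) {
    probit_r_squared(pts$psi - th / pts$t_h, z)
  }, numeric(1))
  best <- which.max(r2)  # first max: ties break toward the smaller thetaH
  lo <- grid[max(1L, best - 1L)]
  hi <- grid[min(grid_n, best + 1L)]
  ref <- optimize(function(th) probit_r_squared(pts$psi - th / pts$t_h, z),
                  interval = c(lo, hi), maximum = TRUE, tol = 1e-9)
  theta_h <- if (ref$objective >= r2[best]) ref$maximum else grid[best]

  fit <- lm(z ~ x, data = data.frame(x = pts$psi - theta_h / pts$t_h, z = z))
  slope <- unname(coef(fit)[2L])
  intercept <- unname(coef(fit)[1L])
  degenerate <- !is.finite(slope) || slope <= 1e-10
  if (degenerate) {
    warning("no water-potential signal in probit regression; ",
            "sigma_psib -> Inf", call. = FALSE)
  }
  structure(
    list(
      theta_h = theta_h,
      psib50 = if (degenerate) NA_real_ else -intercept / slope,
      sigma_psib = if (degenerate) Inf else 1 / slope,
      temperature = temps,
      degenerate = degenerate,
      diagnostics = fit_diagnostics(fit, nrow(pts)),
      points = pts
    ),
    class = "hydrotime_fit"
  )
}

# Moment-based initial guess for thetaH: germination rates of the median
# fraction are linear in psi with slope 1/thetaH, so a line through the
# observed GR(50) values gives the scale. Falls back to a crude
# suprathreshold-psi x time product when fewer than two t50s exist.
hydrotime_theta_init <- function(courses, pts) {
  by_psi <- split(courses, vapply(courses, `[[`, numeric(1),
                                  "water_potential"))
  gr <- do.call(rbind, lapply(by_psi, function(cs) {
    tg <- interpolate_tg(pool_courses(cs), 0.5)
    if (is_undefined(tg) || tg <= 0) return(NULL)
    data.frame(psi = cs[[1L]]$water_potential, gr = 1 / tg)
  }))
  if (!is.null(gr) && nrow(gr) >= 2L) {
    slope <- unname(coef(lm(gr ~ psi, data = gr))[2L])
    if (is.finite(slope) && slope > 0) return(1 / slope)
  }
  median((pts$psi - (min(pts$psi) - 1)) * pts$t_h)
}

#' @export
print.hydrotime_fit <- function(x, ...) {
  cat(sprintf("<hydrotime_fit> T = %g degC\n", x$temperature))
  cat(sprintf("  thetaH     %.4g MPa.h\n", x$theta_h))
  cat(sprintf("  psib(50)   %.4g MPa\n", x$psib50))
  cat(sprintf("  sigma_psib %.4g MPa\n", x$sigma_psib))
  cat(sprintf("  R2 = %.4f  (n = %d)\n", x$diagnostics$r_squared,
              x$diagnostics$n))
  invisible(x)
}

#' Fit the thermal-time model (cardinal temperatures)
#'
#' At a single water potential (normally 0 MPa), the germination rate of a
#' fraction is linear in temperature: increasing below the optimum
#' (x-intercept `Tb`, slope `1/thetaT1`) and decreasing above it
#' (x-intercept `Tc`, slope `-1/thetaT2`). The optimum `To` is the
#' intersection of the two branches. The observed optimum (temperature of
#' maximum rate) is included in both branches.
#'
#' @param courses Time courses at one water potential across >= 3
#'   temperatures, with >= 2 at/below the observed optimum; when fewer than
#'   2 lie at/above it, only the sub-optimal branch is fitted (`Tc`, `To`,
#'   `thetaT2` are `NA`, with a warning).
#' @param g Seed fraction whose rate is modelled (default 0.5).
#' @return An object of class `thermal_fit` with `Tb`, `To`, `Tc`,
#'   `thetaT1`, `thetaT2` (degC-h) and per-branch R-squared.
#' @export
fit_thermal <- function(courses, g = 0.5) {
  courses <- study_courses(courses)
  psis <- unique(vapply(courses, `[[`, numeric(1), "water_potential"))
  if (length(psis) != 1L) {
    abort_invalid("thermal fit expects courses at a single water potential.")
  }
  by_T <- split(courses, vapply(courses, `[[`, numeric(1), "temperature"))
  gr <- do.call(rbind, lapply(by_T, function(cs) {
    tg <- interpolate_tg(pool_courses(cs), g)
    if (is_undefined(tg) || tg <= 0) return(NULL)
    data.frame(temperature = cs[[1L]]$temperature, gr = 1 / tg)
  }))
  if (is.null(gr) || nrow(gr) < 3L) {
    abort_fit("thermal fit needs rates at >= 3 temperatures.")
  }
  To_obs <- gr$temperature[which.max(gr$gr)]
  sub <- gr[gr$temperature <= To_obs, ]
  supra <- gr[gr$temperature >= To_obs, ]
  if (nrow(sub) < 2L) {
    abort_fit("thermal fit needs >= 2 temperatures at/below the optimum.")
  }
  f1 <- lm(gr ~ temperature, data = sub)
  b1 <- unname(coef(f1)[2L]); a1 <- unname(coef(f1)[1L])
  if (!is.finite(b1) || b1 <= 0) {
    abort_fit("non-positive slope on the sub-optimal branch.")
  }
  have_supra <- nrow(supra) >= 2L
  if (have_supra) {
    f2 <- lm(gr ~ temperature, data = supra)
    b2 <- unname(coef(f2)[2L]); a2 <- unname(coef(f2)[1L])
    if (!is.finite(b2) || b2 >= 0) {
      abort_fit("non-negative slope on the supra-optimal branch.")
    }
  } else {
    warning("no supra-optimal branch: Tc, To and thetaT2 not estimable",
            call. = FALSE)
    a2 <- b2 <- NA_real_
  }
  structure(
    list(
      Tb = -a1 / b1,
      Tc = if (have_supra) -a2 / b2 else NA_real_,
      To = if (have_supra) (a2 - a1) / (b1 - b2) else NA_real_,
      thetaT1 = 1 / b1,
      thetaT2 = if (have_supra) -1 / b2 else NA_real_,
      g = g,
      rates = gr,
      diagnostics = list(
        r_squared_sub = summary(f1)$r.squared,
        r_squared_supra = if (have_supra) summary(f2)$r.squared else
          NA_real_,
        n = nrow(gr)
      )
    ),
    class = "thermal_fit"
  )
}

#' @export
print.thermal_fit <- function(x, ...) {
  cat("<thermal_fit>\n")
  cat(sprintf("  Tb = %.3g  To = %.3g  Tc = %.3g degC\n", x$Tb, x$To, x$Tc))
  cat(sprintf("  thetaT1 = %.4g  thetaT2 = %.4g degC.h\n",
              x$thetaT1, x$thetaT2))
  invisible(x)
}

#' Fit the hydrothermal-time model jointly across temperatures
#'
#' Joint probit regression of observed germinated fractions on
#' `x = psi_eff - thetaHTT / ((T - Tb) tg)` with
#' `psi_eff = psi - kT * max(0, T - To)`. `(thetaHTT, Tb, kT)` are found by
#' multi-start bounded quasi-Newton descent on `1 - R^2` with a
#' Nelder-Mead polish; `psib50` and `sigma_psib` come from the final probit
#' line. `To` defaults to the temperature with maximum observed median
#' germination rate. Without supra-optimal temperatures `kT` is fixed at 0
#' with a warning.
#'
#' @param courses Time courses across >= 2 sub-optimal temperatures and
#'   >= 3 water potentials (or a `germination_study`).
#' @param To Optimum temperature, degC; `NULL` (default) selects the
#'   temperature with the fastest observed median germination.
#' @param boundary See [fit_hydrotime_probit()].
#' @return An object of class `htt_fit`: `params` (an [htt_params()]),
#'   `theta_h` (`thetaHTT/(To - Tb)`, MPa-h), `diagnostics`, and the
#'   observation table.
#' @export
fit_htt <- function(courses, To = NULL, boundary = c("exclude", "adjust")) {
  boundary <- match.arg(boundary)
  courses <- study_courses(courses)
  pts <- probit_points(courses, boundary)
  if (nrow(pts) < 5L) {
    abort_fit("no probit-transformable data (all fractions 0 or 1).")
  }
  temps <- sort(unique(pts$temperature))
  if (length(temps) < 2L) abort_fit("HTT fit needs >= 2 temperatures.")
  if (length(unique(pts$psi)) < 3L) {
    abort_fit("HTT fit needs >= 3 water potentials.")
  }
  z <- qnorm(pts$g)

  # Median germination rate at the wettest treatment per temperature.
  by_T <- split(courses, vapply(courses, `[[`, numeric(1), "temperature"))
  gr50 <- do.call(rbind, lapply(by_T, function(cs) {
    psis <- vapply(cs, `[[`, numeric(1), "water_potential")
    wet <- cs[psis == max(psis)]
    tg <- interpolate_tg(pool_courses(wet), 0.5)
    if (is_undefined(tg) || tg <= 0) return(NULL)
    data.frame(temperature = cs[[1L]]$temperature, gr = 1 / tg)
  }))
  if (is.null(To)) {
    if (is.null(gr50) || nrow(gr50) == 0L) {
      abort_fit("cannot determine the optimum temperature from the data.")
    }
    To <- gr50$temperature[which.max(gr50$gr)]
  }
  est_kT <- any(temps > To)
  if (!est_kT) {
    warning("no supra-optimal temperatures: kT fixed at 0", call. = FALSE)
  }

  # Initial Tb from the sub-optimal rate line; initial thetaHTT from the
  # hydrotime constant at the optimum.
  Tb0 <- min(temps) - 5
  if (!is.null(gr50)) {
    sub <- gr50[gr50$temperature <= To, ]
    if (nrow(sub) >= 2L) {
      cf <- coef(lm(gr ~ temperature, data = sub))
      if (is.finite(cf[2L]) && cf[2L] > 0) {
        cand <- unname(-cf[1L] / cf[2L])
        if (cand < min(temps) - 0.5) Tb0 <- cand
      }
    }
  }
  theta0 <- tryCatch({
    ht <- fit_hydrotime_probit(
      Filter(function(tc) tc$temperature == To, courses),
      boundary = boundary
    )
    ht$theta_h * (To - Tb0)
  }, error = function(e) {
    sub_pts <- pts[pts$temperature <= To, ]
    median((sub_pts$psi - (min(sub_pts$psi) - 1)) *
             (sub_pts$temperature - Tb0) * sub_pts$t_h)
  })

  objective <- function(par) {
    th <- exp(par[1L]); tb <- par[2L]
    kt <- if (est_kT) par[3L] else 0
    if (tb >= min(temps)) return(1e6)
    x <- psi_effective(pts$psi, pts$temperature, kt, To) -
      th / ((pts$temperature - tb) * pts$t_h)
    if (!all(is.finite(x))) return(1e6)
    1 - probit_r_squared(x, z)
  }

  lower <- c(log(theta0) - 4, min(temps) - 40, if (est_kT) 0)
  upper <- c(log(theta0) + 4, min(temps) - 0.05, if (est_kT) 1)
  starts <- list(c(log(theta0), Tb0, if (est_kT) 0.05))
  for (tb_s in c(min(temps) - 3, min(temps) - 12)) {
    for (kt_s in if (est_kT) c(0.01, 0.15) else 0) {
      starts <- c(starts, list(c(log(theta0), tb_s, if (est_kT) kt_s)))
    }
  }
  best <- NULL
  for (s in starts) {
    s <- pmin(pmax(s, lower), upper)
    res <- tryCatch(
      optim(s, objective, method = "L-BFGS-B", lower = lower, upper = upper,
            control = list(maxit = 500, factr = 1e3)),
      error = function(e) NULL
    )
    if (!is.null(res) && (is.null(best) || res$value < best$value)) best <- res
  }
  if (is.null(best)) abort_fit("HTT optimisation failed from all starts.")
  polish <- optim(best$par, objective, method = "Nelder-Mead",
                  control = list(maxit = 2000, reltol = 1e-14))
  if (polish$value < best$value) best <- polish

  thetaHTT <- exp(best$par[1L])
  Tb <- best$par[2L]
  kT <- if (est_kT) best$par[3L] else 0
  if (Tb > min(temps) - 0.1) {
    warning("fitted Tb is at the boundary just below the coldest ",
            "treatment; estimate may be unreliable", call. = FALSE)
  }
  x <- psi_effective(pts$psi, pts$temperature, kT, To) -
    thetaHTT / ((pts$temperature - Tb) * pts$t_h)
  fit <- lm(z ~ x, data = data.frame(x = x, z = z))
  slope <- unname(coef(fit)[2L])
  intercept <- unname(coef(fit)[1L])
  if (!is.finite(slope) || slope <= 0) {
    abort_fit("degenerate final probit line in HTT fit.")
  }
  params <- htt_params(
    thetaHTT = thetaHTT, Tb = Tb, psib50 = -intercept / slope,
    sigma_psib = 1 / slope, kT = kT, To = To
  )
  structure(
    list(
      params = params,
      theta_h = thetaHTT / (To - Tb),
      diagnostics = fit_diagnostics(fit, nrow(pts)),
      points = pts,
      convergence = best$convergence
    ),
    class = "htt_fit"
  )
}

#' @export
print.htt_fit <- function(x, ...) {
  cat("<htt_fit>\n")
  print(x$params)
  cat(sprintf("  thetaH(To) %.4g MPa.h\n", x$theta_h))
  cat(sprintf("  R2 = %.4f  (n = %d)\n", x$diagnostics$r_squared,
              x$diagnostics$n))
  invisible(x)
}

#' Per-treatment grid of thermal/hydro/hydrothermal time constants
#'
#' Applies the threshold-model relations cell by cell: for each
#' (temperature, water potential) treatment with an extractable median
#' germination time `tg`, computes `TTsub = (T - Tb) tg`,
#' `TTsupra = (Tc - T) tg`, `thetaH = (psi - psib) tg`,
#' `thetaHTT = (psi - psib)(T - Tb) tg`, the rate `GR = 1/tg`, and the
#' hydro-normalized rate `GR_ht = GR (psi - psib)/(psi_ref - psib)`.
#' `theta_h_ref` is the hydrotime constant referenced to `psi_ref`
#' (default 0 MPa, the distilled-water control), the convention used in
#' published grids of this kind.
#'
#' @param courses Time courses (or a `germination_study`); alternatively
#'   supply `tg_table` directly.
#' @param Tb,Tc Base and ceiling temperatures, degC.
#' @param psib Base water potential, MPa.
#' @param g Seed fraction (default 0.5).
#' @param psi_ref Reference water potential for `theta_h_ref` / `gr_ht`.
#' @param tg_table Optional `data.frame` with columns `temperature`, `psi`,
#'   `tg_h`, bypassing extraction from `courses`.
#' @return A `data.frame` with one row per treatment; cells whose
#'   preconditions fail (e.g. `psi <= psib`, `T <= Tb`, `tg` not reached)
#'   are `NA`.
#' @export
table1_grid <- function(courses = NULL, Tb, Tc, psib, g = 0.5, psi_ref = 0,
                        tg_table = NULL) {
  if (is.null(tg_table)) {
    if (is.null(courses)) {
      abort_invalid("supply either `courses` or `tg_table`.")
    }
    courses <- study_courses(courses)
    key <- paste(
      vapply(courses, `[[`, numeric(1), "temperature"),
      vapply(courses, `[[`, numeric(1), "water_potential")
    )
    tg_table <- do.call(rbind, lapply(split(courses, key), function(cs) {
      tg <- interpolate_tg(pool_courses(cs), g)
      data.frame(
        temperature = cs[[1L]]$temperature,
        psi = cs[[1L]]$water_potential,
        tg_h = as.numeric(tg)
      )
    }))
  }
  tg_table <- tg_table[order(tg_table$temperature, -tg_table$psi), ,
                       drop = FALSE]
  tg <- tg_table$tg_h
  temp <- tg_table$temperature
  psi <- tg_table$psi
  ok <- !is.na(tg) & tg > 0
  above_tb <- ok & temp > Tb
  below_tc <- ok & temp < Tc
  wet <- ok & psi > psib
  out <- data.frame(
    temperature = temp,
    psi = psi,
    tg_h = ifelse(ok, tg, NA_real_),
    tt_sub = ifelse(above_tb, (temp - Tb) * tg, NA_real_),
    tt_supra = ifelse(below_tc, (Tc - temp) * tg, NA_real_),
    theta_h = ifelse(wet, (psi - psib) * tg, NA_real_),
    theta_h_ref = ifelse(ok & psi_ref > psib, (psi_ref - psib) * tg,
                         NA_real_),
    theta_htt = ifelse(wet & above_tb, (psi - psib) * (temp - Tb) * tg,
                       NA_real_),
    gr = ifelse(ok, 1 / tg, NA_real_)
  )
  out$gr_ht <- ifelse(wet & psi_ref > psib,
                      out$gr * (psi - psib) / (psi_ref - psib), NA_real_)
  rownames(out) <- NULL
  out
}
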