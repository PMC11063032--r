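#' Convert a study to the long CSV schema
#'
#' @param x A `germination_study`.
#' @param row.names,optional,... Ignored (S3 signature).
#' @return A `data.frame` with columns `replicate_id`, `temperature_C`,
#'   `psi_MPa`, `time_d`, `cum_germinated`, `n_seeds`.
#' @export
as.data.frame.germination_study <- function(x, row.names = NULL,
                                            optional = FALSE, ...) {
  rows <- lapply(x$courses, function(tc) {
    data.frame(
      replicate_id = tc$replicate_id,
      temperature_C = tc$temperature,
      psi_MPa = tc$water_potential,
      time_d = tc$times_d,
      cum_germinated = tc$cumulative_counts,
      n_seeds = tc$n_seeds,
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

study_schema <- c("replicate_id", "temperature_C", "psi_MPa",
                  "cum_germinated", "n_seeds")

#' Read a germination study from CSV
#'
#' Long format, one row per dish x observation time, with header
#' `replicate_id, temperature_C, psi_MPa, time_d, cum_germinated, n_seeds`
#' (`time_h` instead of `time_d` when `units = "hours"`). Malformed rows
#' are reported with their file line numbers. Positive water potentials are
#' an error unless `assume_tension = TRUE`, in which case they are
#' sign-flipped with a warning (readings recorded as tensions).
#'
#' @param path CSV file path.
#' @param units Unit of the time column: `"days"` or `"hours"`.
#' @param assume_tension Sign policy for positive `psi_MPa` values.
#' @return A `germination_study`.
#' @export
read_study <- function(path, units = c("days", "hours"),
                       assume_tension = FALSE) {
  units <- match.arg(units)
  time_col <- if (units == "days") "time_d" else "time_h"
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c(study_schema, time_col)
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols)) {
    abort_invalid(paste0("missing required columns: ",
                         paste(missing_cols, collapse = ", ")))
  }
  line_no <- seq_len(nrow(df)) + 1L  # +1 for the header line
  problems <- character()

  pos <- !is.na(df$psi_MPa) & df$psi_MPa > 0
  if (any(pos)) {
    if (assume_tension) {
      warning(sprintf(
        "sign-flipping %d positive psi_MPa values (tension convention)",
        sum(pos)), call. = FALSE)
      df$psi_MPa[pos] <- -df$psi_MPa[pos]
    } else {
      problems <- c(problems, sprintf(
        "line %d: positive psi_MPa %g (use assume_tension = TRUE for tensions)",
        line_no[pos], df$psi_MPa[pos]))
    }
  }
  over <- !is.na(df$cum_germinated) & df$cum_germinated > df$n_seeds
  if (any(over)) {
    problems <- c(problems, sprintf(
      "line %d: cum_germinated %g exceeds n_seeds %g",
      line_no[over], df$cum_germinated[over], df$n_seeds[over]))
  }
  neg <- !is.na(df$cum_germinated) & df$cum_germinated < 0
  if (any(neg)) {
    problems <- c(problems,
                  sprintf("line %d: negative cum_germinated", line_no[neg]))
  }

  key <- paste(df$replicate_id, df$temperature_C, df$psi_MPa, sep = "\r")
  for (k in unique(key)) {
    idx <- which(key == k)
    idx <- idx[order(df[[time_col]][idx])]
    bad <- idx[-1L][diff(df$cum_germinated[idx]) < 0]
    if (length(bad)) {
      problems <- c(problems, sprintf(
        "line %d: cumulative count decreases within dish %s",
        line_no[bad], df$replicate_id[bad]))
    }
    if (length(unique(df$n_seeds[idx])) > 1L) {
      problems <- c(problems, sprintf(
        "line %d: n_seeds varies within one dish", line_no[idx[1L]]))
    }
  }
  if (length(problems)) {
    abort_invalid(paste0("invalid study file:\n  ",
                         paste(problems, collapse = "\n  ")))
  }

  courses <- list()
  for (k in unique(key)) {
    idx <- which(key == k)
    idx <- idx[order(df[[time_col]][idx])]
    tc <- germination_time_course(
      df[[time_col]][idx], df$cum_germinated[idx], df$n_seeds[idx][1L],
      temperature = df$temperature_C[idx][1L],
      water_potential = df$psi_MPa[idx][1L],
      replicate_id = df$replicate_id[idx][1L],
      units = units
    )
    nm <- sprintf("T%g_psi%g_%s", tc$temperature, tc$water_potential,
                  tc$replicate_id)
    courses[[nm]] <- tc
  }
  structure(list(courses = courses, truth = NULL, config = NULL),
            class = "germination_study")
}

#' Write a germination study to CSV
#'
#' Canonical long format (see [read_study()]); reading a file written by
#' this function and writing it again is byte-identical.
#'
#' @param study A `germination_study` or list of time courses.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_study <- function(study, path) {
  courses <- study_courses(study)
  df <- as.data.frame.germination_study(list(courses = courses))
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read per-dish seedling measures from CSV
#'
#' Columns: `replicate_id, temperature_C, psi_MPa, radicle_cm, plumule_cm,
#' dryweight_g`.
#'
#' @param path CSV file path.
#' @return A validated `data.frame`.
#' @export
read_seedling_measures <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("replicate_id", "temperature_C", "psi_MPa", "radicle_cm",
            "plumule_cm", "dryweight_g")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols)) {
    abort_invalid(paste0("missing required columns: ",
                         paste(missing_cols, collapse = ", ")))
  }
  vals <- df[c("radicle_cm", "plumule_cm", "dryweight_g")]
  if (any(vals < 0, na.rm = TRUE)) {
    abort_invalid("seedling measures must be non-negative.")
  }
  df
}

#' Read a flat key-value simulation config file
#'
#' Lines of the form `key = value`; `#` starts a comment. Recognised keys:
#' `thetaHTT, Tb, psib50, sigma_psib, kT, To` (population parameters),
#' `temperatures, water_potentials, observation_times_h` (comma-separated),
#' `n_replicates, n_seeds_per_dish, rng_seed, noise_mode`. Missing keys
#' fall back to the [simulation_config()] defaults.
#'
#' @param path Config file path.
#' @return A [simulation_config()].
#' @export
read_sim_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  kv <- list()
  for (ln in lines) {
    parts <- strsplit(ln, "=", fixed = TRUE)[[1L]]
    if (length(parts) < 2L) abort_config(sprintf("bad config line: '%s'", ln))
    kv[[trimws(parts[1L])]] <- trimws(paste(parts[-1L], collapse = "="))
  }
  num <- function(key, default) {
    if (is.null(kv[[key]])) default else as.numeric(kv[[key]])
  }
  vec <- function(key, default) {
    if (is.null(kv[[key]])) default else
      as.numeric(strsplit(kv[[key]], ",")[[1L]])
  }
  defaults <- simulation_config()
  p <- defaults$true_params
  simulation_config(
    true_params = htt_params(
      thetaHTT = num("thetaHTT", p$thetaHTT),
      Tb = num("Tb", p$Tb),
      psib50 = num("psib50", p$psib50),
      sigma_psib = num("sigma_psib", p$sigma_psib),
      kT = num("kT", p$kT),
      To = num("To", p$To)
    ),
    temperatures = vec("temperatures", defaults$temperatures),
    water_potentials = vec("water_potentials", defaults$water_potentials),
    n_replicates = num("n_replicates", defaults$n_replicates),
    n_seeds_per_dish = num("n_seeds_per_dish", defaults$n_seeds_per_dish),
    observation_times_h = vec("observation_times_h",
                              defaults$observation_times_h),
    rng_seed = num("rng_seed", defaults$rng_seed),
    noise_mode = if (is.null(kv[["noise_mode"]])) defaults$noise_mode else
      kv[["noise_mode"]]
  )
}

#' Run the full analysis pipeline
#'
#' Computes the per-dish index table with treatment means, the thermal-time
#' fit (distilled-water dishes), per-temperature hydrotime fits, the joint
#' hydrothermal-time fit, and the per-treatment grid of time constants
#' (using the fitted `Tb`, `psib50` and the thermal-fit `Tc`). Stage
#' failures are isolated: the failing stage is recorded in `$errors` and
#' the remaining stages still run. Deterministic given inputs.
#'
#' @param study A `germination_study` or list of time courses.
#' @param seedling Optional seedling measures `data.frame`
#'   (see [read_seedling_measures()]).
#' @param metrics_only If `TRUE`, skip all model fits.
#' @param g Seed fraction for rate-based fits (default 0.5).
#' @param gri_variant Passed to [germination_rate_index()].
#' @param boundary Passed to the probit fits.
#' @param out_dir Optional directory; when given, all tables are written as
#'   CSV and fit summaries as flat key-value text files.
#' @return An object of class `htt_report`.
#' @export
run_pipeline <- function(study, seedling = NULL, metrics_only = FALSE,
                         g = 0.5, gri_variant = "standard",
                         boundary = "exclude", out_dir = NULL) {
  courses <- study_courses(study)
  errors <- list()
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      errors[[name]] <<- conditionMessage(e)
      NULL
    })
  }
  indices <- means <- NULL
  if (length(courses)) {
    indices <- stage("metrics", index_table(courses, seedling, gri_variant))
    means <- if (!is.null(indices)) {
      stage("treatment_means", treatment_means(indices))
    }
  }
  thermal <- hydro <- htt <- grid <- NULL
  if (!metrics_only && length(courses)) {
    psis <- vapply(courses, `[[`, numeric(1), "water_potential")
    temps <- vapply(courses, `[[`, numeric(1), "temperature")
    thermal <- stage("thermal_fit",
                     fit_thermal(courses[psis == max(psis)], g = g))
    hydro <- stage("hydrotime_fits", {
      fits <- lapply(sort(unique(temps)), function(tt) {
        tryCatch(
          fit_hydrotime_probit(courses[temps == tt], boundary = boundary),
          error = function(e) NULL
        )
      })
      fits <- Filter(Negate(is.null), fits)
      if (!length(fits)) abort_fit("no temperature admitted a hydrotime fit.")
      setNames(fits, vapply(fits, function(f) sprintf("T%g", f$temperature),
                            character(1)))
    })
    htt <- stage("htt_fit", fit_htt(courses, boundary = boundary))
    grid <- stage("grid", {
      if (is.null(htt)) abort_fit("grid stage needs the HTT fit.")
      table1_grid(
        courses,
        Tb = htt$params$Tb,
        Tc = if (!is.null(thermal)) thermal$Tc else Inf,
        psib = htt$params$psib50,
        g = g
      )
    })
  } else if (!length(courses)) {
    errors[["metrics"]] <- "empty study: no dishes to analyse."
  }
  report <- structure(
    list(
      indices = indices, treatment_means = means, thermal = thermal,
      hydrotime = hydro, htt = htt, grid = grid, errors = errors,
      metadata = list(
        g = g, gri_variant = gri_variant, boundary = boundary,
        index_time_unit = "days", model_time_unit = "hours",
        ge_interpretation = "cumulative-% increments over count days",
        t50_convention = "half of final germinated count"
      )
    ),
    class = "htt_report"
  )
  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

#' @export
print.htt_report <- function(x, ...) {
  cat("<htt_report>\n")
  cat(sprintf("  indices: %s dishes\n",
              if (is.null(x$indices)) 0L else nrow(x$indices)))
  for (nm in c("thermal", "htt")) {
    if (!is.null(x[[nm]])) {
      cat(sprintf("  %s fit: ok\n", nm))
    }
  }
  if (!is.null(x$hydrotime)) {
    cat(sprintf("  hydrotime fits at %d temperatures\n", length(x$hydrotime)))
  }
  if (length(x$errors)) {
    cat("  errors:\n")
    for (nm in names(x$errors)) cat(sprintf("    %s: %s\n", nm,
                                            x$errors[[nm]]))
  }
  invisible(x)
}

# Flat key=value fit summaries plus CSV tables for a report bundle.
write_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!is.null(report$indices)) {
    write.csv(report$indices, file.path(out_dir, "indices.csv"),
              row.names = FALSE)
  }
  if (!is.null(report$treatment_means)) {
    write.csv(report$treatment_means,
              file.path(out_dir, "treatment_means.csv"), row.names = FALSE)
  }
  if (!is.null(report$grid)) {
    write.csv(report$grid, file.path(out_dir, "time_constants_grid.csv"),
              row.names = FALSE)
  }
  kv <- character()
  if (!is.null(report$thermal)) {
    th <- report$thermal
    kv <- c(kv, sprintf("thermal.%s = %.10g",
                        c("Tb", "To", "Tc", "thetaT1", "thetaT2"),
                        c(th$Tb, th$To, th$Tc, th$thetaT1, th$thetaT2)))
  }
  if (!is.null(report$hydrotime)) {
    for (f in report$hydrotime) {
      kv <- c(kv, sprintf(
        "hydrotime.T%g.%s = %.10g", f$temperature,
        c("thetaH", "psib50", "sigma_psib", "r_squared"),
        c(f$theta_h, f$psib50, f$sigma_psib, f$diagnostics$r_squared)))
    }
  }
  if (!is.null(report$htt)) {
    p <- report$htt$params
    kv <- c(kv, sprintf(
      "htt.%s = %.10g",
      c("thetaHTT", "Tb", "psib50", "sigma_psib", "kT", "To", "thetaH",
        "r_squared"),
      c(p$thetaHTT, p$Tb, p$psib50, p$sigma_psib, p$kT, p$To,
        report$htt$theta_h, report$htt$diagnostics$r_squared)))
  }
  for (nm in names(report$metadata)) {
    kv <- c(kv, sprintf("meta.%s = %s", nm, report$metadata[[nm]]))
  }
  if (length(report$errors)) {
    kv <- c(kv, sprintf("error.%s = %s", names(report$errors),
                        unlist(report$errors)))
  }
  writeLines(kv, file.path(out_dir, "fit_summary.txt"))
  invisible(out_dir)
}
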