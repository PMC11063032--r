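#' Dish-level germination time course
#'
#' Container for one dish's cumulative germination counts under a single
#' temperature x water potential treatment. Times are stored internally in
#' days (the counting unit of the indices); model code converts to hours.
#'
#' @param times Strictly increasing observation times (> 0), in the unit
#'   given by `units`.
#' @param cumulative_counts Integer cumulative germinated counts, same
#'   length as `times`, non-decreasing, each in `[0, n_seeds]`.
#' @param n_seeds Number of seeds sown in the dish (>= 1).
#' @param temperature Incubation temperature, degrees Celsius.
#' @param water_potential Osmotic water potential, MPa (<= 0).
#' @param replicate_id Replicate label.
#' @param units Unit of `times`: `"days"` (default) or `"hours"`.
#' @return An object of class `germination_time_course`.
#' @examples
#' tc <- germination_time_course(1:5, c(0, 2, 6, 9, 10), 10,
#'                               temperature = 20, water_potential = 0)
#' cumulative_fraction(tc)
#' @export
germination_time_course <- function(times, cumulative_counts, n_seeds,
                                    temperature = NA_real_,
                                    water_potential = NA_real_,
                                    replicate_id = "r1",
                                    units = c("days", "hours")) {
  units <- match.arg(units)
  if (length(n_seeds) != 1L || is.na(n_seeds) || n_seeds < 1 ||
      n_seeds %% 1 != 0) {
    abort_invalid("`n_seeds` must be a single integer >= 1.")
  }
  if (length(times) == 0L || anyNA(times) || any(times <= 0)) {
    abort_invalid("`times` must be positive and non-missing.")
  }
  if (length(times) > 1L && any(diff(times) <= 0)) {
    abort_invalid("`times` must be strictly increasing.")
  }
  if (length(cumulative_counts) != length(times)) {
    abort_invalid("`cumulative_counts` and `times` must have equal length.")
  }
  if (anyNA(cumulative_counts) || any(cumulative_counts %% 1 != 0)) {
    abort_invalid("`cumulative_counts` must be integer-valued.")
  }
  if (any(cumulative_counts < 0) || any(cumulative_counts > n_seeds)) {
    abort_invalid("`cumulative_counts` must lie in [0, n_seeds].")
  }
  if (length(cumulative_counts) > 1L && any(diff(cumulative_counts) < 0)) {
    abort_invalid("`cumulative_counts` must be non-decreasing.")
  }
  if (!is.na(water_potential) && water_potential > 0) {
    abort_invalid("`water_potential` must be <= 0 MPa (tension convention).")
  }
  structure(
    list(
      times_d = if (units == "hours") as.numeric(times) / 24 else
        as.numeric(times),
      cumulative_counts = as.numeric(cumulative_counts),
      n_seeds = as.integer(n_seeds),
      temperature = as.numeric(temperature),
      water_potential = as.numeric(water_potential),
      replicate_id = as.character(replicate_id)
    ),
    class = "germination_time_course"
  )
}

#' @export
print.germination_time_course <- function(x, ...) {
  cat(sprintf(
    "<germination_time_course> %s | T = %s degC | psi = %s MPa | %d seeds\n",
    x$replicate_id, format(x$temperature), format(x$water_potential),
    x$n_seeds
  ))
  cat("  day:   ", paste(format(x$times_d, trim = TRUE), collapse = " "), "\n")
  cat("  count: ", paste(format(x$cumulative_counts, trim = TRUE),
                         collapse = " "), "\n")
  invisible(x)
}

is_time_course <- function(x) inherits(x, "germination_time_course")

assert_time_course <- function(tc) {
  if (!is_time_course(tc)) {
    abort_invalid("expected a `germination_time_course` object.")
  }
  tc
}

times_hours <- function(tc) tc$times_d * 24

#' Cumulative germinated fraction
#'
#' @param tc A [germination_time_course()].
#' @return Numeric vector of fractions in `[0, 1]`, one per observation
#'   time, non-decreasing.
#' @export
cumulative_fraction <- function(tc) {
  assert_time_course(tc)
  if (tc$n_seeds == 0) abort_invalid("`n_seeds` must be positive.")
  tc$cumulative_counts / tc$n_seeds
}

#' Final germination percentage
#'
#' @param tc A [germination_time_course()].
#' @return Final cumulative germination, percent of seeds sown.
#' @export
germination_percent <- function(tc) {
  assert_time_course(tc)
  100 * tc$cumulative_counts[length(tc$cumulative_counts)] / tc$n_seeds
}

#' Interpolate the time to a germination fraction
#'
#' Linear interpolation of the cumulative-fraction curve to extract
#' `tg(g)`, the time for fraction `g` of the seeds to germinate, as needed
#' by the thermal/hydro/hydrothermal time relations. The curve is anchored
#' at (0 h, fraction 0).
#'
#' @param tc A [germination_time_course()].
#' @param g Target fraction in (0, 1].
#' @return Time in hours, or an [undefined_value()] when the curve never
#'   reaches `g`.
#' @export
interpolate_tg <- function(tc, g = 0.5) {
  assert_time_course(tc)
  if (length(g) != 1L || is.na(g) || g <= 0 || g > 1) {
    abort_invalid("`g` must be a single fraction in (0, 1].")
  }
  f <- c(0, cumulative_fraction(tc))
  t_h <- c(0, times_hours(tc))
  hit <- which(f >= g - 1e-12)
  if (length(hit) == 0L) {
    return(undefined_value("fraction_never_reached"))
  }
  i <- hit[1L]
  if (abs(f[i] - g) <= 1e-12) {
    return(t_h[i])
  }
  t_h[i - 1L] + (g - f[i - 1L]) * (t_h[i] - t_h[i - 1L]) / (f[i] - f[i - 1L])
}

# Daily new-germination increments, derived as first differences of the
# cumulative counts. Non-integer observation times are floored to a day
# index with a warning (index formulas assume daily counts).
day_increments <- function(tc) {
  assert_time_course(tc)
  d <- tc$times_d
  if (any(abs(d - round(d)) > 1e-8)) {
    warning("non-integer observation days floored to day indices",
            call. = FALSE)
    d <- floor(d)
  } else {
    d <- round(d)
  }
  data.frame(day = d, new = diff(c(0, tc$cumulative_counts)))
}

# Pool replicate dishes of one treatment: counts and seed numbers are
# summed. All dishes must share the observation schedule.
pool_courses <- function(courses) {
  courses <- lapply(courses, assert_time_course)
  if (length(courses) == 1L) return(courses[[1L]])
  t0 <- courses[[1L]]$times_d
  for (tc in courses[-1L]) {
    if (length(tc$times_d) != length(t0) ||
        any(abs(tc$times_d - t0) > 1e-9)) {
      abort_invalid("cannot pool dishes with different observation times.")
    }
  }
  counts <- Reduce(`+`, lapply(courses, `[[`, "cumulative_counts"))
  n <- sum(vapply(courses, `[[`, integer(1), "n_seeds"))
  germination_time_course(
    t0, counts, n,
    temperature = courses[[1L]]$temperature,
    water_potential = courses[[1L]]$water_potential,
    replicate_id = "pooled"
  )
}
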