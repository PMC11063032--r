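#' Mean germination time (MGT)
#'
#' `MGT = sum(f_i * x_i) / sum(f_i)` where `f_i` is the number of seeds
#' newly germinated on day `x_i` (first differences of the cumulative
#' counts). Days.
#'
#' @param tc A [germination_time_course()].
#' @return MGT in days, or an [undefined_value()] (`"no_germination"`) when
#'   no seed germinated.
#' @export
mean_germination_time <- function(tc) {
  inc <- day_increments(tc)
  total <- sum(inc$new)
  if (total == 0) return(undefined_value("no_germination"))
  sum(inc$new * inc$day) / total
}

#' Mean germination rate (MGR)
#'
#' The exact reciprocal of [mean_germination_time()], in 1/days.
#'
#' @inheritParams mean_germination_time
#' @return MGR in 1/days; undefined when MGT is undefined.
#' @export
mean_germination_rate <- function(tc) {
  mgt <- mean_germination_time(tc)
  if (is_undefined(mgt)) return(mgt)
  1 / mgt
}

#' Germination energy (GE)
#'
#' Sum over count days of the daily increment of cumulative germination
#' percentage divided by the day number:
#' `GE = X1/Y1 + (X2 - X1)/Y2 + ... + (Xn - Xn-1)/Yn`, with `Xi` the
#' cumulative germination percentage and `Yi` the day of count `i`.
#'
#' @inheritParams mean_germination_time
#' @return Germination energy (dimensionless).
#' @export
germination_energy <- function(tc) {
  inc <- day_increments(tc)
  if (any(inc$day <= 0)) {
    abort_invalid("count day numbers must be positive for germination energy.")
  }
  pct_inc <- 100 * inc$new / tc$n_seeds
  sum(pct_inc / inc$day)
}

#' Germination rate index (GRI)
#'
#' With `G_i` the germination percentage newly reached on day `i`, the
#' standard form is `GRI = sum(G_i / i)`. The `"as_printed"` variant
#' divides every increment by 2 instead of its day number (`sum(G_i / 2)`),
#' reproducing a published typographic form of the formula; it is provided
#' for comparison only.
#'
#' @inheritParams mean_germination_time
#' @param variant `"standard"` (default) or `"as_printed"`.
#' @return GRI (dimensionless).
#' @export
germination_rate_index <- function(tc, variant = c("standard", "as_printed")) {
  if (is.character(variant) && length(variant) == 1L &&
      !variant %in% c("standard", "as_printed")) {
    abort_config(sprintf("unknown GRI variant '%s'.", variant))
  }
  variant <- match.arg(variant)
  inc <- day_increments(tc)
  if (any(inc$day <= 0)) {
    abort_invalid("count day numbers must be positive for GRI.")
  }
  pct_inc <- 100 * inc$new / tc$n_seeds
  if (variant == "standard") sum(pct_inc / inc$day) else sum(pct_inc / 2)
}

#' Germination index (GI)
#'
#' Weighted count of daily germination over a fixed 10-day window:
#' `GI = 10*n1 + 9*n2 + ... + 1*n10`, i.e. weight `11 - d` for seeds newly
#' germinated on day `d`. Seeds germinating after day 10 receive weight 0
#' with a warning.
#'
#' @inheritParams mean_germination_time
#' @return GI (dimensionless), bounded by `10 * n_seeds`.
#' @export
germination_index <- function(tc) {
  inc <- day_increments(tc)
  late <- inc$day > 10 & inc$new > 0
  if (any(late)) {
    warning("seeds germinating after day 10 receive weight 0 in GI",
            call. = FALSE)
  }
  w <- pmax(0, 11 - inc$day)
  w[inc$day < 1] <- 0
  sum(w * inc$new)
}

#' Timson germination index
#'
#' Sum of the cumulative germination percentage over each day of the
#' counting window (default 10 days); the percentage is carried forward
#' between observations. Bounded by `100 * window_days`.
#'
#' @inheritParams mean_germination_time
#' @param window_days Length of the counting window in days (>= 1).
#' @return Timson index (dimensionless).
#' @export
timson_index <- function(tc, window_days = 10) {
  assert_time_course(tc)
  if (length(window_days) != 1L || is.na(window_days) || window_days < 1) {
    abort_invalid("`window_days` must be a single value >= 1.")
  }
  cum_pct <- 100 * cumulative_fraction(tc)
  step <- approx(
    x = c(0, tc$times_d), y = c(0, cum_pct),
    xout = seq_len(floor(window_days)),
    method = "constant", f = 0, rule = 2
  )
  sum(step$y)
}

#' Coefficient of velocity of germination (CVG)
#'
#' `CVG = 100 * sum(n_i) / sum(n_i * t_i) = 100 / MGT`, in percent per day.
#'
#' @inheritParams mean_germination_time
#' @return CVG in %/day; undefined when no seed germinated.
#' @export
coefficient_velocity <- function(tc) {
  mgt <- mean_germination_time(tc)
  if (is_undefined(mgt)) return(mgt)
  100 / mgt
}

#' Time to 50% germination (T50)
#'
#' Time at which half of the finally germinated seeds (`N`, the Coolbear /
#' Farooq convention) have germinated, by linear interpolation between the
#' bracketing observations:
#' `T50 = t_i + (N/2 - n_i) (t_j - t_i) / (n_j - n_i)`.
#' Defined only when the final cumulative fraction of seeds sown is >= 0.5.
#'
#' @inheritParams mean_germination_time
#' @return T50 in days, or an [undefined_value()]
#'   (`"final_fraction_below_half"`).
#' @export
time_to_50 <- function(tc) {
  assert_time_course(tc)
  counts <- tc$cumulative_counts
  n_final <- counts[length(counts)]
  if (n_final / tc$n_seeds < 0.5) {
    return(undefined_value("final_fraction_below_half"))
  }
  target <- n_final / 2
  cts <- c(0, counts)
  tms <- c(0, tc$times_d)
  i <- which(cts >= target - 1e-12)[1L]
  if (abs(cts[i] - target) <= 1e-12) return(tms[i])
  tms[i - 1L] + (target - cts[i - 1L]) * (tms[i] - tms[i - 1L]) /
    (cts[i] - cts[i - 1L])
}

#' Seedling measures for vigor indices
#'
#' @param radicle_cm Radicle length, cm (>= 0).
#' @param plumule_cm Plumule length, cm (>= 0).
#' @param dry_weight_g Seedling dry weight, g (>= 0).
#' @return An object of class `seedling_measures`.
#' @export
seedling_measures <- function(radicle_cm, plumule_cm, dry_weight_g) {
  v <- c(radicle_cm, plumule_cm, dry_weight_g)
  if (anyNA(v) || any(v < 0)) {
    abort_invalid("seedling measures must be non-negative.")
  }
  structure(
    list(radicle_cm = radicle_cm, plumule_cm = plumule_cm,
         dry_weight_g = dry_weight_g),
    class = "seedling_measures"
  )
}

#' Seed vigor indices
#'
#' Length-based vigor: `SVI-I = (radicle + plumule) * germination %`;
#' weight-based vigor: `SVI-II = dry weight * germination %`.
#'
#' @param tc A [germination_time_course()].
#' @param sm A [seedling_measures()].
#' @return Named list with `svi_length` and `svi_weight`.
#' @export
seed_vigor_indices <- function(tc, sm) {
  if (!inherits(sm, "seedling_measures")) {
    abort_invalid("`sm` must be a `seedling_measures` object.")
  }
  gp <- germination_percent(tc)
  list(
    svi_length = (sm$radicle_cm + sm$plumule_cm) * gp,
    svi_weight = sm$dry_weight_g * gp
  )
}

#' All germination indices for one dish
#'
#' Computes every scalar index for one time course (and, optionally, the
#' seedling-based vigor indices). Undefined indices are `NA` with their
#' reason codes collected in the `notes` column.
#'
#' @param tc A [germination_time_course()].
#' @param sm Optional [seedling_measures()].
#' @param gri_variant Passed to [germination_rate_index()].
#' @return A one-row `data.frame`.
#' @export
index_report <- function(tc, sm = NULL, gri_variant = "standard") {
  assert_time_course(tc)
  mgt <- mean_germination_time(tc)
  mgr <- mean_germination_rate(tc)
  cvg <- coefficient_velocity(tc)
  t50 <- time_to_50(tc)
  svi <- if (!is.null(sm)) seed_vigor_indices(tc, sm) else
    list(svi_length = NA_real_, svi_weight = NA_real_)
  notes <- c(
    if (is_undefined(mgt)) paste0("MGT:", undefined_reason(mgt)),
    if (is_undefined(t50)) paste0("T50:", undefined_reason(t50))
  )
  data.frame(
    replicate_id = tc$replicate_id,
    temperature_C = tc$temperature,
    psi_MPa = tc$water_potential,
    germination_percent = germination_percent(tc),
    MGT_d = as.numeric(mgt),
    MGR_per_d = as.numeric(mgr),
    GE = germination_energy(tc),
    GRI = germination_rate_index(tc, gri_variant),
    GI = germination_index(tc),
    timson = timson_index(tc),
    CVG_pct_per_d = as.numeric(cvg),
    T50_d = as.numeric(t50),
    SVI_length = svi$svi_length,
    SVI_weight = svi$svi_weight,
    notes = if (length(notes)) paste(notes, collapse = ";") else "",
    stringsAsFactors = FALSE
  )
}

#' Index table for a whole study
#'
#' One [index_report()] row per dish, optionally joined with per-dish
#' seedling measures.
#'
#' @param study A `germination_study` (see [simulate_study()] /
#'   [read_study()]) or a list of time courses.
#' @param seedling Optional `data.frame` with columns `replicate_id`,
#'   `temperature_C`, `psi_MPa`, `radicle_cm`, `plumule_cm`, `dryweight_g`.
#' @param gri_variant Passed to [germination_rate_index()].
#' @return A `data.frame`, one row per dish.
#' @export
index_table <- function(study, seedling = NULL, gri_variant = "standard") {
  courses <- study_courses(study)
  rows <- lapply(courses, function(tc) {
    sm <- NULL
    if (!is.null(seedling)) {
      hit <- seedling$replicate_id == tc$replicate_id &
        abs(seedling$temperature_C - tc$temperature) < 1e-9 &
        abs(seedling$psi_MPa - tc$water_potential) < 1e-9
      if (any(hit)) {
        r <- seedling[which(hit)[1L], ]
        sm <- seedling_measures(r$radicle_cm, r$plumule_cm, r$dryweight_g)
      }
    }
    index_report(tc, sm, gri_variant)
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Treatment means of an index table
#'
#' @param indices Output of [index_table()].
#' @return A `data.frame` of per-treatment means of all numeric indices.
#' @export
treatment_means <- function(indices) {
  num <- vapply(indices, is.numeric, logical(1))
  num[c("temperature_C", "psi_MPa")] <- FALSE
  aggregate(
    indices[num],
    by = list(temperature_C = indices$temperature_C,
              psi_MPa = indices$psi_MPa),
    FUN = mean
  )
}
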