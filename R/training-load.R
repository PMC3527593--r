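#' Default intensity-zone weighting coefficients
#'
#' Weights applied to pool kilometres in each of the seven swim intensity
#' zones (aerobic base through maximal sprint). The exact coefficients used
#' to weight a season are a methodological choice and should be treated as
#' configuration; these defaults follow the swimming training-quantification
#' tradition of steeply increasing cost with intensity.
#'
#' @return Numeric vector of 7 positive, non-decreasing weights.
#' @export
default_zone_coefficients <- function() c(1, 2, 3, 5, 8, 12, 16)

#' Training load of a single session
#'
#' Converts one session into arbitrary training units: each zone's kilometres
#' are multiplied by its coefficient, and dry-land minutes are converted to
#' equivalent kilometres (`dryland_km_equiv_per_hour` per hour) weighted by
#' `dryland_coeff`.
#'
#' @param data A data frame with columns `km_z1` ... `km_z7` and
#'   `dryland_min` (one row per session; extra columns such as `date` pass
#'   through untouched).
#' @param zone_coeffs Seven positive, non-decreasing zone weights.
#' @param dryland_km_equiv_per_hour Kilometres of equivalent swimming per hour
#'   of dry-land work (default 2).
#' @param dryland_coeff Intensity weight applied to the dry-land equivalent
#'   kilometres (default 3).
#' @return The input tibble with a `load` column appended (arbitrary units).
#' @examples
#' session_load(tibble::tibble(km_z1 = 3, km_z2 = 0, km_z3 = 0, km_z4 = 0,
#'                             km_z5 = 1, km_z6 = 0, km_z7 = 0,
#'                             dryland_min = 0))
#' @export
session_load <- function(data, zone_coeffs = default_zone_coefficients(),
                         dryland_km_equiv_per_hour = 2, dryland_coeff = 3) {
  zone_cols <- paste0("km_z", 1:7)
  missing_cols <- setdiff(c(zone_cols, "dryland_min"), names(data))
  if (length(missing_cols) > 0L) {
    abort(sprintf("session_load(): missing columns %s.",
                  paste0("`", missing_cols, "`", collapse = ", ")))
  }
  if (length(zone_coeffs) != 7L) {
    abort("`zone_coeffs` must have exactly 7 entries (one per intensity zone).")
  }
  if (any(zone_coeffs <= 0) || is.unsorted(zone_coeffs)) {
    abort("`zone_coeffs` must be positive and non-decreasing across zones.")
  }
  km <- as.matrix(data[zone_cols])
  if (anyNA(km) || any(km < 0)) abort("Zone distances must be >= 0 with no NA.")
  if (anyNA(data$dryland_min) || any(data$dryland_min < 0)) {
    abort("`dryland_min` must be >= 0 with no NA.")
  }
  data <- as_tibble(data)
  data$load <- as.numeric(km %*% zone_coeffs) +
    (data$dryland_min / 60) * dryland_km_equiv_per_hour * dryland_coeff
  data
}

#' Build the daily training-amount series w(t)
#'
#' Aggregates dated sessions into one training amount per calendar day across
#' the whole season; days without a session get 0. Multiple sessions on a day
#' are summed. Sessions dated outside the season span raise an error.
#'
#' @param sessions A data frame of sessions with a `date` column and either a
#'   precomputed `load` column or the zone/dry-land columns accepted by
#'   [session_load()] (in which case loads are computed with `...` passed on).
#' @param season_start First day of the season (`Date` or string).
#' @param season_days Number of days in the season.
#' @param ... Passed to [session_load()] when loads need computing.
#' @return A tibble of class `training_log` with columns `day` (1-based),
#'   `date` and `w`.
#' @export
build_daily_series <- function(sessions, season_start, season_days, ...) {
  season_start <- as.Date(season_start)
  check_number(season_days, "season_days", min = 1)
  if (!"load" %in% names(sessions)) sessions <- session_load(sessions, ...)
  if (!"date" %in% names(sessions)) {
    abort("build_daily_series(): `sessions` needs a `date` column.")
  }
  dates <- as.Date(sessions$date)
  day_idx <- as.integer(dates - season_start) + 1L
  if (nrow(sessions) > 0L &&
      (any(day_idx < 1L) || any(day_idx > season_days))) {
    bad <- which(day_idx < 1L | day_idx > season_days)[1L]
    abort(sprintf(
      "Session dated %s falls outside the season (%s + %d days).",
      format(dates[bad]), format(season_start), season_days))
  }
  w <- numeric(season_days)
  if (nrow(sessions) > 0L) {
    sums <- tapply(sessions$load, day_idx, sum)
    w[as.integer(names(sums))] <- as.numeric(sums)
  }
  out <- tibble(
    day = seq_len(season_days),
    date = season_start + seq_len(season_days) - 1L,
    w = w
  )
  class(out) <- c("training_log", class(out))
  out
}

#' Read a session log CSV
#'
#' Expects columns `date`, `km_z1` ... `km_z7`, `dryland_min`.
#'
#' @param path CSV file path.
#' @return A tibble of sessions.
#' @export
read_sessions_csv <- function(path) {
  if (!file.exists(path)) abort(sprintf("Session file not found: '%s'.", path))
  readr::read_csv(path, show_col_types = FALSE)
}

assert_training_log <- function(log, fn) {
  if (!is.data.frame(log) || !"w" %in% names(log)) {
    abort(sprintf("`%s()` expects a training log with a `w` column.", fn))
  }
  if (anyNA(log$w) || any(log$w < 0)) {
    abort(sprintf("`%s()`: training amounts `w` must be >= 0.", fn))
  }
  invisible(log)
}
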