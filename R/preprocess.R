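#' Log10-transform raw concentrations
#'
#' Concentration data such as TOC are strongly right-skewed; working on the
#' log10 scale symmetrises the distribution and damps the influence of single
#' high values on the local regressions. All downstream stages (centering,
#' trend fitting, the CV screen) operate on log10 values.
#'
#' @param data An observation table in scale `"raw"`.
#' @return The table with `value = log10(value)` and scale `"log10"`.
#' @export
log10_transform <- function(data) {
  check_scale(data, "raw", "log10_transform()")
  if (any(data$value <= 0)) {
    abort_validation("All raw values must be strictly positive for log10.")
  }
  data$value <- log10(data$value)
  gwt_log("log10_transform: {nrow(data)} rows transformed to log10 scale.")
  set_obs_scale(data, "log10")
}

#' Drop stations with too few observations
#'
#' Trend estimation needs time-series-type data: stations visited fewer than
#' `min_n` times carry no within-station temporal information and are removed
#' before fitting. The number of observations discarded is attached as
#' attribute `"removed_obs"` (and the number of stations as
#' `"removed_stations"`).
#'
#' @param data An observation table (any scale).
#' @param min_n Minimum observations a station must have to be kept.
#'   Default 2.
#' @return The filtered table, same scale, input order preserved.
#' @export
filter_min_observations <- function(data, min_n = 2) {
  if (!is.numeric(min_n) || length(min_n) != 1 || min_n < 1) {
    abort_config("{.arg min_n} must be a single count >= 1.")
  }
  sc <- obs_scale(data)
  counts <- dplyr::count(data, .data$station_id)
  keep_ids <- counts$station_id[counts$n >= min_n]
  keep <- data$station_id %in% keep_ids
  removed_obs <- sum(!keep)
  removed_stations <- dplyr::n_distinct(data$station_id[!keep])
  out <- data[keep, , drop = FALSE]
  if (!is.na(sc)) out <- set_obs_scale(out, sc)
  attr(out, "removed_obs") <- removed_obs
  attr(out, "removed_stations") <- removed_stations
  gwt_log("filter_min_observations: min_n = {min_n}; kept {nrow(out)} rows / {length(keep_ids)} stations; removed {removed_obs} observations at {removed_stations} stations.")
  out
}

#' Coefficient of variation for log-normal data
#'
#' For a variable that is log-normal, the coefficient of variation on the
#' original scale is `sqrt(exp(s_ln^2) - 1)` where `s_ln` is the standard
#' deviation of the natural-log values. Measurements here are log10, so
#' `s_ln = s10 * ln(10)` with `s10` the SD of the log10 values. A CV of 1
#' means the back-transformed SD matches the mean level — a useful screen for
#' stations whose variability is suspiciously large relative to their level.
#'
#' @param s10 Standard deviation(s) of log10-scale values; vectorised.
#' @return Dimensionless CV, same length as `s10`; 0 exactly when `s10 = 0`.
#' @examples
#' cv_lognormal(0.2)
#' cv_lognormal(sqrt(log(2)) / log(10)) # exactly 1
#' @export
cv_lognormal <- function(s10) {
  if (!is.numeric(s10)) {
    abort_validation("{.arg s10} must be numeric.")
  }
  if (any(s10 < 0, na.rm = TRUE)) {
    abort_validation("{.arg s10} must be non-negative (it is a standard deviation).")
  }
  s_ln <- s10 * log(10)
  sqrt(expm1(s_ln^2))
}

#' Per-station summaries on the log10 scale
#'
#' Computes, per station: observation count, mean and sample SD (denominator
#' n - 1) of the log10 values, the log-normal CV, first and last year
#' observed, and the crude change per year
#' `(last log10 value - first log10 value) / (last year - first year)`.
#' The crude change uses only the temporally first and last observations and
#' feeds the spatial-heterogeneity diagnostic ([morans_i()]); it is not a
#' trend estimate. Stations with a single observation get `NA` SD, CV and
#' change. When two rows tie for the first (or last) year, the earlier
#' (later) row in input order is used and the ambiguity is logged.
#'
#' @param data An observation table in scale `"log10"` (or
#'   `"log10_centered"`; SD and change are unaffected by centering).
#' @return A tibble with one row per station: `station_id`, `x`, `y`,
#'   `n_obs`, `mean_log`, `s10`, `s_ln`, `cv_lognormal`, `first_year`,
#'   `last_year`, `change_per_year`.
#' @export
station_summaries <- function(data) {
  check_scale(data, c("log10", "log10_centered"), "station_summaries()")
  data$.row <- seq_len(nrow(data))
  tie_stations <- 0L
  out <- data |>
    dplyr::group_by(.data$station_id, .data$x, .data$y) |>
    dplyr::summarise(
      n_obs = dplyr::n(),
      mean_log = mean(.data$value),
      s10 = if (dplyr::n() >= 2) sd(.data$value) else NA_real_,
      first_year = min(.data$year),
      last_year = max(.data$year),
      .first_val = .data$value[.data$year == min(.data$year)][1],
      .last_val = rev(.data$value[.data$year == max(.data$year)])[1],
      .tied = sum(.data$year == min(.data$year)) > 1 ||
        sum(.data$year == max(.data$year)) > 1,
      .groups = "drop"
    )
  # restore first-appearance order of stations
  first_seen <- tapply(data$.row, data$station_id, min)
  out <- out[order(first_seen[as.character(out$station_id)]), , drop = FALSE]
  tie_stations <- sum(out$.tied & out$last_year > out$first_year)
  out <- out |>
    dplyr::mutate(
      s_ln = .data$s10 * log(10),
      cv_lognormal = sqrt(expm1(.data$s_ln^2)),
      change_per_year = dplyr::if_else(
        .data$last_year > .data$first_year,
        (.data$.last_val - .data$.first_val) / (.data$last_year - .data$first_year),
        NA_real_
      )
    ) |>
    dplyr::select(
      "station_id", "x", "y", "n_obs", "mean_log", "s10", "s_ln",
      "cv_lognormal", "first_year", "last_year", "change_per_year"
    )
  if (tie_stations > 0) {
    gwt_log("station_summaries: {tie_stations} station{?s} had ties at the first or last year; used input order (earlier row first, later row last).")
  }
  gwt_log("station_summaries: {nrow(out)} stations summarised from {nrow(data) } observations.")
  out
}

#' Flag stations whose log-normal CV exceeds a threshold
#'
#' Stations with unusually large variation relative to their level either hold
#' suspect measurements or sit on a genuinely steep trend; the recommended
#' handling is to refit without them and compare slopes ([compare_fits()]),
#' not to downweight. The comparison is strict (`>`).
#'
#' @param summaries Output of [station_summaries()].
#' @param threshold CV cutoff, e.g. 0.8 or 1. Must be positive.
#' @return Character vector of flagged station ids (possibly empty).
#' @export
flag_high_cv <- function(summaries, threshold = 0.8) {
  if (!is.numeric(threshold) || length(threshold) != 1 || threshold <= 0) {
    abort_config("{.arg threshold} must be a single positive number.")
  }
  flagged <- summaries$station_id[
    !is.na(summaries$cv_lognormal) & summaries$cv_lognormal > threshold
  ]
  gwt_log("flag_high_cv: {length(flagged)} station{?s} with CV_log-normal > {threshold}.")
  as.character(flagged)
}

#' Station-wise mean-centering
#'
#' Subtracts each station's mean log10 value from its observations, leaving a
#' zero-mean series per station. In a rotating-panel design, stations enter
#' the record in different years; without centering, between-station level
#' differences masquerade as temporal trends in the pooled local regressions
#' (a window where high-level stations happen to be visited late shows a
#' spurious upward slope). Centering removes the level so only within-station
#' change remains. Idempotent on already-centered data.
#'
#' @param data An observation table in scale `"log10"` (or
#'   `"log10_centered"`, in which case it is re-centered, a no-op up to
#'   floating-point error).
#' @return The table with centered values, scale `"log10_centered"`.
#' @export
center_by_station <- function(data) {
  check_scale(data, c("log10", "log10_centered"), "center_by_station()")
  data <- data |>
    dplyr::group_by(.data$station_id) |>
    dplyr::mutate(value = .data$value - mean(.data$value)) |>
    dplyr::ungroup()
  gwt_log("center_by_station: centered {nrow(data)} rows at {dplyr::n_distinct(data$station_id)} stations.")
  set_obs_scale(data, "log10_centered")
}
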