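#' Classify station trends at a significance level
#'
#' Maps each station to `"down"` (p < alpha and negative slope), `"up"`
#' (p < alpha and positive slope) or `"none"` — the three colours of a
#' significance map. The comparison is strict: `p == alpha` is `"none"`.
#' P-values are unadjusted by design; the classes delineate candidate
#' regions, they are not confirmatory tests.
#'
#' @param result A `gwr_fit` object or a tidy per-station tibble with
#'   `slope` and `p_slope` columns.
#' @param alpha Significance level in (0, 1). Default 0.05.
#' @return A tibble `station_id`, `slope`, `p_slope`, `signif_class`
#'   (factor with levels down/none/up).
#' @export
significance_classes <- function(result, alpha = 0.05) {
  if (!is.numeric(alpha) || length(alpha) != 1 || alpha <= 0 || alpha >= 1) {
    abort_config("{.arg alpha} must be a single number in (0, 1).")
  }
  tab <- if (inherits(result, "gwr_fit")) result$stations else tibble::as_tibble(result)
  dplyr::tibble(
    station_id = tab$station_id,
    slope = tab$slope,
    p_slope = tab$p_slope,
    signif_class = classify_slope(tab$slope, tab$p_slope, alpha)
  )
}

#' Compare two trend fits station by station
#'
#' The validation move used throughout: refit after some change (stations
#' removed, different k, extra program merged) and look at how much each
#' station's slope moved and which stations changed significance class.
#' Differences are `fit_b - fit_a` on the stations present in both fits.
#'
#' @param fit_a,fit_b `gwr_fit` objects or tidy per-station tibbles.
#' @param alpha Level at which significance classes are recomputed.
#' @return An object of class `gwr_comparison`: [tidy()] gives the
#'   per-station table (`slope_a`, `slope_b`, `slope_difference`, classes,
#'   `class_flip`); [glance()] the summary (`n_common`,
#'   `max_abs_difference`, `n_class_flips`).
#' @export
compare_fits <- function(fit_a, fit_b, alpha = 0.05) {
  ta <- if (inherits(fit_a, "gwr_fit")) fit_a$stations else tibble::as_tibble(fit_a)
  tb <- if (inherits(fit_b, "gwr_fit")) fit_b$stations else tibble::as_tibble(fit_b)
  common <- dplyr::inner_join(
    dplyr::select(ta, "station_id", "x", "y", slope_a = "slope", p_a = "p_slope"),
    dplyr::select(tb, "station_id", slope_b = "slope", p_b = "p_slope"),
    by = "station_id"
  )
  if (nrow(common) == 0) {
    abort_validation("The two fits share no station; nothing to compare.")
  }
  common <- common |>
    dplyr::mutate(
      slope_difference = .data$slope_b - .data$slope_a,
      class_a = classify_slope(.data$slope_a, .data$p_a, alpha),
      class_b = classify_slope(.data$slope_b, .data$p_b, alpha),
      class_flip = .data$class_a != .data$class_b
    )
  summary <- tibble::tibble(
    n_common = nrow(common),
    max_abs_difference = max(abs(common$slope_difference)),
    n_class_flips = sum(common$class_flip),
    alpha = alpha
  )
  gwt_log("compare_fits: {nrow(common)} common stations; max |slope change| = {signif(summary$max_abs_difference, 4)}; {summary$n_class_flips} class flip{?s} at alpha = {alpha}.")
  structure(list(stations = common, summary = summary), class = "gwr_comparison")
}

#' Merge observation tables from several monitoring programs
#'
#' Because the estimator pools observations through spatial weights, programs
#' with different temporal resolution can be analysed jointly by simple
#' concatenation — e.g. a sparse rotating-panel survey plus a small
#' frequently sampled trend network. An optional inclusive month window per
#' table (e.g. `c(9, 12)` for autumn) subsets seasonally comparable rows
#' first. Station ids must be unique across programs.
#'
#' @param tables List of observation tables sharing one scale.
#' @param month_ranges Optional list, same length, each `NULL` or an
#'   inclusive `c(first_month, last_month)` pair applied to that table
#'   (requires its `month` column).
#' @param programs Optional character vector of program labels, one per
#'   table; when given it overrides any existing `program` column. Otherwise
#'   existing columns are kept and missing ones are filled from the list
#'   names, then `"program_<i>"`.
#' @return A single observation table in the shared scale, rows in
#'   list-then-input order, `program` column filled.
#' @export
combine_programs <- function(tables, month_ranges = NULL, programs = NULL) {
  if (!is.list(tables) || length(tables) == 0) {
    abort_config("{.arg tables} must be a non-empty list of observation tables.")
  }
  scales <- purrr::map_chr(tables, obs_scale)
  if (anyNA(scales) || length(unique(scales)) != 1) {
    abort_state("All tables must share one known scale; received {.val {scales}}.")
  }
  if (is.null(month_ranges)) month_ranges <- vector("list", length(tables))
  if (length(month_ranges) != length(tables)) {
    abort_config("{.arg month_ranges} must have one entry per table.")
  }
  labs <- if (!is.null(programs)) {
    programs
  } else if (!is.null(names(tables)) && all(names(tables) != "")) {
    names(tables)
  } else {
    paste0("program_", seq_along(tables))
  }
  prepared <- purrr::map(seq_along(tables), function(i) {
    tab <- tables[[i]]
    rng <- month_ranges[[i]]
    if (!is.null(rng)) {
      if (!"month" %in% names(tab)) {
        abort_config("Table {i} has no {.field month} column but a month range was requested.")
      }
      keep <- !is.na(tab$month) & tab$month >= rng[1] & tab$month <= rng[2]
      gwt_log("combine_programs: table {i}: month filter [{rng[1]}, {rng[2]}] kept {sum(keep)} of {nrow(tab)} rows.")
      tab <- tab[keep, , drop = FALSE]
    }
    if (!is.null(programs) || !"program" %in% names(tab)) tab$program <- labs[[i]]
    tab
  })
  ids <- purrr::map(prepared, function(tab) unique(tab$station_id))
  all_ids <- unlist(ids)
  coll <- unique(all_ids[duplicated(all_ids)])
  if (length(coll) > 0) {
    abort_validation("Station id{?s} {.val {head(coll, 5)}} appear in more than one program; ids must be unique across programs.")
  }
  out <- dplyr::bind_rows(prepared)
  out <- set_obs_scale(out, scales[[1]])
  gwt_log("combine_programs: merged {length(tables)} program{?s} into {nrow(out)} rows / {dplyr::n_distinct(out$station_id)} stations.")
  out
}

#' Moving-window trend fits for detecting nonlinearity
#'
#' A single linear slope per station cannot show a trend that turns. Fitting
#' the full pipeline inside fixed-length temporal windows advanced one step
#' at a time — per window: subset by year, re-apply the minimum-observation
#' filter, re-center stations within the window, re-select the neighbourhood
#' size by cross-validation, fit — and inspecting the slope fields side by
#' side reveals such reversals. Windows run from the earliest year until the
#' window end reaches the latest year (a 2008–2021 record with 10-year
#' windows and step 1 gives 2008–2017 … 2012–2021).
#'
#' @param data An observation table in scale `"log10"` (centering happens
#'   per window).
#' @param window_length Window length in years. Default 10.
#' @param step Advance between consecutive window starts, years. Default 1.
#' @param k_grid Candidate neighbourhood sizes passed to
#'   [select_bandwidth()] inside each window (candidates exceeding a
#'   window's observation count are dropped there).
#' @param min_n Minimum observations per station within a window. Default 2.
#' @param alpha Significance level forwarded to [fit_gwr()].
#' @return An object of class `gwr_windows`: a tibble with one row per
#'   window (`window_start`, `window_end`, `n_stations`, `n_obs`,
#'   `selected_k`, `empty`, and a `fit` list-column of `gwr_fit`).
#'   [tidy()] unnests per-station slopes across windows; [autoplot()] draws
#'   the slope evolution.
#' @export
moving_window_fit <- function(data, window_length = 10, step = 1, k_grid,
                              min_n = 2, alpha = 0.05) {
  check_scale(data, "log10", "moving_window_fit()")
  years <- range(data$year)
  span <- years[2] - years[1] + 1
  if (span < window_length) {
    abort_config("Data span {span} years; shorter than the {window_length}-year window.")
  }
  starts <- seq(years[1], years[2] - window_length + 1, by = step)
  rows <- purrr::map(starts, function(s) {
    e <- s + window_length - 1
    sub <- data[data$year >= s & data$year <= e, , drop = FALSE]
    sub <- set_obs_scale(sub, "log10")
    sub <- filter_min_observations(sub, min_n = min_n)
    n_st <- dplyr::n_distinct(sub$station_id)
    if (n_st < 3) {
      cli::cli_warn("Window {s}–{e}: only {n_st} station{?s} after filtering; window flagged empty.")
      return(tibble::tibble(
        window_start = s, window_end = e, n_stations = n_st,
        n_obs = nrow(sub), selected_k = NA_integer_, empty = TRUE,
        fit = list(NULL)
      ))
    }
    sub <- center_by_station(sub)
    sel <- select_bandwidth(sub, k_grid = k_grid)
    fit <- fit_gwr(sub, k = sel$selected_k, alpha = alpha)
    tibble::tibble(
      window_start = s, window_end = e, n_stations = n_st,
      n_obs = nrow(sub), selected_k = sel$selected_k, empty = FALSE,
      fit = list(fit)
    )
  })
  out <- dplyr::bind_rows(rows)
  gwt_log("moving_window_fit: {nrow(out)} windows of {window_length} years (step {step}) over {years[1]}–{years[2]}.")
  structure(out, class = c("gwr_windows", class(out)))
}
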