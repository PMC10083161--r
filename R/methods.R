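#' @export
print.gwr_fit <- function(x, ...) {
  cli::cli_text("{.cls gwr_fit}: local temporal trends at {nrow(x$stations)} stations ({x$n_obs} observations)")
  cli::cli_text("k = {x$k} ({x$kernel} kernel), effective df = {round(x$effective_df, 1)}, sigma2_hat = {signif(x$sigma2_hat, 4)}, overall adj. R2 = {signif(x$overall_adj_r2, 3)}")
  counts <- table(x$stations$signif_class)
  cli::cli_text("significance at alpha = {x$alpha}: {counts[['down']]} down / {counts[['none']]} none / {counts[['up']]} up")
  print(x$stations, ...)
  invisible(x)
}

#' Tidy and summarise fitted objects
#'
#' `tidy()` on a `gwr_fit` returns the per-station table (one row per
#' station: coordinates, coefficients, SEs, t/p, significance class, local
#' R-squared, bandwidth); `glance()` the one-row model summary. For a
#' `gwr_bandwidth` selection, `tidy()` is the CV-score grid. For
#' `gwr_comparison`, `tidy()`/`glance()` give per-station differences and
#' the flip summary. For `gwr_windows`, `tidy()` unnests per-station
#' results across windows.
#'
#' @param x A fitted object from this package.
#' @param ... Unused.
#' @return A tibble.
#' @name gwtrends-tidiers
NULL

#' @rdname gwtrends-tidiers
#' @export
tidy.gwr_fit <- function(x, ...) {
  x$stations
}

#' @rdname gwtrends-tidiers
#' @export
glance.gwr_fit <- function(x, ...) {
  tibble::tibble(
    k = x$k, kernel = x$kernel, n_obs = x$n_obs,
    n_stations = nrow(x$stations), sigma2_hat = x$sigma2_hat,
    trace_S = x$trace_S, trace_StS = x$trace_StS,
    effective_df = x$effective_df, rss = x$rss,
    overall_adj_r2 = x$overall_adj_r2
  )
}

#' @export
print.gwr_bandwidth <- function(x, ...) {
  cli::cli_text("{.cls gwr_bandwidth}: selected k = {x$selected_k} by leave-one-{x$loo}-out cross-validation")
  print(x$grid, ...)
  invisible(x)
}

#' @rdname gwtrends-tidiers
#' @export
tidy.gwr_bandwidth <- function(x, ...) {
  x$grid
}

#' @rdname gwtrends-tidiers
#' @export
glance.gwr_bandwidth <- function(x, ...) {
  tibble::tibble(
    selected_k = x$selected_k,
    min_cv_score = min(x$grid$cv_score),
    n_candidates = nrow(x$grid),
    loo = x$loo, kernel = x$kernel
  )
}

#' @export
print.gwr_comparison <- function(x, ...) {
  cli::cli_text("{.cls gwr_comparison}: {x$summary$n_common} common stations, max |slope change| = {signif(x$summary$max_abs_difference, 4)}, {x$summary$n_class_flips} class flips (alpha = {x$summary$alpha})")
  invisible(x)
}

#' @rdname gwtrends-tidiers
#' @export
tidy.gwr_comparison <- function(x, ...) {
  x$stations
}

#' @rdname gwtrends-tidiers
#' @export
glance.gwr_comparison <- function(x, ...) {
  x$summary
}

#' @rdname gwtrends-tidiers
#' @export
tidy.gwr_windows <- function(x, ...) {
  purrr::map(which(!x$empty), function(i) {
    tibble::add_column(
      tidy(x$fit[[i]]),
      window_start = x$window_start[i], window_end = x$window_end[i],
      selected_k = x$selected_k[i], .before = 1
    )
  }) |> dplyr::bind_rows()
}
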