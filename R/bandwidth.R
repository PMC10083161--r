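#' Leave-one-out cross-validation score for a neighbourhood size
#'
#' For each observation, the local model at its station is refitted with that
#' observation's weight set to zero — all other weights, and the bandwidth
#' ranks computed on the full observation set, unchanged — and the squared
#' error of the prediction at the observation's year is accumulated:
#' `score = sum_i (y_i - yhat_(-i))^2`. `loo = "station"` instead zeroes all
#' of the focal station's observations at once, predicting a station from its
#' neighbours only.
#'
#' Observations whose leave-one-out design is singular (too few positive
#' weights, or no spread in year) are excluded from the sum; their count is
#' logged and attached as attribute `"n_excluded"`.
#'
#' @inheritParams fit_gwr
#' @param loo Leave out a single `"observation"` (default) or the whole
#'   `"station"`.
#' @return The CV score (numeric scalar) with attribute `n_excluded`.
#' @export
cv_score <- function(data, k, kernel = c("bisquare", "uniform"),
                     loo = c("observation", "station"),
                     allow_uncentered = FALSE) {
  kernel <- match.arg(kernel)
  loo <- match.arg(loo)
  expected <- if (allow_uncentered) c("log10", "log10_centered") else "log10_centered"
  check_scale(data, expected, "cv_score()")
  n <- nrow(data)
  if (!is.numeric(k) || length(k) != 1 || k != round(k) || k < 3 || k > n) {
    abort_config("{.arg k} must be an integer with 3 <= k <= {n}.")
  }
  stations <- station_table(data)
  ox <- data$x
  oy <- data$y
  tt <- data$year
  yy <- data$value
  station_rows <- split(seq_len(n), factor(data$station_id, levels = stations$station_id))
  score <- 0
  n_excluded <- 0L
  for (i in seq_len(nrow(stations))) {
    d <- sqrt((ox - stations$x[i])^2 + (oy - stations$y[i])^2)
    b <- kth_smallest(d, k)
    w <- if (kernel == "uniform") rep(1, n) else {
      if (b <= 0) {
        n_excluded <- n_excluded + length(station_rows[[i]])
        next
      }
      bisquare_weight(d, b)
    }
    idx <- station_rows[[i]]
    if (loo == "station") {
      w2 <- w
      w2[idx] <- 0
      fit <- tryCatch(wls_line(tt, yy, w2), gwtrends_error = function(e) e)
      if (inherits(fit, "error")) {
        n_excluded <- n_excluded + length(idx)
        next
      }
      pred <- fit$ybar + fit$slope * (tt[idx] - fit$tbar)
      score <- score + sum((yy[idx] - pred)^2)
    } else {
      for (j in idx) {
        w2 <- w
        w2[j] <- 0
        fit <- tryCatch(wls_line(tt, yy, w2), gwtrends_error = function(e) e)
        if (inherits(fit, "error")) {
          n_excluded <- n_excluded + 1L
          next
        }
        pred <- fit$ybar + fit$slope * (tt[j] - fit$tbar)
        score <- score + (yy[j] - pred)^2
      }
    }
  }
  if (n_excluded > 0) {
    gwt_log("cv_score: k = {k}: {n_excluded} observation{?s} had singular leave-one-out fits and were excluded from the score.")
  }
  attr(score, "n_excluded") <- n_excluded
  score
}

#' Select the neighbourhood size by cross-validation
#'
#' Evaluates [cv_score()] over an explicit grid of candidate `k` values and
#' picks the minimiser; ties go to the smaller `k` (logged). An exhaustive
#' grid is used rather than a line search because the score need not be
#' convex in `k` and the full profile is worth inspecting ([autoplot()]
#' draws it).
#'
#' @inheritParams cv_score
#' @param k_grid Integer vector of candidate neighbourhood sizes
#'   (observations). Candidates larger than the number of observations are
#'   dropped with a log message.
#' @return An object of class `gwr_bandwidth`: [tidy()] gives the
#'   `(k, cv_score, n_excluded)` grid, `$selected_k` the chosen size.
#' @examples
#' cfg <- synthetic_config(n_stations = 50, noise_sd = 0.05, seed = 3)
#' obs <- simulate_survey(cfg, trend_surface(intercept = 0.9, slope = 0.005))
#' sel <- select_bandwidth(center_by_station(obs), k_grid = c(10, 25, 50))
#' sel$selected_k
#' @export
select_bandwidth <- function(data, k_grid, kernel = c("bisquare", "uniform"),
                             loo = c("observation", "station"),
                             allow_uncentered = FALSE) {
  kernel <- match.arg(kernel)
  loo <- match.arg(loo)
  if (length(k_grid) == 0) {
    abort_config("{.arg k_grid} must be a non-empty vector of candidate sizes.")
  }
  k_grid <- as.integer(sort(unique(k_grid)))
  n <- nrow(data)
  valid <- k_grid >= 3 & k_grid <= n
  if (any(!valid)) {
    gwt_log("select_bandwidth: dropped {sum(!valid)} candidate{?s} outside 3..{n}.")
    k_grid <- k_grid[valid]
  }
  if (length(k_grid) == 0) {
    abort_config("No valid candidates remain in {.arg k_grid} for {n} observations.")
  }
  scores <- purrr::map(k_grid, function(k) {
    s <- cv_score(data, k, kernel = kernel, loo = loo,
                  allow_uncentered = allow_uncentered)
    tibble::tibble(k = k, cv_score = as.numeric(s),
                   n_excluded = attr(s, "n_excluded"))
  }) |> dplyr::bind_rows()
  best <- min(scores$cv_score)
  winners <- scores$k[scores$cv_score == best]
  selected_k <- min(winners)
  if (length(winners) > 1) {
    gwt_log("select_bandwidth: tie among k = {winners}; choosing the smallest.")
  }
  gwt_log("select_bandwidth: selected k = {selected_k} (CV score {signif(best, 6)}) from grid of {nrow(scores)}.")
  structure(
    list(grid = scores, selected_k = selected_k, loo = loo, kernel = kernel),
    class = "gwr_bandwidth"
  )
}
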