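#' Bisquare kernel weight
#'
#' The compactly supported kernel used to downweight observations with
#' distance from the focal station:
#' `w = (1 - (d/b)^2)^2` for `d < b`, and 0 otherwise. The support boundary
#' is strict, so the observation exactly at the bandwidth distance receives
#' weight 0.
#'
#' @param d Distance(s), metres; non-negative. Vectorised.
#' @param b Bandwidth, metres; must be strictly positive.
#' @return Weights in `[0, 1]`, same length as `d`.
#' @examples
#' bisquare_weight(c(0, 0.5, 1, 2), b = 1)
#' @export
bisquare_weight <- function(d, b) {
  if (!is.numeric(b) || length(b) != 1 || !is.finite(b) || b <= 0) {
    abort_validation("Bandwidth {.arg b} must be a single strictly positive number.")
  }
  if (any(d < 0, na.rm = TRUE)) {
    abort_validation("Distances {.arg d} must be non-negative.")
  }
  ifelse(d < b, (1 - (d / b)^2)^2, 0)
}

#' Adaptive bandwidth: distance to the k-th nearest observation
#'
#' With spatially uneven sampling, a fixed-radius kernel would pool hundreds
#' of observations in dense regions and almost none in sparse ones. The
#' adaptive rule sets the bandwidth at each focal location to the Euclidean
#' distance of its k-th nearest observation (observations, not stations:
#' co-located observations each occupy a rank, and the focal station's own
#' observations are included at distance 0). Under the strict bisquare
#' support, the k-th neighbour itself then receives weight 0.
#'
#' @param focal Numeric length-2 vector `c(x, y)` of the focal location.
#' @param obs_coords Two-column matrix or data frame of all observation
#'   coordinates.
#' @param k Neighbourhood size in observations, `3 <= k <= nrow(obs_coords)`.
#' @return The bandwidth in metres. A returned 0 (k co-located observations)
#'   is degenerate and rejected by [bisquare_weight()] downstream.
#' @export
adaptive_bandwidth <- function(focal, obs_coords, k) {
  obs_coords <- as.matrix(obs_coords)
  n <- nrow(obs_coords)
  if (!is.numeric(k) || length(k) != 1 || k != round(k) || k < 3 || k > n) {
    abort_config("{.arg k} must be an integer with 3 <= k <= {n} (number of observations).")
  }
  d <- sqrt((obs_coords[, 1] - focal[1])^2 + (obs_coords[, 2] - focal[2])^2)
  b <- kth_smallest(d, k)
  if (b == 0) {
    gwt_log("adaptive_bandwidth: k = {k} co-located observations at ({focal[1]}, {focal[2]}); bandwidth 0 is degenerate.")
  }
  b
}

# Weighted least squares of y on (1, t), numerically centered in t.
# Returns coefficients in original t coordinates plus the pieces fit_gwr and
# cv_score need. Errors carry a class; station id (if known) is added by
# callers.
wls_line <- function(t, y, w) {
  pos <- w > 0
  npos <- sum(pos)
  if (npos < 2) {
    gwt_abort("Fewer than 2 observations with positive weight.",
              "gwtrends_insufficient_data_error")
  }
  if (length(unique(t[pos])) < 2) {
    gwt_abort("All positively weighted observations share one time value: local design is singular.",
              "gwtrends_singular_design_error")
  }
  sw <- sum(w)
  tbar <- sum(w * t) / sw
  tc <- t - tbar
  stc2 <- sum(w * tc^2)
  ybar <- sum(w * y) / sw
  slope <- sum(w * tc * y) / stc2
  intercept <- ybar - slope * tbar
  fitted <- ybar + slope * tc
  res <- y - fitted
  rss_w <- sum(w * res^2)
  tss_w <- sum(w * (y - ybar)^2)
  local_r2 <- if (tss_w > 0) 1 - rss_w / tss_w else NA_real_
  # unscaled covariance: Ainv %*% (X' W^2 X) %*% Ainv in centered coords,
  # mapped back with beta = M beta_c, M = [[1, -tbar], [0, 1]]
  ainv <- matrix(c(1 / sw, 0, 0, 1 / stc2), 2)
  bmat <- matrix(c(sum(w^2), sum(w^2 * tc), sum(w^2 * tc), sum(w^2 * tc^2)), 2)
  cc <- ainv %*% bmat %*% ainv
  m <- matrix(c(1, 0, -tbar, 1), 2)
  cov_unscaled <- m %*% cc %*% t(m)
  list(
    intercept = intercept, slope = slope, cov_unscaled = cov_unscaled,
    rss_w = rss_w, tss_w = tss_w, local_r2 = local_r2,
    n_pos = npos, sw = sw, tbar = tbar, ybar = ybar
  )
}

#' Weighted least squares line fit
#'
#' Fits `y = intercept + slope * t` by weighted least squares — the per-focal
#' regression at the heart of the estimator, exposed for inspection and
#' testing. The coefficient covariance is returned unscaled:
#' `Var(beta) = sigma^2 * (X'WX)^-1 X'W^2X (X'WX)^-1`, with the `sigma^2`
#' convention supplied by [fit_gwr()].
#'
#' @param t Numeric time values (years).
#' @param y Numeric responses.
#' @param w Non-negative weights; at least two positive weights spanning two
#'   distinct `t` values are required.
#' @return A list: `intercept`, `slope`, `cov_unscaled` (2x2, order
#'   intercept/slope), `rss_w` (weighted residual sum of squares), `tss_w`,
#'   `local_r2`, `n_pos`.
#' @export
local_wls <- function(t, y, w) {
  if (length(t) != length(y) || length(y) != length(w)) {
    abort_validation("{.arg t}, {.arg y} and {.arg w} must share one length.")
  }
  if (any(w < 0)) {
    abort_validation("Weights must be non-negative.")
  }
  fit <- wls_line(t, y, w)
  fit[c("intercept", "slope", "cov_unscaled", "rss_w", "tss_w", "local_r2", "n_pos")]
}

# classify a slope/p pair at level alpha (strict: p == alpha -> "none")
classify_slope <- function(slope, p, alpha) {
  out <- rep("none", length(slope))
  out[!is.na(p) & p < alpha & slope < 0] <- "down"
  out[!is.na(p) & p < alpha & slope > 0] <- "up"
  factor(out, levels = c("down", "none", "up"))
}

#' Fit geographically weighted temporal trends
#'
#' At each station, a local linear regression of the (centered) log10 values
#' on calendar year is fitted by weighted least squares, with bisquare
#' weights over the `k` nearest observations ([adaptive_bandwidth()],
#' [bisquare_weight()]). The result is a per-station trend slope (log10 units
#' per year), its standard error, t- and p-value, and local R-squared.
#'
#' Standard errors use a single global residual variance
#' `sigma2_hat = RSS / effective_df` with
#' `effective_df = n - 2 tr(S) + tr(S'S)`, `S` the hat matrix mapping all
#' observations to their locally fitted values; p-values are two-sided t with
#' `effective_df` degrees of freedom and are not adjusted for multiple
#' testing (columns `p_bh` and `p_bonferroni` are provided for optional
#' reporting). `sigma = "local"` switches to a per-station residual variance
#' `rss_w / (sum(w) - 2)`.
#'
#' Because each station contributes only a handful of observations, the fit
#' should normally run on station-wise mean-centered data
#' ([center_by_station()]); set `allow_uncentered = TRUE` to reproduce an
#' uncentered comparison run on `"log10"`-scale input.
#'
#' @param data An observation table in scale `"log10_centered"` (or
#'   `"log10"` with `allow_uncentered = TRUE`); every station needs at least
#'   2 observations ([filter_min_observations()]).
#' @param k Neighbourhood size in observations (>= 3).
#' @param kernel `"bisquare"` (default) or `"uniform"` — the latter gives all
#'   observations weight 1 and exists to verify the global-OLS limit at
#'   `k = n`.
#' @param sigma `"global"` (default) or `"local"` residual-variance
#'   convention for standard errors.
#' @param alpha Significance level for the reported `signif_class` column.
#' @return An object of class `gwr_fit`. [tidy()] returns the per-station
#'   table; [glance()] the one-row model summary (`k`, `n_obs`,
#'   `sigma2_hat`, `trace_S`, `trace_StS`, `effective_df`, `rss`,
#'   `overall_adj_r2`); [autoplot()] maps the slope field.
#' @examples
#' cfg <- synthetic_config(n_stations = 60, noise_sd = 0.05, seed = 1)
#' surf <- trend_surface(intercept = 0.9, slope = 0.01)
#' obs <- simulate_survey(cfg, surf)
#' fit <- fit_gwr(center_by_station(obs), k = 20)
#' glance(fit)
#' @export
fit_gwr <- function(data, k, kernel = c("bisquare", "uniform"),
                    sigma = c("global", "local"), alpha = 0.05,
                    allow_uncentered = FALSE) {
  kernel <- match.arg(kernel)
  sigma <- match.arg(sigma)
  expected <- if (allow_uncentered) c("log10", "log10_centered") else "log10_centered"
  scale_used <- check_scale(data, expected, "fit_gwr()")
  n <- nrow(data)
  if (!is.numeric(k) || length(k) != 1 || k != round(k) || k < 3 || k > n) {
    abort_config("{.arg k} must be an integer with 3 <= k <= {n} (number of observations).")
  }
  counts <- dplyr::count(data, .data$station_id)
  if (any(counts$n < 2)) {
    abort_validation(c(
      "{sum(counts$n < 2)} station{?s} have fewer than 2 observations.",
      i = "Apply {.fn filter_min_observations} before fitting."
    ))
  }
  stations <- station_table(data)
  ox <- data$x
  oy <- data$y
  tt <- data$year # wls_line centers internally, so raw years are safe here
  yy <- data$value
  station_rows <- split(seq_len(n), factor(data$station_id, levels = stations$station_id))

  m <- nrow(stations)
  res <- vector("list", m)
  trace_s <- 0
  trace_sts <- 0
  rss <- 0
  used_obs <- 0L
  used_y <- numeric(0)
  dropped <- character(0)
  for (i in seq_len(m)) {
    sx <- stations$x[i]
    sy <- stations$y[i]
    d <- sqrt((ox - sx)^2 + (oy - sy)^2)
    b <- kth_smallest(d, k)
    w <- if (kernel == "uniform") rep(1, n) else {
      if (b <= 0) {
        dropped <- c(dropped, stations$station_id[i])
        cli::cli_warn("Station {.val {stations$station_id[i]}}: bandwidth 0 ({k} co-located observations); fit skipped.")
        next
      }
      bisquare_weight(d, b)
    }
    fit <- tryCatch(wls_line(tt, yy, w), gwtrends_error = function(e) e)
    if (inherits(fit, "error")) {
      dropped <- c(dropped, stations$station_id[i])
      cli::cli_warn("Station {.val {stations$station_id[i]}}: {conditionMessage(fit)} Fit skipped and excluded from hat-matrix traces.")
      next
    }
    idx <- station_rows[[i]]
    # hat rows for this station's observations: s_j = w * (1/sw + tc_j * tc / stc2)
    tc <- tt - fit$tbar
    stc2 <- sum(w * tc^2)
    for (j in idx) {
      s_row <- w * (1 / fit$sw + tc[j] * tc / stc2)
      trace_s <- trace_s + s_row[j]
      trace_sts <- trace_sts + sum(s_row^2)
      fitted_j <- fit$ybar + fit$slope * tc[j]
      rss <- rss + (yy[j] - fitted_j)^2
    }
    used_obs <- used_obs + length(idx)
    used_y <- c(used_y, yy[idx])
    res[[i]] <- tibble::tibble(
      station_id = stations$station_id[i], x = sx, y = sy,
      n_obs = length(idx),
      intercept = fit$intercept,
      slope = fit$slope,
      var_intercept_unscaled = fit$cov_unscaled[1, 1],
      var_slope_unscaled = fit$cov_unscaled[2, 2],
      rss_w = fit$rss_w, local_r2 = fit$local_r2,
      bandwidth_dist = b, k = as.integer(k), n_positive_weight = fit$n_pos,
      sigma2_local = fit$rss_w / max(fit$sw - 2, .Machine$double.eps)
    )
  }
  fits <- dplyr::bind_rows(res)
  if (nrow(fits) == 0) {
    abort_degenerate("No station could be fitted.")
  }
  effective_df <- used_obs - 2 * trace_s + trace_sts
  sigma2_hat <- rss / effective_df
  scale_var <- if (sigma == "global") sigma2_hat else fits$sigma2_local
  fits$se_intercept <- sqrt(scale_var * fits$var_intercept_unscaled)
  fits$se_slope <- sqrt(scale_var * fits$var_slope_unscaled)
  fits$t_slope <- fits$slope / fits$se_slope
  fits$p_slope <- 2 * pt(-abs(fits$t_slope), df = effective_df)
  fits$p_bh <- stats::p.adjust(fits$p_slope, method = "BH")
  fits$p_bonferroni <- stats::p.adjust(fits$p_slope, method = "bonferroni")
  fits$signif_class <- classify_slope(fits$slope, fits$p_slope, alpha)
  tss <- sum((used_y - mean(used_y))^2)
  overall_adj_r2 <- 1 - (rss / effective_df) / (tss / (used_obs - 1))
  fits <- fits[, c("station_id", "x", "y", "n_obs", "intercept", "slope",
                   "se_intercept", "se_slope", "t_slope", "p_slope",
                   "p_bh", "p_bonferroni", "signif_class", "local_r2",
                   "bandwidth_dist", "k", "n_positive_weight", "sigma2_local")]
  gwt_log("fit_gwr: k = {k} ({kernel} kernel, {sigma} sigma^2), {nrow(fits)} stations / {used_obs} observations; effective df = {round(effective_df, 1)}; sigma2_hat = {signif(sigma2_hat, 4)}.")
  structure(
    list(
      stations = fits, k = as.integer(k), kernel = kernel, sigma = sigma,
      alpha = alpha, scale = scale_used, n_obs = used_obs,
      sigma2_hat = sigma2_hat, trace_S = trace_s, trace_StS = trace_sts,
      effective_df = effective_df, rss = rss,
      overall_adj_r2 = overall_adj_r2, dropped = dropped
    ),
    class = "gwr_fit"
  )
}
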