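test_that("bisquare kernel matches its closed form and support rules", {
  expect_equal(bisquare_weight(0, 1), 1)
  expect_equal(bisquare_weight(1, 1), 0) # strict support boundary
  expect_equal(bisquare_weight(0.5, 1), 0.5625)
  d <- seq(0, 3, by = 0.01)
  w <- bisquare_weight(d, 1.5)
  expect_true(all(w >= 0 & w <= 1))
  expect_true(all(diff(w) <= 1e-12)) # nonincreasing
  expect_true(all(w[d >= 1.5] == 0))
  expect_error(bisquare_weight(0.5, 0), class = "gwtrends_validation_error")
  expect_error(bisquare_weight(-1, 1), class = "gwtrends_validation_error")
})

test_that("adaptive bandwidth is the distance to the k-th nearest observation", {
  coords <- cbind(c(0, 1, 2, 3), c(0, 0, 0, 0))
  expect_equal(adaptive_bandwidth(c(0, 0), coords, k = 3), 2)
  expect_equal(adaptive_bandwidth(c(0, 0), coords, k = 4), 3)
  expect_error(adaptive_bandwidth(c(0, 0), coords, k = 2),
               class = "gwtrends_config_error")
  expect_error(adaptive_bandwidth(c(0, 0), coords, k = 5),
               class = "gwtrends_config_error")
  # k co-located observations: degenerate zero bandwidth
  co <- cbind(c(0, 0, 0, 5), c(0, 0, 0, 0))
  expect_equal(adaptive_bandwidth(c(0, 0), co, k = 3), 0)
})

test_that("local_wls interpolates two points and matches OLS at uniform weights", {
  fit <- local_wls(c(0, 1), c(0, 1), c(1, 1))
  expect_equal(fit$intercept, 0, tolerance = 1e-12)
  expect_equal(fit$slope, 1, tolerance = 1e-12)
  expect_equal(fit$local_r2, 1, tolerance = 1e-12)

  for (seed in 1:5) {
    set.seed(seed)
    t <- sample(2008:2021, 20, replace = TRUE)
    y <- 0.5 + 0.01 * t + rnorm(20, 0, 0.1)
    fit <- local_wls(t, y, rep(1, 20))
    ols <- lm(y ~ t)
    expect_equal(fit$intercept, unname(coef(ols)[1]), tolerance = 1e-10)
    expect_equal(fit$slope, unname(coef(ols)[2]), tolerance = 1e-10)
    # covariance contract at uniform weights reduces to sigma^2 (X'X)^-1
    expect_equal(fit$cov_unscaled, unname(summary(ols)$cov.unscaled),
                 tolerance = 1e-8, ignore_attr = TRUE)
  }
})

test_that("zero-weight observations are inert in local_wls", {
  set.seed(3)
  t <- c(2008, 2011, 2014, 2017, 2020)
  y <- rnorm(5)
  w <- c(1, 0.5, 0.25, 0.8, 0.1)
  base <- local_wls(t, y, w)
  poisoned <- local_wls(c(t, 1990, 2050), c(y, 100, -100), c(w, 0, 0))
  expect_equal(poisoned$intercept, base$intercept, tolerance = 1e-12)
  expect_equal(poisoned$slope, base$slope, tolerance = 1e-12)
  expect_equal(poisoned$rss_w, base$rss_w, tolerance = 1e-12)
})

test_that("local_wls rejects singular and insufficient designs", {
  expect_error(local_wls(c(2008, 2008, 2008), c(1, 2, 3), c(1, 1, 1)),
               class = "gwtrends_singular_design_error")
  expect_error(local_wls(c(2008, 2014), c(1, 2), c(1, 0)),
               class = "gwtrends_insufficient_data_error")
})

test_that("local_wls agrees with a brute-force grid minimiser", {
  set.seed(9)
  t <- c(0, 1, 2, 3, 5)
  y <- 0.3 + 0.2 * t + rnorm(5, 0, 0.05)
  w <- c(1, 0.7, 0.4, 0.9, 0.2)
  fit <- local_wls(t, y, w)
  obj <- function(a, b) sum(w * (y - a - b * t)^2)
  # coarse grid around the fit, then refinement
  best <- c(0, 0)
  centre <- c(0.3, 0.2)
  span <- c(0.5, 0.5)
  for (round in 1:6) {
    as <- seq(centre[1] - span[1], centre[1] + span[1], length.out = 21)
    bs <- seq(centre[2] - span[2], centre[2] + span[2], length.out = 21)
    vals <- outer(as, bs, Vectorize(obj))
    idx <- which(vals == min(vals), arr.ind = TRUE)[1, ]
    centre <- c(as[idx[1]], bs[idx[2]])
    span <- span / 8
  }
  expect_equal(fit$intercept, centre[1], tolerance = 1e-4)
  expect_equal(fit$slope, centre[2], tolerance = 1e-4)
})

test_that("noise-free constant-slope data are recovered exactly", {
  # uncentered fit: with a constant intercept field and zero noise, all
  # observations lie on one exact line
  cfg <- synthetic_config(n_stations = 50, noise_sd = 0, seed = 2)
  obs <- simulate_survey(cfg, trend_surface(intercept = 0.9, slope = 0.01))
  fit <- fit_gwr(obs, k = 20, allow_uncentered = TRUE)
  tab <- tidy(fit)
  expect_true(all(abs(tab$slope - 0.01) < 1e-10))
  expect_true(all(abs(tab$local_r2 - 1) < 1e-10 | is.na(tab$local_r2)))
  expect_lt(fit$rss, 1e-18)
  # centered fit stays exact when every station shares the visit years
  # (annual panel); under rotating panels centering subtracts panel-dependent
  # means and exactness is not expected
  cfg1 <- synthetic_config(n_stations = 40, n_panels = 1, noise_sd = 0, seed = 2)
  obs1 <- simulate_survey(cfg1, trend_surface(intercept = 0.9, slope = 0.01))
  fit1 <- fit_gwr(center_by_station(obs1), k = 20)
  expect_true(all(abs(tidy(fit1)$slope - 0.01) < 1e-10))
})

test_that("uniform kernel with k = n reproduces the global OLS fit everywhere", {
  obs <- center_by_station(random_obs(n_stations = 25, seed = 6))
  fit <- fit_gwr(obs, k = nrow(obs), kernel = "uniform")
  ols <- lm(value ~ year, data = obs)
  tab <- tidy(fit)
  expect_true(all(abs(tab$slope - coef(ols)[2]) < 1e-10))
  expect_true(all(abs(tab$intercept - coef(ols)[1]) < 1e-10))
})

test_that("slopes are invariant to per-station level shifts and year translation", {
  obs <- random_obs(n_stations = 30, seed = 8)
  cent <- center_by_station(obs)
  fit0 <- fit_gwr(cent, k = 25)

  # add an arbitrary constant per station, re-center: identical slopes
  shifts <- setNames(rnorm(dplyr::n_distinct(obs$station_id), 0, 2),
                     unique(obs$station_id))
  shifted <- obs
  shifted$value <- shifted$value + shifts[shifted$station_id]
  shifted <- set_obs_scale(shifted, "log10")
  fit1 <- fit_gwr(center_by_station(shifted), k = 25)
  expect_equal(tidy(fit1)$slope, tidy(fit0)$slope, tolerance = 1e-12)

  # translate all years: slopes identical, intercepts absorb the shift
  moved <- cent
  moved$year <- moved$year + 100L
  moved <- set_obs_scale(moved, "log10_centered")
  fit2 <- fit_gwr(moved, k = 25)
  expect_equal(tidy(fit2)$slope, tidy(fit0)$slope, tolerance = 1e-12)
  expect_equal(tidy(fit2)$se_slope, tidy(fit0)$se_slope, tolerance = 1e-10)
})

test_that("fit_gwr enforces scale state and minimum observations", {
  obs <- random_obs(n_stations = 20, seed = 10)
  expect_error(fit_gwr(obs, k = 10), class = "gwtrends_state_error")
  expect_no_error(fit_gwr(obs, k = 10, allow_uncentered = TRUE))
  # a station with one observation is refused
  extra <- obs[1, ]
  extra$station_id <- "LONER"
  extra$x <- extra$x + 123
  both <- set_obs_scale(dplyr::bind_rows(obs, extra), "log10")
  expect_error(fit_gwr(center_by_station(both), k = 10),
               class = "gwtrends_validation_error")
  expect_error(fit_gwr(center_by_station(obs), k = 2),
               class = "gwtrends_config_error")
})

test_that("model-level summaries are coherent", {
  obs <- center_by_station(random_obs(n_stations = 30, seed = 12))
  fit <- fit_gwr(obs, k = 25)
  g <- glance(fit)
  expect_gt(g$effective_df, 0)
  expect_gte(g$rss, 0)
  tab <- tidy(fit)
  expect_true(all(tab$p_slope >= 0 & tab$p_slope <= 1))
  expect_true(all(tab$se_slope > 0))
  expect_true(all(tab$local_r2 >= 0 & tab$local_r2 <= 1, na.rm = TRUE))
  expect_true(all(tab$n_positive_weight <= fit$k))
  # adjusted p columns dominate the raw p
  expect_true(all(tab$p_bh >= tab$p_slope - 1e-15))
  expect_true(all(tab$p_bonferroni >= tab$p_slope - 1e-15))
  # local sigma variant runs and gives positive SEs
  fl <- fit_gwr(obs, k = 25, sigma = "local")
  expect_true(all(tidy(fl)$se_slope > 0))
})

test_that("slope-field spatial variance is nonincreasing in k (up to jitter)", {
  obs <- center_by_station(random_obs(n_stations = 60, seed = 14, noise_sd = 0.1))
  ks <- c(20, 50, 100, 140)
  vars <- sapply(ks, function(k) var(tidy(fit_gwr(obs, k = k))$slope))
  expect_true(all(diff(vars) <= 0.1 * vars[-length(vars)] + 1e-12))
})
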