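test_that("the generator is fully deterministic given a config", {
  cfg <- synthetic_config(n_stations = 80, noise_sd = 0.1, seed = 5)
  surf <- two_region_surface()
  a <- simulate_survey(cfg, surf)
  b <- simulate_survey(cfg, surf)
  expect_identical(as.data.frame(a), as.data.frame(b))
  # different seed: identical design rows, different values
  cfg2 <- synthetic_config(n_stations = 80, noise_sd = 0.1, seed = 6)
  net <- generate_network(cfg)
  sched <- assign_panels(net, cfg)
  o1 <- simulate_observations(sched, surf, cfg)
  o2 <- simulate_observations(sched, surf, cfg2)
  expect_identical(o1[c("station_id", "x", "y", "year")],
                   o2[c("station_id", "x", "y", "year")])
  expect_false(any(o1$value == o2$value))
})

test_that("network respects bounds, size and density gradient", {
  cfg <- synthetic_config(n_stations = 100, seed = 1)
  net <- generate_network(cfg)
  expect_equal(nrow(net), 100)
  b <- cfg$bounds
  expect_true(all(net$x >= b[["xmin"]] & net$x <= b[["xmax"]]))
  expect_true(all(net$y >= b[["ymin"]] & net$y <= b[["ymax"]]))
  expect_equal(dplyr::n_distinct(net$station_id), 100)
  # single station
  net1 <- generate_network(synthetic_config(n_stations = 1, seed = 2))
  expect_equal(nrow(net1), 1)
  # 2:1 south:north linear gradient: southern-half mass is
  # int_0^.5 (2 - u) du / int_0^1 (2 - u) du = 7/12; binomial test
  cfgd <- synthetic_config(n_stations = 5000, density_ratio = 2, seed = 3)
  netd <- generate_network(cfgd)
  south <- sum(netd$y < mean(b[c("ymin", "ymax")]))
  expect_gt(south, 2500) # more stations in the south
  pval <- binom.test(south, 5000, p = 7 / 12)$p.value
  expect_gt(pval, 0.001)
  expect_error(
    synthetic_config(bounds = c(xmin = 0, xmax = 0, ymin = 0, ymax = 1)),
    class = "gwtrends_validation_error"
  )
})

test_that("panel schedule follows the rotating modular design", {
  cfg <- synthetic_config(n_stations = 90, n_panels = 6, years = 2008:2021, seed = 4)
  net <- generate_network(cfg)
  sched <- assign_panels(net, cfg)
  visits <- dplyr::count(sched, .data$station_id, .data$panel)
  # panels starting 2008 and 2009 (panel 0 and 1) are seen 3 times, others 2
  expect_true(all(visits$n[visits$panel %in% c(0, 1)] == 3))
  expect_true(all(visits$n[visits$panel %in% 2:5] == 2))
  # revisit interval equals the number of panels
  gaps <- sched |>
    dplyr::group_by(.data$station_id) |>
    dplyr::summarise(g = list(diff(sort(.data$year))), .groups = "drop")
  expect_true(all(unlist(gaps$g) == 6))
  # one panel means every station is seen every year
  cfg1 <- synthetic_config(n_stations = 10, n_panels = 1, years = 2008:2012, seed = 4)
  s1 <- assign_panels(generate_network(cfg1), cfg1)
  expect_equal(nrow(s1), 10 * 5)
  # reproducible partition
  s2 <- assign_panels(generate_network(cfg1), cfg1)
  expect_identical(s1, s2)
})

test_that("simulated values follow the surface model with the configured noise", {
  # noise-free values sit exactly on the local line of the surface
  cfg0 <- synthetic_config(n_stations = 30, noise_sd = 0, seed = 8)
  surf <- trend_surface(intercept = 0.9, slope = 0.01)
  obs0 <- simulate_survey(cfg0, surf)
  mid <- mean(range(cfg0$years))
  expect_equal(obs0$value, 0.9 + 0.01 * (obs0$year - mid), tolerance = 1e-12)
  expect_identical(obs_scale(obs0), "log10")
  # Monte-Carlo: empirical SD of replicated draws matches noise_sd within 2%
  cfgm <- synthetic_config(n_stations = 1, n_panels = 1, years = 2010L,
                           obs_per_visit = 10000, noise_sd = 0.1, seed = 9)
  obsm <- simulate_survey(cfgm, surf)
  expect_equal(sd(obsm$value), 0.1, tolerance = 0.02)
})

test_that("truth attribute matches the surface at station locations", {
  cfg <- synthetic_config(n_stations = 40, seed = 10)
  surf <- two_region_surface()
  obs <- simulate_survey(cfg, surf)
  truth <- attr(obs, "truth")
  expect_equal(nrow(truth), 40)
  st <- dplyr::distinct(obs, .data$station_id, .data$x, .data$y)
  joined <- dplyr::inner_join(truth, st, by = "station_id")
  expect_equal(joined$true_slope, eval_surface(surf, joined$x, joined$y, "slope"))
})

test_that("outlier injection shifts only the first observation of chosen stations", {
  cfg <- synthetic_config(n_stations = 50, noise_sd = 0.05,
                          outlier_fraction = 0.2, outlier_shift = 0.8, seed = 11)
  surf <- trend_surface(intercept = 0.9, slope = 0)
  net <- generate_network(cfg)
  sched <- assign_panels(net, cfg)
  clean <- simulate_observations(sched, surf, cfg)
  dirty <- inject_outliers(clean, cfg)
  injected <- attr(dirty, "outlier_stations")
  expect_equal(length(injected), 10)
  delta <- dirty$value - clean$value
  changed <- which(delta != 0)
  expect_equal(length(changed), 10)
  expect_true(all(abs(delta[changed] - 0.8) < 1e-15))
  # each changed row is its station's earliest observation
  for (i in changed) {
    rows <- clean$station_id == clean$station_id[i]
    expect_equal(clean$year[i], min(clean$year[rows]))
  }
  # fraction 0: unchanged, empty list
  cfg0 <- synthetic_config(n_stations = 50, outlier_fraction = 0, seed = 11)
  same <- inject_outliers(clean, cfg0)
  expect_identical(same$value, clean$value)
  expect_length(attr(same, "outlier_stations"), 0)
  # zero shift: values unchanged though stations are listed
  cfgz <- synthetic_config(n_stations = 50, outlier_fraction = 0.2,
                           outlier_shift = 0, seed = 11)
  z <- inject_outliers(clean, cfgz)
  expect_identical(z$value, clean$value)
  expect_length(attr(z, "outlier_stations"), 10)
})

test_that("outlier-screen recall is nondecreasing in the injected shift", {
  shifts <- c(0.2, 0.5, 0.8, 1.2)
  recall <- sapply(shifts, function(sh) {
    cfg <- synthetic_config(n_stations = 200, noise_sd = 0.05,
                            outlier_fraction = 0.1, outlier_shift = sh, seed = 12)
    obs <- simulate_survey(cfg, trend_surface(intercept = 0.9, slope = 0))
    injected <- attr(obs, "outlier_stations")
    flagged <- flag_high_cv(station_summaries(obs), threshold = 0.8)
    mean(injected %in% flagged)
  })
  expect_true(all(diff(recall) >= 0))
})
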