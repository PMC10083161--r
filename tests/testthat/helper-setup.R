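options(gwtrends.verbose = FALSE)

# small hand-built observation table: ids, coords in km-scale metres
toy_obs <- function(scale = "log10") {
  as_obs_table(tibble::tibble(
    station_id = c("A", "A", "B", "B", "B", "C", "C"),
    x = c(1e4, 1e4, 5e4, 5e4, 5e4, 9e4, 9e4),
    y = c(2e4, 2e4, 6e4, 6e4, 6e4, 1e5, 1e5),
    year = c(2008L, 2014L, 2009L, 2015L, 2021L, 2010L, 2016L),
    value = c(1.0, 1.2, 0.8, 0.9, 1.0, 0.5, 0.4)
  ), scale = scale)
}

# random many-station table on the log10 scale (values ~ level + slope*t + noise)
random_obs <- function(n_stations = 40, seed = 1, noise_sd = 0.05,
                       slope = 0.01, years = 2008:2021, n_panels = 6) {
  cfg <- synthetic_config(
    n_stations = n_stations, n_panels = n_panels, years = years,
    noise_sd = noise_sd, seed = seed
  )
  simulate_survey(cfg, trend_surface(intercept = 0.9, slope = slope))
}
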