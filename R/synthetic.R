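#' Smooth spatial trend surfaces
#'
#' True intercept and slope fields for simulation, each a constant plus a sum
#' of (optionally anisotropic) Gaussian bumps. Closed-form truth makes bias
#' and RMSE of the estimator exactly accountable at any coordinate.
#'
#' @param intercept,slope Constant terms: baseline log10 level and baseline
#'   slope (log10 units per year).
#' @param intercept_bumps,slope_bumps `NULL` or a data frame with columns
#'   `x`, `y` (bump centre, metres), `sd_x` (width, metres), optional `sd_y`
#'   (defaults to `sd_x`) and `amplitude` (same units as the constant).
#' @return An object of class `trend_surface`.
#' @seealso [two_region_surface()], [eval_surface()]
#' @export
trend_surface <- function(intercept = 0.9, slope = 0,
                          intercept_bumps = NULL, slope_bumps = NULL) {
  check_bumps <- function(b, what) {
    if (is.null(b)) {
      return(tibble::tibble(x = numeric(0), y = numeric(0), sd_x = numeric(0),
                            sd_y = numeric(0), amplitude = numeric(0)))
    }
    b <- tibble::as_tibble(b)
    need <- c("x", "y", "sd_x", "amplitude")
    if (!all(need %in% names(b))) {
      abort_config("{what} needs columns {.field {need}} (and optionally sd_y).")
    }
    if (!"sd_y" %in% names(b)) b$sd_y <- b$sd_x
    if (any(b$sd_x <= 0 | b$sd_y <= 0)) {
      abort_config("Bump widths must be strictly positive.")
    }
    b[c("x", "y", "sd_x", "sd_y", "amplitude")]
  }
  structure(
    list(
      intercept_const = intercept, slope_const = slope,
      intercept_bumps = check_bumps(intercept_bumps, "intercept_bumps"),
      slope_bumps = check_bumps(slope_bumps, "slope_bumps")
    ),
    class = "trend_surface"
  )
}

#' Evaluate a trend surface at coordinates
#'
#' @param surface A [trend_surface()].
#' @param x,y Coordinate vectors, metres.
#' @param what `"slope"` or `"intercept"` field.
#' @return Numeric vector of field values.
#' @export
eval_surface <- function(surface, x, y, what = c("slope", "intercept")) {
  what <- match.arg(what)
  stopifnot(inherits(surface, "trend_surface"))
  const <- if (what == "slope") surface$slope_const else surface$intercept_const
  bumps <- if (what == "slope") surface$slope_bumps else surface$intercept_bumps
  out <- rep(const, length(x))
  for (i in seq_len(nrow(bumps))) {
    out <- out + bumps$amplitude[i] * exp(
      -0.5 * (((x - bumps$x[i]) / bumps$sd_x[i])^2 +
                ((y - bumps$y[i]) / bumps$sd_y[i])^2)
    )
  }
  out
}

#' Reference two-region slope field
#'
#' A west/east split of the trend direction, mimicking the situation where
#' one part of the country browns while another recovers: the slope field is
#' `slope_east` everywhere plus a Gaussian ridge anchored at the western edge
#' that lifts the west to `slope_west`. The sign boundary (where the field
#' crosses zero) is returned as attribute `"boundary_x"` so simulation
#' studies can separate interior stations from the transition zone exactly.
#'
#' @param bounds Named numeric vector `c(xmin, xmax, ymin, ymax)`, metres.
#' @param slope_west,slope_east Slope values (log10/yr) attained at the west
#'   edge and far east. Defaults +0.015 / -0.02, the magnitude range typical
#'   of decadal lake browning signals.
#' @param intercept Constant intercept field (log10 level). Default 0.9
#'   (about 8 mg/L).
#' @return A [trend_surface()] with attribute `boundary_x`.
#' @export
two_region_surface <- function(bounds = c(xmin = 0, xmax = 5e5, ymin = 0, ymax = 1.5e6),
                               slope_west = 0.015, slope_east = -0.02,
                               intercept = 0.9) {
  width <- bounds[["xmax"]] - bounds[["xmin"]]
  sd_x <- 0.45 * width
  amp <- slope_west - slope_east
  surf <- trend_surface(
    intercept = intercept, slope = slope_east,
    slope_bumps = tibble::tibble(
      x = bounds[["xmin"]], y = mean(bounds[c("ymin", "ymax")]),
      sd_x = sd_x, sd_y = 1e12, amplitude = amp
    )
  )
  # field crosses 0 where amp * exp(-u^2/2) = -slope_east
  if (slope_east < 0 && slope_west > 0) {
    u <- sqrt(2 * log(amp / (-slope_east)))
    attr(surf, "boundary_x") <- bounds[["xmin"]] + u * sd_x
  }
  surf
}

#' Configuration of a synthetic rotating-panel survey
#'
#' Design parameters mirroring a national lake survey: many stations split
#' into panels revisited on a fixed cycle, so each station holds only 2–3
#' observations over the study period. Defaults follow that template: 800
#' stations over a 500 x 1500 km domain, 6 panels, years 2008–2021 (so
#' panels starting in the first two years are visited three times, the rest
#' twice), one observation per visit, log10-scale noise SD 0.1.
#'
#' @param n_stations Number of stations.
#' @param bounds Domain `c(xmin, xmax, ymin, ymax)`, metres.
#' @param n_panels Number of revisit panels (revisit time in years).
#' @param years Integer vector of survey years.
#' @param obs_per_visit Observations recorded per station visit.
#' @param noise_sd Log10-scale SD of the i.i.d. Gaussian measurement/short-term
#'   noise.
#' @param outlier_fraction Fraction of stations whose first observation is
#'   shifted by `outlier_shift` ([inject_outliers()]).
#' @param outlier_shift Log10 shift applied to injected outliers.
#' @param density_ratio South:north station-density ratio (>= 1 puts more
#'   stations at low `y`). Default 1 (uniform).
#' @param seed Integer master seed; placement, panel shuffle, noise and
#'   outlier choice use fixed distinct offsets of it, so the design is
#'   byte-reproducible and the noise stream is independent of the design
#'   stream.
#' @return A validated list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_stations = 800,
                             bounds = c(xmin = 0, xmax = 5e5, ymin = 0, ymax = 1.5e6),
                             n_panels = 6, years = 2008:2021,
                             obs_per_visit = 1, noise_sd = 0.1,
                             outlier_fraction = 0, outlier_shift = 0,
                             density_ratio = 1, seed = 1) {
  if (n_stations < 1) abort_config("{.arg n_stations} must be >= 1.")
  if (bounds[["xmax"]] <= bounds[["xmin"]] || bounds[["ymax"]] <= bounds[["ymin"]]) {
    abort_validation("Degenerate domain bounds: max must exceed min in both axes.")
  }
  if (n_panels < 1 || n_panels > length(years)) {
    abort_config("{.arg n_panels} must be between 1 and the number of years.")
  }
  if (noise_sd < 0) abort_config("{.arg noise_sd} must be >= 0.")
  if (outlier_fraction < 0 || outlier_fraction > 1) {
    abort_config("{.arg outlier_fraction} must lie in [0, 1].")
  }
  if (density_ratio < 1) abort_config("{.arg density_ratio} must be >= 1 (south-heavy or uniform).")
  structure(
    list(
      n_stations = as.integer(n_stations), bounds = bounds,
      n_panels = as.integer(n_panels), years = as.integer(years),
      obs_per_visit = as.integer(obs_per_visit), noise_sd = noise_sd,
      outlier_fraction = outlier_fraction, outlier_shift = outlier_shift,
      density_ratio = density_ratio, seed = as.integer(seed)
    ),
    class = "synthetic_config"
  )
}

# fixed sub-seed offsets (kept < 2^31 for small master seeds)
seed_for <- function(config, purpose) {
  off <- c(network = 0L, panels = 1000003L, noise = 2000003L, outliers = 3000003L)
  config$seed + off[[purpose]]
}

#' Generate a station network
#'
#' Places `n_stations` uniformly in the domain, or with a linear south-north
#' density gradient (`density_ratio` > 1 emulates the denser sampling of the
#' populated south). Reproducible from the config seed.
#'
#' @param config A [synthetic_config()].
#' @return Tibble `station_id`, `x`, `y`.
#' @export
generate_network <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  b <- config$bounds
  n <- config$n_stations
  r <- config$density_ratio
  withr::with_seed(seed_for(config, "network"), {
    x <- runif(n, b[["xmin"]], b[["xmax"]])
    v <- runif(n)
    u <- if (r == 1) v else (r - sqrt(r^2 - (r^2 - 1) * v)) / (r - 1)
    y <- b[["ymin"]] + u * (b[["ymax"]] - b[["ymin"]])
  })
  gwt_log("generate_network: {n} stations, density ratio {r}, seed {seed_for(config, 'network')}.")
  tibble::tibble(
    station_id = sprintf("S%05d", seq_len(n)),
    x = x, y = y
  )
}

#' Assign stations to revisit panels and build the visit schedule
#'
#' Stations are shuffled (seeded) and dealt round-robin into `n_panels`
#' panels; panel `p` is visited in the years where
#' `(year - first_year) mod n_panels == p`. Over 2008–2021 with 6 panels,
#' panels starting 2008 and 2009 are visited three times and the others
#' twice.
#'
#' @param stations Output of [generate_network()] (or any tibble with
#'   `station_id`, `x`, `y`).
#' @param config A [synthetic_config()].
#' @return Schedule tibble: one row per (station, year) visit, columns
#'   `station_id`, `x`, `y`, `panel`, `year`.
#' @export
assign_panels <- function(stations, config) {
  stopifnot(inherits(config, "synthetic_config"))
  n <- nrow(stations)
  withr::with_seed(seed_for(config, "panels"), {
    perm <- sample.int(n)
  })
  panel <- integer(n)
  panel[perm] <- (seq_len(n) - 1L) %% config$n_panels
  years <- config$years
  sched <- tibble::tibble(
    station_id = stations$station_id, x = stations$x, y = stations$y,
    panel = panel
  ) |>
    tidyr::expand_grid(year = years) |>
    dplyr::filter((.data$year - years[1]) %% config$n_panels == .data$panel)
  gwt_log("assign_panels: {n} stations into {config$n_panels} panel{?s}; {nrow(sched)} visits over {min(years)}–{max(years)}.")
  sched
}

#' Simulate observations from a schedule and a trend surface
#'
#' Each visit yields `obs_per_visit` values
#' `intercept_field(x, y) + slope_field(x, y) * (year - mid_year) + N(0, noise_sd^2)`
#' on the log10 scale. Time is centered at the survey mid-year inside the
#' simulator only, to decouple the intercept and slope fields; the fitted
#' model is invariant to that choice. With the same schedule, changing the
#' seed changes the noise but not the design rows.
#'
#' @param schedule Output of [assign_panels()].
#' @param surface A [trend_surface()].
#' @param config A [synthetic_config()].
#' @return An observation table in scale `"log10"` (use
#'   `10^value` for a raw-scale export), carrying per-station truth in
#'   attribute `"truth"` (`station_id`, `true_intercept`, `true_slope`).
#' @export
simulate_observations <- function(schedule, surface, config) {
  stopifnot(inherits(config, "synthetic_config"), inherits(surface, "trend_surface"))
  mid_year <- mean(range(config$years))
  obs <- schedule[rep(seq_len(nrow(schedule)), each = config$obs_per_visit), , drop = FALSE]
  f0 <- eval_surface(surface, obs$x, obs$y, "intercept")
  f1 <- eval_surface(surface, obs$x, obs$y, "slope")
  withr::with_seed(seed_for(config, "noise"), {
    eps <- rnorm(nrow(obs), 0, config$noise_sd)
  })
  out <- tibble::tibble(
    station_id = obs$station_id, x = obs$x, y = obs$y,
    year = as.integer(obs$year),
    value = f0 + f1 * (obs$year - mid_year) + eps,
    program = "synthetic"
  )
  out <- as_obs_table(out, scale = "log10")
  st <- dplyr::distinct(schedule, .data$station_id, .data$x, .data$y)
  attr(out, "truth") <- tibble::tibble(
    station_id = st$station_id,
    true_intercept = eval_surface(surface, st$x, st$y, "intercept"),
    true_slope = eval_surface(surface, st$x, st$y, "slope")
  )
  gwt_log("simulate_observations: {nrow(out)} observations at {nrow(st)} stations; noise SD {config$noise_sd}; seed {seed_for(config, 'noise')}.")
  out
}

#' Inject first-observation outliers
#'
#' Shifts the temporally first observation of a seeded random fraction of
#' stations by `outlier_shift` log10 units — the failure mode where an
#' erroneous early value manufactures an artificial trend. The injected
#' station ids are attached as attribute `"outlier_stations"` so screening
#' rules can be scored against the truth.
#'
#' @param data An observation table.
#' @param config A [synthetic_config()] supplying `outlier_fraction`,
#'   `outlier_shift` and the seed.
#' @return The table with shifted values (same scale), attribute
#'   `"outlier_stations"` listing injected stations.
#' @export
inject_outliers <- function(data, config) {
  stopifnot(inherits(config, "synthetic_config"))
  sc <- obs_scale(data)
  ids <- unique(data$station_id)
  n_inject <- round(config$outlier_fraction * length(ids))
  if (n_inject == 0) {
    attr(data, "outlier_stations") <- character(0)
    return(data)
  }
  withr::with_seed(seed_for(config, "outliers"), {
    chosen <- sample(ids, n_inject)
  })
  for (id in chosen) {
    rows <- which(data$station_id == id)
    first <- rows[which.min(data$year[rows])]
    data$value[first] <- data$value[first] + config$outlier_shift
  }
  if (!is.na(sc)) data <- set_obs_scale(data, sc)
  attr(data, "outlier_stations") <- as.character(chosen)
  gwt_log("inject_outliers: shifted the first observation of {n_inject} station{?s} by {config$outlier_shift} log10 units.")
  data
}

#' One-call synthetic survey
#'
#' Chains [generate_network()], [assign_panels()],
#' [simulate_observations()] and (when `outlier_fraction > 0`)
#' [inject_outliers()].
#'
#' @param config A [synthetic_config()].
#' @param surface A [trend_surface()].
#' @return An observation table in scale `"log10"` with attributes
#'   `"truth"` and `"outlier_stations"`.
#' @export
simulate_survey <- function(config, surface) {
  net <- generate_network(config)
  sched <- assign_panels(net, config)
  obs <- simulate_observations(sched, surface, config)
  truth <- attr(obs, "truth")
  if (config$outlier_fraction > 0) {
    obs <- inject_outliers(obs, config)
    attr(obs, "truth") <- truth
  } else {
    attr(obs, "outlier_stations") <- character(0)
  }
  obs
}
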