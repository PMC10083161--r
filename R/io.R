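#' Read a long-format observation table from CSV
#'
#' Reads one row per (station, year) measurement. Column names in the file can
#' differ from the canonical names via `column_map`. The file is read in input
#' order, which is preserved everywhere downstream, and rows sharing a
#' (station, year) pair are all retained.
#'
#' @param path Path to a CSV file (comma-separated, header row, UTF-8).
#' @param column_map Named character vector mapping canonical names
#'   (`station_id`, `x`, `y`, `year`, `value`, and optionally `program`,
#'   `month`) to the column names used in the file. Unmentioned names default
#'   to themselves.
#' @param scale Scale of the `value` column in the file; monitoring exports
#'   are normally `"raw"` concentrations.
#'
#' @return An observation table (see [as_obs_table()]) in the given scale.
#' @seealso [write_gwr_results()]
#' @examples
#' f <- tempfile(fileext = ".csv")
#' writeLines(c(
#'   "station_id,x,y,year,value",
#'   "A,100000,6400000,2008,8.2",
#'   "A,100000,6400000,2014,9.1",
#'   "B,200000,6500000,2010,3.3"
#' ), f)
#' read_observations(f)
#' @export
read_observations <- function(path, column_map = NULL, scale = "raw") {
  if (!file.exists(path)) {
    abort_config("File {.path {path}} does not exist.")
  }
  canonical <- c("station_id", "x", "y", "year", "value", "program", "month")
  map <- setNames(canonical, canonical)
  if (!is.null(column_map)) {
    unknown <- setdiff(names(column_map), canonical)
    if (length(unknown) > 0) {
      abort_config("Unknown column-map entr{?y/ies}: {.field {unknown}}.")
    }
    map[names(column_map)] <- unlist(column_map)
  }
  raw <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  required <- c("station_id", "x", "y", "year", "value")
  missing_cols <- map[required][!map[required] %in% names(raw)]
  if (length(missing_cols) > 0) {
    abort_config("Input file lacks required column{?s} {.field {unname(missing_cols)}}.")
  }
  out <- tibble::tibble(
    station_id = raw[[map[["station_id"]]]],
    x = parse_num_col(raw[[map[["x"]]]], map[["x"]]),
    y = parse_num_col(raw[[map[["y"]]]], map[["y"]]),
    year = parse_num_col(raw[[map[["year"]]]], map[["year"]]),
    value = parse_num_col(raw[[map[["value"]]]], map[["value"]])
  )
  if (map[["program"]] %in% names(raw)) out$program <- raw[[map[["program"]]]]
  if (map[["month"]] %in% names(raw)) {
    out$month <- parse_num_col(raw[[map[["month"]]]], map[["month"]], allow_na = TRUE)
  }
  tab <- as_obs_table(out, scale = scale)
  gwt_log("read_observations: {nrow(tab)} rows, {dplyr::n_distinct(tab$station_id)} stations from {.path {path}} (scale = {scale}).")
  tab
}

parse_num_col <- function(x, name, allow_na = FALSE) {
  out <- suppressWarnings(as.numeric(x))
  bad <- which(is.na(out) & !(allow_na & (is.na(x) | x == "")))
  if (length(bad) > 0) {
    abort_validation(
      "Column {.field {name}}: value missing or not numeric in row(s) {paste(head(bad, 5), collapse = ', ')}{if (length(bad) > 5) ' ...' else ''}."
    )
  }
  out
}

#' Write per-station trend results to CSV or GeoJSON
#'
#' Emits one record per station with columns `station_id`, `x`, `y`, `n_obs`,
#' `intercept`, `slope`, `se_intercept`, `se_slope`, `t_slope`, `p_slope`,
#' `signif_class`, `local_r2`, `bandwidth_dist`, `k`. The CSV round-trips all
#' numeric fields at full double precision; the GeoJSON output is an RFC 7946
#' FeatureCollection of Point features carrying the same fields as properties,
#' for direct display in any GIS.
#'
#' @param result A [fit_gwr()] result or its [tidy()] tibble.
#' @param path Output file path.
#' @param format `"csv"` or `"geojson"`.
#' @return `path`, invisibly.
#' @seealso [read_gwr_results()]
#' @export
write_gwr_results <- function(result, path, format = c("csv", "geojson")) {
  format <- match.arg(format)
  tab <- if (inherits(result, "gwr_fit")) tidy(result) else tibble::as_tibble(result)
  if (nrow(tab) == 0) {
    abort_validation("Result table is empty; nothing to write.")
  }
  cols <- c("station_id", "x", "y", "n_obs", "intercept", "slope",
            "se_intercept", "se_slope", "t_slope", "p_slope", "signif_class",
            "local_r2", "bandwidth_dist", "k")
  missing_cols <- setdiff(cols, names(tab))
  if (length(missing_cols) > 0) {
    abort_validation("Result table lacks column{?s} {.field {missing_cols}}.")
  }
  tab <- tab[cols]
  tab$signif_class <- as.character(tab$signif_class)
  if (format == "csv") {
    readr::write_csv(tab, path, progress = FALSE)
  } else {
    features <- purrr::pmap(tab, function(station_id, x, y, ...) {
      props <- list(station_id = station_id, x = x, y = y, ...)
      list(
        type = "Feature",
        geometry = list(type = "Point", coordinates = c(x, y)),
        properties = props
      )
    })
    fc <- list(type = "FeatureCollection", features = features)
    jsonlite::write_json(fc, path, auto_unbox = TRUE, digits = NA, na = "null")
  }
  gwt_log("write_gwr_results: wrote {nrow(tab)} stations to {.path {path}} ({format}).")
  invisible(path)
}

#' @rdname write_gwr_results
#' @export
read_gwr_results <- function(path) {
  if (!file.exists(path)) {
    abort_config("File {.path {path}} does not exist.")
  }
  readr::read_csv(
    path,
    col_types = readr::cols(
      station_id = readr::col_character(),
      signif_class = readr::col_character(),
      k = readr::col_integer(),
      n_obs = readr::col_integer(),
      .default = readr::col_double()
    ),
    progress = FALSE
  )
}
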