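#' Observation tables and their measurement scale
#'
#' The package represents monitoring data as a long-format tibble with one row
#' per observation: columns `station_id`, `x`, `y` (planar projected metres),
#' `year` (integer calendar year), `value`, and optionally `program` and
#' `month`. The scale the `value` column is currently on — `"raw"`
#' (concentration, e.g. mg/L), `"log10"`, or `"log10_centered"` (log10 after
#' station-wise mean-centering) — is tracked as an attribute so that pipeline
#' stages can refuse input on the wrong scale. Transitions only ever run
#' raw -> log10 -> log10_centered.
#'
#' `as_obs_table()` validates a data frame and stamps the scale;
#' `obs_scale()` reads the scale back; `set_obs_scale()` restamps a table
#' whose attribute was dropped by other data-frame tooling.
#'
#' @param data A data frame with columns `station_id`, `x`, `y`, `year`,
#'   `value`, optionally `program` and `month`.
#' @param scale Scale the `value` column is on: `"raw"`, `"log10"`, or
#'   `"log10_centered"`.
#' @param validate Run validation checks (coordinate consistency, positive
#'   raw values, month range, lon/lat rejection). Default `TRUE`.
#'
#' @details
#' Coordinates must be planar projected metres: all distances in the package
#' are Euclidean. Input that looks like geographic longitude/latitude (every
#' `|x| <= 180` and `|y| <= 90`) is rejected with instructions to project
#' first; there is no on-the-fly reprojection.
#'
#' Duplicate (station, year) rows are deliberately retained: several
#' observations per location are a feature of the pooled local-regression
#' model, not an error. Row order is never changed.
#'
#' @return A tibble with the scale recorded in attribute `"gwtrends_scale"`.
#' @examples
#' obs <- tibble::tibble(
#'   station_id = c("A", "A", "B"), x = c(1e5, 1e5, 2e5),
#'   y = c(6e6, 6e6, 6.5e6), year = c(2008L, 2014L, 2010L),
#'   value = c(8.2, 9.1, 3.3)
#' )
#' tab <- as_obs_table(obs, scale = "raw")
#' obs_scale(tab)
#' @export
as_obs_table <- function(data, scale = c("raw", "log10", "log10_centered"),
                         validate = TRUE) {
  scale <- match.arg(scale)
  data <- tibble::as_tibble(data)
  required <- c("station_id", "x", "y", "year", "value")
  missing_cols <- setdiff(required, names(data))
  if (length(missing_cols) > 0) {
    abort_config("Missing required column{?s}: {.field {missing_cols}}.")
  }
  if (validate) {
    validate_obs_table(data, scale)
  }
  attr(data, "gwtrends_scale") <- scale
  data
}

validate_obs_table <- function(data, scale) {
  for (col in c("x", "y", "value")) {
    if (!is.numeric(data[[col]])) {
      abort_validation("Column {.field {col}} must be numeric.")
    }
  }
  bad <- which(!is.finite(data$x) | !is.finite(data$y))
  if (length(bad) > 0) {
    abort_validation(
      "Non-finite coordinates in row(s) {paste(head(bad, 5), collapse = ', ')}{if (length(bad) > 5) ' ...' else ''}."
    )
  }
  if (!is.numeric(data$year) || any(data$year != round(data$year), na.rm = TRUE) ||
      anyNA(data$year)) {
    abort_validation("Column {.field year} must hold integer calendar years with no missing values.")
  }
  bad_val <- which(!is.finite(data$value))
  if (length(bad_val) > 0) {
    abort_validation(
      "Missing or non-finite value in row(s) {paste(head(bad_val, 5), collapse = ', ')}{if (length(bad_val) > 5) ' ...' else ''}."
    )
  }
  if (scale == "raw") {
    nonpos <- which(data$value <= 0)
    if (length(nonpos) > 0) {
      abort_validation(
        "Raw-scale values must be strictly positive; offending row(s): {paste(head(nonpos, 5), collapse = ', ')}{if (length(nonpos) > 5) ' ...' else ''}."
      )
    }
  }
  if ("month" %in% names(data)) {
    m <- data$month[!is.na(data$month)]
    if (any(m < 1 | m > 12 | m != round(m))) {
      abort_validation("Column {.field month} must contain integers 1..12.")
    }
  }
  if (nrow(data) > 0 && all(abs(data$x) <= 180) && all(abs(data$y) <= 90)) {
    abort_validation(c(
      "Coordinates look like geographic longitude/latitude (degrees).",
      i = "Project stations to a planar metric CRS (metres) before analysis; distances here are Euclidean."
    ))
  }
  # each station must carry a single coordinate pair
  coords <- dplyr::distinct(data, .data$station_id, .data$x, .data$y)
  dup <- coords$station_id[duplicated(coords$station_id)]
  if (length(dup) > 0) {
    dup <- unique(dup)
    abort_validation(
      "{length(dup)} station{?s} appear with more than one coordinate pair: {.val {head(dup, 5)}}."
    )
  }
  invisible(data)
}

#' @rdname as_obs_table
#' @param x An observation table.
#' @export
obs_scale <- function(x) {
  attr(x, "gwtrends_scale") %||% NA_character_
}

#' @rdname as_obs_table
#' @export
set_obs_scale <- function(x, scale = c("raw", "log10", "log10_centered")) {
  scale <- match.arg(scale)
  attr(x, "gwtrends_scale") <- scale
  x
}

# enforce an expected scale, with a helpful state error
check_scale <- function(data, expected, what) {
  sc <- obs_scale(data)
  if (is.na(sc)) {
    abort_state(c(
      "{.arg data} carries no scale attribute.",
      i = "Create it with {.fn as_obs_table} or restore it with {.fn set_obs_scale}."
    ))
  }
  if (!sc %in% expected) {
    abort_state(
      "{what} expects scale {.val {expected}} but received {.val {sc}}."
    )
  }
  sc
}

# distinct stations in first-appearance order
station_table <- function(data) {
  dplyr::distinct(data, .data$station_id, .data$x, .data$y)
}
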