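#' Moran's I spatial autocorrelation of a per-station variable
#'
#' Used here as the pre-fit heterogeneity diagnostic: computed on the crude
#' per-station change per year ([station_summaries()]), a significant
#' positive I means nearby stations change alike — i.e. a single global trend
#' model is inadequate and a geographically weighted analysis is warranted.
#'
#' Weights are inverse Euclidean distance, `w_ij = 1 / d_ij` with a zero
#' diagonal, by default without row standardisation (set
#' `row_standardize = TRUE` for the row-normalised variant). The expected
#' value under no autocorrelation is `-1/(n-1)`; the variance is the analytic
#' moment under the randomization (permutation) assumption, and the p-value
#' is the two-sided normal approximation. The variance formula requires
#' `n >= 4`; with exactly 3 stations the statistic and expectation are still
#' returned but `sd_i` and `p_value` are `NA`.
#'
#' @param values Numeric vector, one value per station.
#' @param coords Data frame or matrix of station coordinates with columns
#'   `x`, `y` (metres), same length as `values`.
#' @param row_standardize Divide each weight row by its sum before computing
#'   the statistic. Default `FALSE`.
#' @return A one-row tibble: `observed_i`, `expected_i`, `sd_i`, `p_value`,
#'   `n`, `weight_scheme`.
#' @export
morans_i <- function(values, coords, row_standardize = FALSE) {
  coords <- as.data.frame(coords)
  if (!all(c("x", "y") %in% names(coords))) {
    names(coords)[1:2] <- c("x", "y")
  }
  n <- length(values)
  if (nrow(coords) != n) {
    abort_validation("{.arg values} and {.arg coords} must have the same length.")
  }
  if (n < 3) {
    abort_validation("Moran's I needs at least 3 stations; received {n}.")
  }
  if (anyNA(values)) {
    abort_validation("{.arg values} must not contain missing values.")
  }
  if (var(values) == 0) {
    abort_degenerate("All values identical: Moran's I is undefined for zero variance.")
  }
  d <- as.matrix(stats::dist(coords[, c("x", "y")]))
  if (any(d[upper.tri(d)] == 0)) {
    abort_validation(c(
      "Coincident stations (pairwise distance 0) make inverse-distance weights undefined.",
      i = "Jitter or aggregate coincident stations first."
    ))
  }
  w <- 1 / d
  diag(w) <- 0
  if (row_standardize) {
    w <- w / rowSums(w)
  }
  z <- values - mean(values)
  s0 <- sum(w)
  m2 <- sum(z^2)
  observed <- (n / s0) * as.numeric(crossprod(z, w %*% z)) / m2
  expected <- -1 / (n - 1)
  if (n >= 4) {
    s1 <- 0.5 * sum((w + t(w))^2)
    s2 <- sum((rowSums(w) + colSums(w))^2)
    b2 <- n * sum(z^4) / m2^2
    var_i <- (n * ((n^2 - 3 * n + 3) * s1 - n * s2 + 3 * s0^2) -
                b2 * ((n^2 - n) * s1 - 2 * n * s2 + 6 * s0^2)) /
      ((n - 1) * (n - 2) * (n - 3) * s0^2) - expected^2
    sd_i <- sqrt(var_i)
    p_value <- 2 * pnorm(-abs((observed - expected) / sd_i))
  } else {
    sd_i <- NA_real_
    p_value <- NA_real_
  }
  scheme <- paste0(
    "inverse Euclidean distance, zero diagonal",
    if (row_standardize) ", row-standardized" else ""
  )
  gwt_log("morans_i: n = {n}, observed I = {signif(observed, 4)}, p = {signif(p_value, 3)} ({scheme}).")
  tibble::tibble(
    observed_i = observed, expected_i = expected, sd_i = sd_i,
    p_value = p_value, n = n, weight_scheme = scheme
  )
}
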