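# Independent oracles, written from the definitions, not from package code.

# Moran's I by explicit double sums over the standard formula
moran_double_sum <- function(values, coords, row_standardize = FALSE) {
  n <- length(values)
  w <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i != j) {
        d <- sqrt((coords$x[i] - coords$x[j])^2 + (coords$y[i] - coords$y[j])^2)
        w[i, j] <- 1 / d
      }
    }
  }
  if (row_standardize) {
    for (i in seq_len(n)) w[i, ] <- w[i, ] / sum(w[i, ])
  }
  z <- values - mean(values)
  num <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(n)) num <- num + w[i, j] * z[i] * z[j]
  }
  (n / sum(w)) * num / sum(z^2)
}

# brute-force leave-one-out CV: package weights, lm() refits
cv_bruteforce <- function(data, k) {
  n <- nrow(data)
  stations <- dplyr::distinct(data, station_id, x, y)
  score <- 0
  for (i in seq_len(n)) {
    st <- stations[stations$station_id == data$station_id[i], ]
    d <- sqrt((data$x - st$x)^2 + (data$y - st$y)^2)
    b <- sort(d)[k]
    w <- bisquare_weight(d, b)
    w[i] <- 0
    keep <- w > 0
    fit <- lm(value ~ year, data = data[keep, ], weights = w[keep])
    pred <- unname(predict(fit, newdata = data[i, ]))
    score <- score + (data$value[i] - pred)^2
  }
  score
}
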