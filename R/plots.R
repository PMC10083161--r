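#' Plot methods
#'
#' `autoplot()` on a `gwr_fit` draws the station map coloured by trend
#' slope (`what = "slope"`), by significance class (`what = "signif"`,
#' blue = significant decrease, red = significant increase, grey = none), or
#' by local R-squared (`what = "local_r2"`). On a `gwr_bandwidth` it draws
#' the CV-score profile over the candidate grid; on a `gwr_windows` result,
#' the distribution of station slopes per temporal window.
#'
#' @param object A `gwr_fit`, `gwr_bandwidth` or `gwr_windows` object.
#' @param what For `gwr_fit`: `"slope"`, `"signif"` or `"local_r2"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @name gwtrends-autoplot
NULL

#' @rdname gwtrends-autoplot
#' @export
autoplot.gwr_fit <- function(object, what = c("slope", "signif", "local_r2"), ...) {
  what <- match.arg(what)
  tab <- tidy(object)
  base <- ggplot2::ggplot(tab, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "Easting (m)", y = "Northing (m)") +
    ggplot2::theme_minimal()
  switch(what,
    slope = base +
      ggplot2::geom_point(ggplot2::aes(colour = .data$slope), size = 1) +
      ggplot2::scale_colour_gradient2(low = "#2166ac", mid = "white", high = "#b2182b") +
      ggplot2::labs(colour = "slope\n(log10/yr)",
                    title = paste0("Local trend slopes (k = ", object$k, ")")),
    signif = base +
      ggplot2::geom_point(ggplot2::aes(colour = .data$signif_class), size = 1) +
      ggplot2::scale_colour_manual(
        values = c(down = "#2166ac", none = "grey70", up = "#b2182b"),
        drop = FALSE
      ) +
      ggplot2::labs(colour = NULL,
                    title = paste0("Significant trends at alpha = ", object$alpha)),
    local_r2 = base +
      ggplot2::geom_point(ggplot2::aes(colour = .data$local_r2), size = 1) +
      ggplot2::scale_colour_viridis_c(limits = c(0, 1)) +
      ggplot2::labs(colour = expression(local ~ R^2),
                    title = "Local goodness of fit")
  )
}

#' @rdname gwtrends-autoplot
#' @export
autoplot.gwr_bandwidth <- function(object, ...) {
  ggplot2::ggplot(object$grid, ggplot2::aes(x = .data$k, y = .data$cv_score)) +
    ggplot2::geom_line(colour = "grey60") +
    ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = object$selected_k, linetype = 2,
                        colour = "#b2182b") +
    ggplot2::labs(
      x = "neighbourhood size k (observations)",
      y = "leave-one-out CV score",
      title = paste0("Bandwidth selection: k = ", object$selected_k)
    ) +
    ggplot2::theme_minimal()
}

#' @rdname gwtrends-autoplot
#' @export
autoplot.gwr_windows <- function(object, ...) {
  tab <- tidy(object)
  tab$window <- paste0(tab$window_start, "–", tab$window_end)
  ggplot2::ggplot(tab, ggplot2::aes(x = .data$window, y = .data$slope)) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey60") +
    ggplot2::geom_boxplot(outlier.size = 0.5) +
    ggplot2::labs(
      x = "temporal window", y = "station trend slope (log10/yr)",
      title = "Slope evolution across moving windows"
    ) +
    ggplot2::theme_minimal()
}
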