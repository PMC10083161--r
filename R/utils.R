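# Internal helpers: logging and error classes.

gwt_verbose <- function() {
  isTRUE(getOption("gwtrends.verbose", TRUE))
}

# info-level pipeline log; silenced with options(gwtrends.verbose = FALSE)
gwt_log <- function(..., .envir = parent.frame()) {
  if (gwt_verbose()) {
    cli::cli_inform(paste0(...), class = "gwtrends_log", .envir = .envir)
  }
  invisible(NULL)
}

gwt_abort <- function(message, class, ..., .envir = parent.frame()) {
  cli::cli_abort(message, class = c(class, "gwtrends_error"), ..., .envir = .envir)
}

abort_config <- function(message, ..., .envir = parent.frame()) {
  gwt_abort(message, "gwtrends_config_error", ..., .envir = .envir)
}

abort_validation <- function(message, ..., .envir = parent.frame()) {
  gwt_abort(message, "gwtrends_validation_error", ..., .envir = .envir)
}

abort_state <- function(message, ..., .envir = parent.frame()) {
  gwt_abort(message, "gwtrends_state_error", ..., .envir = .envir)
}

abort_degenerate <- function(message, ..., .envir = parent.frame()) {
  gwt_abort(message, "gwtrends_degenerate_error", ..., .envir = .envir)
}

# k-th smallest of a numeric vector (ties share a value, so stable by value)
kth_smallest <- function(d, k) {
  sort(d, partial = k)[k]
}
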